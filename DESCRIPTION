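Package: voxelfc
Title: Classification of Resting-State fMRI Cohorts Using Functional
    Connectivity Between Activity Voxels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a voxel-level functional-connectivity pipeline for
    discriminating two cohorts of resting-state fMRI subjects (for example
    Alzheimer's disease patients versus healthy controls). Per-subject spatial
    independent component analysis with minimum-description-length model-order
    estimation and multi-run stability selection detects activity voxels;
    intersection across subjects and cohorts yields the common activity-voxel
    set; Pearson correlations between all pairs of common activity voxels form
    per-subject feature vectors; edge-wise two-sample t-tests with
    Benjamini-Hochberg false-discovery-rate correction select differential
    connections; and repeated stratified hold-out support-vector-machine
    evaluation compares the selected features against the full connectivity
    profile. A synthetic group-fMRI generator with planted active regions and
    planted differential edges provides ground truth for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    MASS,
    rpart,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
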