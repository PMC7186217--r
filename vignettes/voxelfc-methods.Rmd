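---
title: "Voxel-level functional connectivity classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level functional connectivity classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

voxelfc discriminates two cohorts of resting-state fMRI subjects — the
motivating case is Alzheimer's disease (AD) patients versus healthy controls
(HC) — using the functional connectivity between *activity voxels*: voxels
that carry strong loadings in the spatial independent components of each
subject's data.

Each subject's preprocessed, spatially normalized 4D volume is reduced to a
matrix $X_i \in \mathbb{R}^{T \times V}$ of $T$ timepoints by $V$ in-mask
voxels, modelled by the spatial-ICA generative equation

$$X_i = M_i S_i + E_i,$$

where the rows of $S_i \in \mathbb{R}^{N_i \times V}$ are statistically
independent spatial maps, the columns of $M_i \in \mathbb{R}^{T \times N_i}$
are their time courses, and $E_i$ is noise. The pipeline then proceeds in
four stages:

1. **Activity voxels.** Each spatial map is z-scored over in-mask voxels
   (population denominator). Subject $i$'s activity-voxel location set is
   $\mathrm{AVL}_i = \bigcup_j \{v : |z_{ij}(v)| \ge \theta\}$, with
   $\theta = 2$ by default. The comparison is inclusive, and because of the
   absolute value the set is invariant to the arbitrary sign and order of
   ICA components.
2. **Common activity voxels.** Within each cohort,
   $\mathrm{CAVL}_g = \bigcap_i \mathrm{AVL}_i$; across cohorts,
   $\mathrm{CAVL}_{12} = \mathrm{CAVL}_1 \cap \mathrm{CAVL}_2$ with
   $N_{12}$ voxels. Intersection rather than union deliberately keeps only
   locations active in *every* subject, which suppresses noise-driven
   "activations" that do not replicate across subjects.
3. **Connectivity features.** For each subject, the Pearson correlation of
   the time series of every unordered pair of $\mathrm{CAVL}_{12}$ voxels
   gives a feature vector of length $N_{12}(N_{12}-1)/2$, computed on the
   (optionally band-passed) data matrix itself, not on any ICA
   reconstruction. Edges are enumerated lexicographically over positions in
   the sorted voxel set, so feature $e$ means the same voxel pair for every
   subject. No Fisher transform is applied to the features; the raw
   correlation is the feature.
4. **Differential edges and classification.** Each edge is tested with a
   two-sided pooled-variance two-sample t-test; Benjamini–Hochberg FDR
   adjustment is applied over the full edge family, and the differential set
   DFCI keeps edges with adjusted $p < 0.05$ (strict). The selected columns
   (DFC features) and the full feature matrix are then both evaluated with a
   repeated stratified 80/20 hold-out linear SVM ($C = 1$), sharing split
   sequences so the comparison is paired.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `theta` | 2 | activity threshold on the z-scored maps (z units); swept 1.5–2.5 by `threshold_sweep()` |
| `alpha` | 0.05 | significance level on the FDR-adjusted scale |
| `ica_order` | `"mdl"` | number of components, estimated per subject by MDL (cap `max_order = 30`) |
| `ica_runs` | 20 | ICA runs pooled by stability selection; 1 = single run |
| `svm_c` | 1 | SVM soft-margin constant |
| `train_fraction`, `n_runs` | 0.8, 1000 | repeated hold-out protocol |
| `low_hz`, `high_hz`, `tr_seconds` | 0.01, 0.08, 3 | optional band-pass (off by default; inputs are assumed preprocessed) |

The MDL model order minimizes
$-V(T-k)\log(g_k/a_k) + \tfrac{1}{2}k(2T-k)\log V$ over $k$, where $g_k$ and
$a_k$ are the geometric and arithmetic means of the $T-k$ smallest
eigenvalues of the temporal covariance — the standard information-theoretic
order choice for spatial ICA (T channels, V samples). Different MDL variants
would change only $N_i$; activity detection is a union over components, so
mild over-estimation of the order is benign.

ICA itself is symmetric fixed-point iteration with the tanh contrast,
tolerance $10^{-4}$, at most 1000 iterations, after PCA whitening; data are
standardized by removing each voxel's temporal mean only (no variance
normalization), so downstream correlations are computed on the original
signal scale. Components are returned in decreasing order of the variance
explained by their time course. Multi-run stability selection pools the maps
of `ica_runs` randomized runs (random initialization, plus timepoint
bootstrap), clusters them by average-linkage agglomeration of
$1-|r|$, and keeps each cluster's centrotype; the per-component stability
index is the mean within-cluster $|r|$ minus the mean between-cluster $|r|$.
Single fixed-point runs can occasionally converge to a mixed spurious
optimum; the multi-run procedure is the standard remedy and is the default.

## Classification protocol choices

Splits are stratified by default (the cohorts of interest are imbalanced,
67/76-like, and unstratified 20% test draws can lose a class); an
unstratified mode exists. Features are z-scored using training-split
statistics only, because SVMs are scale sensitive. The positive class for
sensitivity is the patient cohort (second group label by default).
Comparison baselines follow common practice where the original protocol is
silent: Gaussian-SVM bandwidth $1/p$, KNN with $k = 5$, decision trees with
`minsplit = 4` (the rpart default of 20 refuses to split at ~19 training
subjects per class), logistic regression and LDA as implemented in stats and
MASS. These baselines are intended for the low-dimensional DFC feature set;
with many more features than subjects, LDA and logistic regression are
rank-deficient and only the SVM baselines are meaningful.

## The synthetic generator

`generate_cohorts()` emulates the study conditions at desk scale: a
$12^3$ grid, $T = 130$ timepoints at TR $= 3$ s (a 140-volume acquisition
minus 10 discarded volumes), four spherical sources of radius 2 (33 voxels
each) common to all subjects, per-subject band-limited (0.01–0.08 Hz) source
time courses with 10% amplitude jitter, white noise with sd 0.05 relative to
the unit source amplitude, and two cohorts of 20 subjects. Differential
connectivity is planted at 10 voxel pairs spanning different sources: each
planted voxel's series is a mix $\sqrt{1-w}\,\mathrm{tc} + \sqrt{w}\,r$ of
its source time course and a latent residual channel, with $w = 0.6$ and the
two residuals of a pair correlated so the pair's total correlation hits the
cohort target — 0.1 in cohort 1 versus 0.5 in cohort 2
($\Delta r = 0.4$). Targets beyond $0.95\,w$ are infeasible and rejected
with the attainable bound.

Two design choices matter for interpretation:

* **Sample-exact orthogonality.** Within each subject, source time courses
  (and each pair's latent residuals, against the sources) are QR-
  orthogonalized before scaling. Empirical correlations between two
  independent band-limited series at $T = 130$ have sd $\approx 0.13$;
  without orthogonalization these chance correlations are *shared* by every
  between-source voxel pair, and their cohort-level average acts as a
  correlated confound that the edge-wise t-test flags as dozens of spurious
  differential edges. Orthogonalization makes the null exactly null and the
  planted correlations sample-exact, so edge-level recovery is crisply
  scoreable. The cost is realism: real data have exactly such shared
  fluctuations, and the package's FDR behaviour on real data will be
  correspondingly less clean than on the generator.
* **Point-planted edges.** Differential connectivity is planted at specific
  voxel pairs rather than as whole-network covariance changes, so edge-level
  sensitivity and precision are well defined.

What the generator does *not* emulate: hemodynamic response shapes, motion
and physiological artifacts, scanner drift, spatial autocorrelation of
noise, anatomical variability, and registration error. Passing the
recovery and calibration tests therefore demonstrates the correctness of
the pipeline's statistics under its own model assumptions, not expected
performance on clinical data.

## Numerical conventions and degenerate inputs

* Canonical voxel order is R's native array order (x fastest, z slowest);
  all voxel indices are 1-based positions within the in-mask ordering of a
  shared brain mask.
* The automatic mask keeps voxels with strictly positive temporal variance
  in every subject, which guarantees every Pearson correlation downstream is
  defined; an explicit mask, if given, is additionally pruned by the same
  rule.
* Band-pass filtering is an ideal (frequency-rectangle) zero-phase filter
  after per-voxel linear detrending, the convention of common resting-state
  toolboxes.
* Zero pooled variance at an edge yields $t = 0$, $p = 1$ when group means
  agree, and a flagged degenerate $p = 0$ when they differ.
* An empty differential selection is a typed outcome, not an error; the
  pipeline then evaluates the full feature set and records the fallback. An
  empty joint common voxel set raises a typed error suggesting a lower
  threshold; the threshold sweep records such rows as degenerate and
  continues.
* Atlas-region summaries use the strict filters (more than `min_count`
  voxels *and* more than `min_fraction` of the region); the filter affects
  reporting only. By default the joint common voxel set used for features is
  not atlas-restricted; `atlas_restrict = TRUE` confines it to labelled
  (e.g. gray-matter) voxels, since both readings of the original protocol
  are defensible.
* Every stochastic stage takes an explicit seed and is bitwise reproducible;
  multi-run ICA uses `base_seed + run - 1`, evaluation split $r$ uses
  `base_seed + r`.

## Problem sizes used by the shipped experiments

The package's acceptance experiments run on the generator defaults with
single-run ICA inside the replicate loops (20 null-calibration replicates,
10 recovery seeds), 200 hold-out splits for the paired feature-set contrast
and 50 splits per threshold in the 11-point sweep. These sizes are the
package's own choices for a desk-scale demonstration; the protocol constants
themselves (80/20, $C = 1$, $\theta$ grid) are the defaults documented
above, and `eval_protocol(n_runs = 1000)` reproduces the full-size protocol.

## Known limitations

* Per-subject ICA followed by intersection assumes spatial normalization has
  brought homologous voxels into register; no dual-regression or group-ICA
  variant is provided.
* The differential selection is computed once on all subjects by default,
  as in the original protocol; this leaks selection information into the
  held-out evaluation. The `nested_selection` option re-selects inside each
  training split and reports the leakage-free accuracy alongside — on real
  data the nested estimate is the one to trust.
* The pooled t-test assumes equal edge variance across cohorts (`welch =
  TRUE` relaxes this), and testing raw correlations rather than Fisher-z
  values follows the original formulation (`fisher_z = TRUE` is available).
* MDL assumes white residual noise; coloured noise typically inflates the
  estimated order, which the union over components tolerates.
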