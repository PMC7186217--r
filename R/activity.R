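# Activity-voxel detection and intersection: per-subject activity-voxel
# location sets (AVL), their within-cohort intersection (CAVL), the joint
# intersection of the two cohorts (CAVL12), and atlas-region summaries.

#' Construct a voxel location set
#'
#' Indices are 1-based positions in the canonical in-mask ordering of `mask`,
#' kept strictly increasing.
#'
#' @param indices integer vector of in-mask voxel positions.
#' @param mask the shared [brain_mask()].
#' @param provenance one of `"subject_avl"`, `"group_cavl"`, `"joint_cavl12"`.
#' @return An object of class `voxel_set` with fields `indices`, `n`,
#'   `provenance` and `mask`.
#' @export
voxel_set <- function(indices, mask, provenance = c("subject_avl", "group_cavl", "joint_cavl12")) {
  provenance <- match.arg(provenance)
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && (indices[1] < 1L || indices[length(indices)] > mask$n_voxels))
    vfc_error("voxelfc_parameter_error", "voxel indices outside 1..n_voxels")
  structure(list(indices = indices, n = length(indices),
                 provenance = provenance, mask = mask),
            class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("voxel_set (%s): %d voxels\n", x$provenance, x$n))
  invisible(x)
}

#' Per-subject activity voxels from z-scored maps
#'
#' A voxel is active if its absolute z value reaches the threshold `theta` in
#' at least one component (inclusive comparison, `|z| >= theta`); the
#' subject's activity-voxel location set is the union over components.
#'
#' @param zmaps a `zmaps` object.
#' @param mask the shared [brain_mask()].
#' @param theta activation threshold on the z scale (default 2).
#' @return A `voxel_set` with provenance `subject_avl`; empty sets are
#'   permitted but flagged with a warning.
#' @export
subject_active_voxels <- function(zmaps, mask, theta = 2) {
  if (!is_number(theta) || theta <= 0)
    vfc_error("voxelfc_parameter_error", "theta must be a positive number")
  hit <- which(colSums(abs(zmaps$z) >= theta) > 0L)
  if (!length(hit))
    vfc_warn("voxelfc_empty_warning",
             sprintf("no activity voxels for subject '%s' at theta = %g",
                     zmaps$subject_id, theta))
  voxel_set(hit, mask, "subject_avl")
}

check_same_mask <- function(sets) {
  n <- vapply(sets, function(s) s$mask$n_voxels, integer(1))
  shapes <- vapply(sets, function(s) paste(s$mask$grid$shape, collapse = "x"), character(1))
  if (length(unique(n)) != 1L || length(unique(shapes)) != 1L)
    vfc_error("voxelfc_spatial_error", "voxel sets do not share one brain mask")
}

#' Common activity voxels of a cohort
#'
#' Intersects the activity-voxel sets of all subjects in one cohort.
#'
#' @param avls nonempty list of `voxel_set`s with provenance `subject_avl`
#'   (or `group_cavl`), all on the same mask.
#' @return A `voxel_set` with provenance `group_cavl`.
#' @export
group_common_voxels <- function(avls) {
  if (!length(avls))
    vfc_error("voxelfc_parameter_error", "need at least one activity-voxel set")
  check_same_mask(avls)
  common <- Reduce(intersect, lapply(avls, `[[`, "indices"))
  if (!length(common))
    vfc_warn("voxelfc_empty_warning",
             "no voxel is active in every subject; consider lowering theta")
  voxel_set(common, avls[[1]]$mask, "group_cavl")
}

#' Joint common activity voxels of two cohorts
#'
#' Intersects the two cohorts' common activity-voxel sets; the result indexes
#' the voxel pairs over which functional-connectivity features are computed.
#'
#' @param cavl1,cavl2 `voxel_set`s with provenance `group_cavl` on one mask.
#' @return A `voxel_set` with provenance `joint_cavl12`.
#' @export
joint_common_voxels <- function(cavl1, cavl2) {
  if (cavl1$provenance != "group_cavl" || cavl2$provenance != "group_cavl")
    vfc_error("voxelfc_parameter_error", "inputs must be cohort-level common voxel sets")
  check_same_mask(list(cavl1, cavl2))
  common <- intersect(cavl1$indices, cavl2$indices)
  if (length(common) < 2L)
    vfc_error("voxelfc_degenerate_error",
              "fewer than 2 joint common activity voxels: no connectivity computable; consider lowering theta")
  voxel_set(common, cavl1$mask, "joint_cavl12")
}

#' Restrict a voxel set to atlas-labelled voxels
#'
#' Optionally confines a voxel set to voxels carrying a nonzero atlas label
#' (for example gray-matter regions) before connectivity is computed.
#'
#' @param voxels a `voxel_set`.
#' @param atlas an `atlas_labels` object on the same grid.
#' @return A `voxel_set` with the same provenance.
#' @export
restrict_to_atlas <- function(voxels, atlas) {
  lin <- mask_linear_indices(voxels$mask)[voxels$indices]
  keep <- atlas$labels[lin] > 0L
  voxel_set(voxels$indices[keep], voxels$mask, voxels$provenance)
}

#' Summarize a voxel set by atlas region
#'
#' Counts active voxels per region and keeps regions with strictly more than
#' `min_count` active voxels that make up strictly more than `min_fraction`
#' of the region's in-mask size; this filter affects reporting only.  The
#' representative coordinate is the world-mm centroid of the region's active
#' voxels.
#'
#' @param voxels a `voxel_set`.
#' @param atlas an `atlas_labels` object on the same grid.
#' @param min_count minimum active-voxel count (exclusive; default 10).
#' @param min_fraction minimum active fraction of the region (exclusive;
#'   default 0.01).
#' @return A data.frame with columns `label`, `name`, `voxel_number`,
#'   `voxel_ratio`, `x_mm`, `y_mm`, `z_mm`.
#' @export
summarize_regions <- function(voxels, atlas, min_count = 10L, min_fraction = 0.01) {
  if (!all(atlas$grid$shape == voxels$mask$grid$shape))
    vfc_error("voxelfc_spatial_error", "atlas grid does not match mask grid")
  lin <- mask_linear_indices(voxels$mask)[voxels$indices]
  lab <- atlas$labels[lin]
  keep <- lab > 0L
  lin <- lin[keep]; lab <- lab[keep]
  out <- data.frame(label = integer(0), name = character(0),
                    voxel_number = integer(0), voxel_ratio = numeric(0),
                    x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0))
  for (l in sort(unique(lab))) {
    idx <- lin[lab == l]
    count <- length(idx)
    size <- atlas$region_sizes[[as.character(l)]]
    frac <- count / size
    if (count > min_count && frac > min_fraction) {
      cen <- colMeans(grid_world_coords(atlas$grid, idx))
      out <- rbind(out, data.frame(
        label = l, name = atlas$region_names[[as.character(l)]],
        voxel_number = count, voxel_ratio = frac,
        x_mm = cen[1], y_mm = cen[2], z_mm = cen[3]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write / read a voxel set as plain text and as a NIfTI mask
#'
#' @param voxels a `voxel_set`.
#' @param prefix output prefix; writes `<prefix>.txt` (one in-mask index per
#'   line) and `<prefix>.nii.gz` (binary mask volume).
#' @export
write_voxel_set <- function(voxels, prefix) {
  writeLines(as.character(voxels$indices), paste0(prefix, ".txt"))
  flags <- rep(0, prod(voxels$mask$grid$shape))
  flags[mask_linear_indices(voxels$mask)[voxels$indices]] <- 1
  write_nifti_grid(array(flags, dim = voxels$mask$grid$shape),
                   voxels$mask$grid, paste0(prefix, ".nii.gz"))
  invisible(prefix)
}

#' @rdname write_voxel_set
#' @param path path to a text file of in-mask indices.
#' @param mask the shared [brain_mask()].
#' @param provenance provenance tag for the restored set.
#' @export
read_voxel_set <- function(path, mask, provenance = "subject_avl") {
  voxel_set(as.integer(readLines(path)), mask, provenance)
}
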