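# Functional-connectivity features: Pearson correlation between every pair of
# joint common activity voxels, one feature vector per subject.

#' Canonical edge enumeration over a joint common voxel set
#'
#' Enumerates all unordered pairs (p, q), p < q, of positions 1..N12 within
#' the sorted joint common voxel set, lexicographically by (p, q).  The
#' enumeration is identical for every subject sharing the set, so feature e
#' always refers to the same voxel pair.
#'
#' @param cavl12 a `voxel_set` with provenance `joint_cavl12` (or an integer
#'   count N12).
#' @return A list with `pairs` (2 x E matrix of positions), `voxel_pairs`
#'   (2 x E matrix of in-mask voxel indices, when a voxel set was given) and
#'   `edge_count` E = N12 (N12 - 1) / 2.
#' @export
edge_index <- function(cavl12) {
  if (inherits(cavl12, "voxel_set")) {
    n <- cavl12$n
    vox <- cavl12$indices
  } else {
    n <- as.integer(cavl12)
    vox <- NULL
  }
  if (n < 2L)
    vfc_error("voxelfc_degenerate_error", "need at least 2 voxels to form edges")
  pairs <- combn(n, 2L)
  list(pairs = pairs,
       voxel_pairs = if (!is.null(vox)) rbind(vox[pairs[1, ]], vox[pairs[2, ]]),
       edge_count = ncol(pairs))
}

#' Per-subject functional-connectivity feature vector
#'
#' Pearson correlation of the time series of every pair of joint common
#' activity voxels, in canonical edge order.
#'
#' @param subject a `subject_matrix` (T >= 3 timepoints).
#' @param cavl12 a `voxel_set` with provenance `joint_cavl12`.
#' @return An object of class `fc_vector` with `values` of length
#'   N12 (N12 - 1) / 2.
#' @export
fc_vector <- function(subject, cavl12) {
  if (cavl12$provenance != "joint_cavl12")
    vfc_error("voxelfc_parameter_error", "cavl12 must have provenance joint_cavl12")
  if (subject$t_points < 3L)
    vfc_error("voxelfc_degenerate_error", "need at least 3 timepoints for correlation")
  X <- subject$data[, cavl12$indices, drop = FALSE]
  sds <- apply(X, 2, sd)
  bad <- which(sds <= 0)
  if (length(bad))
    vfc_error("voxelfc_degenerate_error", sprintf(
      "zero-variance series at joint common voxel(s): %s",
      paste(cavl12$indices[bad], collapse = ", ")))
  R <- cor(X)
  ei <- edge_index(cavl12)
  structure(list(subject_id = subject$subject_id,
                 values = R[t(ei$pairs)],
                 edge_count = ei$edge_count),
            class = "fc_vector")
}

#' Stack the FC vectors of one cohort into a feature matrix
#'
#' @param subjects list of `subject_matrix` objects sharing one group label
#'   and mask.
#' @param cavl12 a `voxel_set` with provenance `joint_cavl12`.
#' @return An object of class `group_fc_matrix` with `matrix`
#'   (subjects x edges), `group_label`, `subject_ids` and the edge index.
#' @export
stack_group_fc <- function(subjects, cavl12) {
  if (!length(subjects))
    vfc_error("voxelfc_grouping_error", "empty subject list")
  labels <- vapply(subjects, `[[`, character(1), "group_label")
  if (length(unique(labels)) != 1L)
    vfc_error("voxelfc_grouping_error", sprintf(
      "mixed group labels in one cohort: %s", paste(unique(labels), collapse = ", ")))
  rows <- lapply(subjects, function(s) fc_vector(s, cavl12)$values)
  structure(list(group_label = labels[1],
                 matrix = do.call(rbind, rows),
                 subject_ids = vapply(subjects, `[[`, character(1), "subject_id"),
                 edges = edge_index(cavl12)),
            class = "group_fc_matrix")
}

#' @export
print.group_fc_matrix <- function(x, ...) {
  cat(sprintf("group_fc_matrix '%s': %d subjects x %d edges\n",
              x$group_label, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Export a cohort FC matrix as TSV
#'
#' Column e is named `v<p>_v<q>` after the in-mask indices of the two voxels
#' of edge e.
#'
#' @param fc a `group_fc_matrix`.
#' @param path output TSV path.
#' @export
write_group_fc <- function(fc, path) {
  vp <- fc$edges$voxel_pairs
  colnames(fc$matrix) <- paste0("v", vp[1, ], "_v", vp[2, ])
  df <- data.frame(subject_id = fc$subject_ids, fc$matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
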