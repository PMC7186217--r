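# Synthetic two-cohort resting-state fMRI generator with ground truth.
#
# Each subject is generated from the linear mixing model X = M S + noise:
# spherical spatial sources (shared across subjects and cohorts, so the
# activity-voxel intersection is well defined) times per-subject band-limited
# time courses, plus white Gaussian noise.  Differential connectivity is
# planted at specific voxel pairs by mixing a shared band-limited latent
# signal into the two voxels' residuals so that each cohort's pairwise
# correlation has a known target value, which makes edge-level recovery
# exactly scoreable.

#' Configuration of the synthetic group-fMRI generator
#'
#' Defaults emulate a small-scale version of a typical resting-state
#' acquisition: 130 retained volumes at TR = 3 s, sources band-limited to
#' 0.01-0.08 Hz, two cohorts of 20 subjects, four spherical active regions,
#' and 10 planted differential edges whose cohort correlations differ by 0.4.
#'
#' @param grid_shape 3D grid (default 12 x 12 x 12).
#' @param t_points timepoints per subject (default 130, minimum 20).
#' @param tr_seconds repetition time (default 3 s).
#' @param n_sources number of spherical sources (default 4).
#' @param radius blob radius in voxels (default 2).
#' @param amplitude source amplitude (default 1).
#' @param n_subjects length-2 vector of cohort sizes (default 20, 20).
#' @param group_labels the two cohort labels (default `"HC"`, `"AD"`).
#' @param noise_sd white-noise standard deviation relative to the unit source
#'   amplitude (default 0.05).
#' @param n_diff_edges number of planted differential voxel pairs (default
#'   10); pairs connect voxels of different sources and reuse no voxel.
#' @param diff_corr length-2 vector: target pair correlation in cohort 1 and
#'   cohort 2 (default 0.1 and 0.5). Set `n_diff_edges = 0` for a null
#'   dataset with identically distributed cohorts.
#' @param residual_weight fraction of a planted voxel's signal variance
#'   carried by the correlated residual channel (default 0.6); target
#'   correlations are attainable up to `0.95 * residual_weight`.
#' @param subject_jitter per-subject relative amplitude variability (default 0.1).
#' @param band_hz pass band of the source time courses (default 0.01-0.08 Hz).
#' @param seed RNG seed; generation is bitwise-deterministic given the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(12L, 12L, 12L), t_points = 130L,
                         tr_seconds = 3, n_sources = 4L, radius = 2,
                         amplitude = 1, n_subjects = c(20L, 20L),
                         group_labels = c("HC", "AD"), noise_sd = 0.05,
                         n_diff_edges = 10L, diff_corr = c(0.1, 0.5),
                         residual_weight = 0.6, subject_jitter = 0.1,
                         band_hz = c(0.01, 0.08), seed = 1L) {
  if (!is_count(t_points, min = 20L))
    vfc_error("voxelfc_parameter_error", "t_points must be an integer >= 20")
  if (length(n_subjects) != 2L || any(n_subjects < 1L))
    vfc_error("voxelfc_parameter_error", "n_subjects must be two positive counts")
  if (any(abs(diff_corr) > 0.95))
    vfc_error("voxelfc_parameter_error", "target correlations must lie in [-0.95, 0.95]")
  bound <- 0.95 * residual_weight
  if (n_diff_edges > 0L && any(abs(diff_corr) > bound))
    vfc_error("voxelfc_feasibility_error", sprintf(
      "target correlation %.2f exceeds the attainable bound %.3f at residual_weight %.2f",
      max(abs(diff_corr)), bound, residual_weight))
  structure(list(grid_shape = as.integer(grid_shape), t_points = as.integer(t_points),
                 tr_seconds = tr_seconds, n_sources = as.integer(n_sources),
                 radius = radius, amplitude = amplitude,
                 n_subjects = as.integer(n_subjects), group_labels = group_labels,
                 noise_sd = noise_sd, n_diff_edges = as.integer(n_diff_edges),
                 diff_corr = diff_corr, residual_weight = residual_weight,
                 subject_jitter = subject_jitter, band_hz = band_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Evenly spread blob centres inside the grid, away from the faces.
default_blob_centers <- function(shape, n_sources, radius) {
  lo <- rep(ceiling(radius) + 1, 3)
  hi <- shape - ceiling(radius)
  corners <- rbind(c(lo[1], lo[2], lo[3]), c(hi[1], hi[2], lo[3]),
                   c(lo[1], hi[2], hi[3]), c(hi[1], lo[2], hi[3]),
                   c(hi[1], hi[2], hi[3]), c(lo[1], lo[2], hi[3]),
                   c(lo[1], hi[2], lo[3]), c(hi[1], lo[2], lo[3]))
  if (n_sources > nrow(corners))
    vfc_error("voxelfc_parameter_error", "at most 8 default sources supported")
  corners[seq_len(n_sources), , drop = FALSE]
}

blob_voxels <- function(shape, center, radius) {
  ijk <- arrayInd(seq_len(prod(shape)), shape)
  d2 <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 + (ijk[, 3] - center[3])^2
  which(d2 <= radius^2)
}

# n independent unit-variance series band-limited to band_hz, T x n.  The DC
# bin is outside the band, so every column has exact zero sample mean.
band_limited_series <- function(t_points, tr_seconds, band_hz, n) {
  raw <- matrix(rnorm(t_points * n), t_points, n)
  out <- ideal_bandpass(raw, band_hz[1], band_hz[2], tr_seconds)
  sdv <- apply(out, 2, sd)
  sdv[sdv <= 0] <- 1
  sweep(out, 2, sdv, "/")
}

# Band-limited series that are sample-orthogonal to each other (and to the
# columns of `against`), rescaled to unit sd.  Sample-exact orthogonality
# keeps baseline cross-source correlations at zero within every subject, so
# chance cohort-level correlation offsets cannot masquerade as differential
# connectivity, and planted pair correlations hit their targets exactly.
orthogonal_series <- function(t_points, tr_seconds, band_hz, n, against = NULL) {
  raw <- band_limited_series(t_points, tr_seconds, band_hz, n)
  if (!is.null(against)) {
    q <- qr.Q(qr(against))
    raw <- raw - q %*% crossprod(q, raw)
  }
  out <- qr.Q(qr(raw))
  sdv <- apply(out, 2, sd)
  sdv[sdv <= 0] <- 1
  sweep(out, 2, sdv, "/")
}

#' Generate two synthetic cohorts with ground truth
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_dataset`: `grid`, `subjects` (list with
#'   `subject_id`, `group_label` and a T x grid-voxels series matrix),
#'   `truth` (active voxel set, per-source voxel lists, source time courses
#'   per subject, planted differential edges with cohort targets), `atlas`
#'   (3D label array, one region per source) and the `config`.
#' @export
generate_cohorts <- function(config = synth_config()) {
  shape <- config$grid_shape
  Vg <- prod(shape)
  Tn <- config$t_points
  centers <- default_blob_centers(shape, config$n_sources, config$radius)
  blobs <- lapply(seq_len(config$n_sources),
                  function(j) blob_voxels(shape, centers[j, ], config$radius))
  active <- sort(unique(unlist(blobs)))
  atlas <- rep(0L, Vg)
  for (j in seq_len(config$n_sources)) atlas[blobs[[j]]] <- j

  # Planted differential pairs: voxels from different blobs, no voxel reused.
  diff_edges <- NULL
  if (config$n_diff_edges > 0L) {
    pool <- lapply(blobs, function(b) b)
    u <- integer(config$n_diff_edges); v <- integer(config$n_diff_edges)
    src <- cbind(rep(seq_len(config$n_sources), length.out = config$n_diff_edges),
                 rep(c(seq_len(config$n_sources)[-1], 1L), length.out = config$n_diff_edges))
    taken <- integer(0)
    for (k in seq_len(config$n_diff_edges)) {
      cand_u <- setdiff(pool[[src[k, 1]]], taken)
      cand_v <- setdiff(pool[[src[k, 2]]], taken)
      if (!length(cand_u) || !length(cand_v))
        vfc_error("voxelfc_parameter_error", "not enough blob voxels for the requested diff edges")
      u[k] <- cand_u[1]; v[k] <- cand_v[1]
      taken <- c(taken, u[k], v[k])
    }
    diff_edges <- data.frame(voxel_u = u, voxel_v = v,
                             source_u = src[, 1], source_v = src[, 2],
                             target_corr_1 = config$diff_corr[1],
                             target_corr_2 = config$diff_corr[2])
  }

  labels <- rep(config$group_labels, config$n_subjects)
  n_total <- sum(config$n_subjects)
  subjects <- vector("list", n_total)
  truth_tc <- vector("list", n_total)
  w <- config$residual_weight
  for (i in seq_len(n_total)) {
    g <- match(labels[i], config$group_labels)
    gen <- with_seed(config$seed + 1000L * i, {
      tc <- orthogonal_series(Tn, config$tr_seconds, config$band_hz, config$n_sources)
      amp <- config$amplitude * pmax(0.2, 1 + config$subject_jitter * rnorm(config$n_sources))
      X <- matrix(0, Tn, Vg)
      for (j in seq_len(config$n_sources))
        X[, blobs[[j]]] <- tcrossprod(tc[, j] * amp[j], rep(1, length(blobs[[j]])))
      if (!is.null(diff_edges)) {
        rho <- config$diff_corr[g] / w
        for (k in seq_len(nrow(diff_edges))) {
          lat <- orthogonal_series(Tn, config$tr_seconds, config$band_hz, 3L, against = tc)
          ru <- sqrt(abs(rho)) * lat[, 1] + sqrt(1 - abs(rho)) * lat[, 2]
          rv <- sign(rho) * sqrt(abs(rho)) * lat[, 1] + sqrt(1 - abs(rho)) * lat[, 3]
          ju <- diff_edges$source_u[k]; jv <- diff_edges$source_v[k]
          X[, diff_edges$voxel_u[k]] <-
            amp[ju] * (sqrt(1 - w) * tc[, ju] + sqrt(w) * ru)
          X[, diff_edges$voxel_v[k]] <-
            amp[jv] * (sqrt(1 - w) * tc[, jv] + sqrt(w) * rv)
        }
      }
      if (config$noise_sd > 0)
        X <- X + config$noise_sd * matrix(rnorm(Tn * Vg), Tn, Vg)
      list(series = X, tc = tc)
    })
    truth_tc[[i]] <- gen$tc
    subjects[[i]] <- list(
      subject_id = sprintf("%s_%02d", labels[i], sum(labels[seq_len(i)] == labels[i])),
      group_label = labels[i], series = gen$series)
  }
  structure(list(
    grid = volume_grid(shape),
    subjects = subjects,
    truth = list(active_voxels = active, source_voxels = blobs,
                 centers = centers, time_courses = truth_tc,
                 diff_edges = diff_edges),
    atlas = array(atlas, dim = shape),
    config = config),
    class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d subjects (%s), grid %s, %d active voxels, %d planted edges\n",
              length(x$subjects),
              paste(x$config$n_subjects, collapse = "+"),
              paste(x$grid$shape, collapse = "x"),
              length(x$truth$active_voxels),
              if (is.null(x$truth$diff_edges)) 0L else nrow(x$truth$diff_edges)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one 4D NIfTI volume per subject, a cohort manifest TSV
#' (`subject_id`, `group_label`, `path`), the toy atlas volume, and the
#' ground truth as JSON.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) instead of `.nii`.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  shape <- dataset$grid$shape
  rows <- lapply(dataset$subjects, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ext))
    arr <- array(t(s$series), dim = c(shape, nrow(s$series)))
    write_nifti_grid(arr, dataset$grid, path)
    data.frame(subject_id = s$subject_id, group_label = s$group_label, path = path)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_nifti_grid(dataset$atlas, dataset$grid, file.path(dir, paste0("atlas", ext)))
  truth <- dataset$truth
  truth$time_courses <- NULL  # bulky; regenerate from the config if needed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Score pipeline recovery against ground truth
#'
#' Voxel level: sensitivity of the recovered common activity voxels against
#' the planted active set, and the fraction of truly inactive in-mask voxels
#' wrongly recovered.  Edge level: sensitivity and precision of the selected
#' differential edges against the planted pairs (unordered match).
#'
#' @param truth the `truth` element of a `synth_dataset`.
#' @param cavl12 recovered `voxel_set` (any provenance).
#' @param dfc_result optional `dfc_result` carrying an edge index; when
#'   absent, only voxel metrics are returned.
#' @return A list with `voxel_sensitivity`, `voxel_fp_fraction`, and (when
#'   edges were scored) `edge_sensitivity` and `edge_precision`
#'   (`NA` when nothing was selected).
#' @export
recovery_score <- function(truth, cavl12, dfc_result = NULL) {
  mask <- cavl12$mask
  lin <- mask_linear_indices(mask)
  recovered <- lin[cavl12$indices]
  active <- intersect(truth$active_voxels, lin)
  inactive <- setdiff(lin, active)
  out <- list(
    voxel_sensitivity = if (length(active)) length(intersect(recovered, active)) / length(active) else NA_real_,
    voxel_fp_fraction = if (length(inactive)) length(setdiff(recovered, active)) / length(inactive) else 0)
  if (!is.null(dfc_result)) {
    planted <- truth$diff_edges
    if (is.null(planted) || !nrow(planted)) {
      out$edge_sensitivity <- NA_real_
      out$edge_precision <- NA_real_
      return(out)
    }
    truth_keys <- paste(pmin(planted$voxel_u, planted$voxel_v),
                        pmax(planted$voxel_u, planted$voxel_v))
    if (length(dfc_result$dfci)) {
      vp <- dfc_result$edges$voxel_pairs[, dfc_result$dfci, drop = FALSE]
      gu <- lin[vp[1, ]]; gv <- lin[vp[2, ]]
      sel_keys <- paste(pmin(gu, gv), pmax(gu, gv))
      out$edge_sensitivity <- mean(truth_keys %in% sel_keys)
      out$edge_precision <- mean(sel_keys %in% truth_keys)
    } else {
      out$edge_sensitivity <- 0
      out$edge_precision <- NA_real_
    }
  }
  out
}
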