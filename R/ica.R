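# Per-subject spatial ICA: MDL model-order estimation, fixed-point ICA on the
# voxel dimension, multi-run stability selection, and z-scoring of maps.
#
# Spatial convention: the T timepoints are the channels and the V voxels the
# samples, so a subject's data X (T x V) is modelled as X = M S with S
# (N x V) the independent spatial maps and M (T x N) their time courses.

# Eigenvalues of the temporal (T x T) covariance of the voxel-mean-removed
# data, sorted decreasing.  Shared by the MDL criterion and the whitening step.
temporal_eig <- function(data) {
  Xc <- sweep(data, 2, colMeans(data))
  Xr <- Xc - rowMeans(Xc)
  C <- tcrossprod(Xr) / ncol(Xr)
  e <- eigen(C, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  list(values = e$values, vectors = e$vectors, Xr = Xr)
}

#' Estimate the number of independent components by MDL
#'
#' Evaluates the minimum-description-length criterion
#' `MDL(k) = -V (T-k) log(g_k / a_k) + k (2T - k) log(V) / 2`,
#' where `g_k` and `a_k` are the geometric and arithmetic means of the `T-k`
#' smallest eigenvalues of the temporal covariance of the (voxel-mean-removed)
#' data, and returns the minimizing `k`.  This is the standard information
#' criterion used to pick the ICA model order in fMRI.
#'
#' @param subject a `subject_matrix`.
#' @param max_order largest order considered; must be below `min(T, V)`.
#' @return The estimated order (integer).
#' @export
estimate_order_mdl <- function(subject, max_order = 30L) {
  T <- subject$t_points
  V <- ncol(subject$data)
  if (!is_count(max_order) || max_order >= min(T, V))
    vfc_error("voxelfc_parameter_error", "max_order must be a positive integer below min(T, V)")
  ev <- temporal_eig(subject$data)$values
  if (any(!is.finite(ev)))
    vfc_error("voxelfc_numerical_error", "non-finite covariance eigenvalues")
  crit <- mdl_curve(ev, V, max_order)
  which.min(crit)
}

# MDL(k) for k = 1..max_order given decreasing eigenvalues of the T x T
# temporal covariance. Zero eigenvalues are floored so the log is defined.
mdl_curve <- function(ev, V, max_order) {
  T <- length(ev)
  ev <- pmax(ev, .Machine$double.eps)
  vapply(seq_len(max_order), function(k) {
    tail_ev <- ev[(k + 1):T]
    g <- exp(mean(log(tail_ev)))
    a <- mean(tail_ev)
    -V * (T - k) * log(g / a) + 0.5 * k * (2 * T - k) * log(V)
  }, numeric(1))
}

sym_decorrelate <- function(W) {
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(s$values, .Machine$double.eps)
  s$vectors %*% diag(1 / sqrt(vals), nrow = length(vals)) %*% t(s$vectors) %*% W
}

#' Fixed-point spatial ICA of one subject
#'
#' PCA-whitens the data to `n_components` temporal dimensions and runs
#' symmetric fixed-point ICA (tanh contrast) on the voxel dimension.  The run
#' is deterministic given `seed`; components are returned in decreasing order
#' of the variance explained by their time course.  Component sign is
#' arbitrary, and downstream activity detection uses absolute values.
#'
#' @param subject a `subject_matrix`.
#' @param n_components model order, between 1 and `min(T, V)`.
#' @param seed RNG seed for the random orthogonal initialization.
#' @param tol convergence tolerance on the unmixing update.
#' @param max_iter maximum fixed-point iterations; non-convergence raises a
#'   warning carrying the iteration count and returns the best estimate.
#' @return An object of class `ica_decomposition` with `spatial_maps`
#'   (N x V, rows zero-mean unit-variance over voxels), `mixing` (T x N),
#'   `n_components`, `seed` and optional `stability_index`.
#' @export
run_spatial_ica <- function(subject, n_components, seed = 1L,
                            tol = 1e-4, max_iter = 1000L) {
  T <- subject$t_points
  V <- ncol(subject$data)
  k <- n_components
  if (!is_count(k) || k > min(T, V))
    vfc_error("voxelfc_parameter_error", "n_components must lie in 1..min(T, V)")
  te <- temporal_eig(subject$data)
  vals <- te$values[seq_len(k)]
  if (any(vals <= .Machine$double.eps * te$values[1]))
    vals <- pmax(vals, .Machine$double.eps * max(te$values[1], 1))
  Kw <- diag(1 / sqrt(vals), nrow = k) %*% t(te$vectors[, seq_len(k), drop = FALSE])
  Z <- Kw %*% te$Xr                       # k x V, rows zero-mean, ZZ'/V = I
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    WX <- W %*% Z
    G <- tanh(WX)
    W1 <- tcrossprod(G, Z) / V - diag(rowMeans(1 - G^2), nrow = k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
    if (iter >= max_iter) {
      vfc_warn("voxelfc_convergence_warning",
               sprintf("ICA did not converge in %d iterations (delta = %.3g); returning best estimate",
                       iter, delta))
      break
    }
  }
  S <- W %*% Z                            # k x V, rows zero-mean unit-variance
  Xc <- sweep(subject$data, 2, colMeans(subject$data))
  M <- tcrossprod(Xc, S) / V              # T x k time courses
  ord <- order(colSums(M^2), decreasing = TRUE)
  new_ica_decomposition(subject$subject_id, S[ord, , drop = FALSE],
                        M[, ord, drop = FALSE], seed)
}

new_ica_decomposition <- function(subject_id, S, M, seed, stability_index = NULL) {
  structure(list(subject_id = subject_id, n_components = nrow(S),
                 spatial_maps = S, mixing = M, seed = seed,
                 stability_index = stability_index),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("ica_decomposition '%s': %d components x %d voxels\n",
              x$subject_id, x$n_components, ncol(x$spatial_maps)))
  if (!is.null(x$stability_index))
    cat("  stability:", paste(sprintf("%.2f", x$stability_index), collapse = " "), "\n")
  invisible(x)
}

#' Multi-run ICA stability selection
#'
#' Runs ICA `n_runs` times with varying random initialization (and, when
#' `bootstrap = TRUE`, timepoint resampling with replacement), pools all
#' spatial maps, clusters them by average-linkage agglomeration of the
#' dissimilarity `1 - |r|`, and returns each cluster's centrotype (the member
#' with the largest summed within-cluster |r|).  The per-component stability
#' index is the mean within-cluster |r| minus the mean |r| to all other
#' clusters, so reproducible components score near 1.  With `n_runs = 1` this
#' degrades to a single plain ICA run with no stability index.
#'
#' @param subject a `subject_matrix`.
#' @param n_components model order.
#' @param n_runs number of ICA runs (default 20).
#' @param base_seed seed of the first run; run r uses `base_seed + r - 1`.
#' @param bootstrap resample timepoints with replacement in runs 2..n_runs.
#' @return An `ica_decomposition` with `stability_index`.
#' @export
stability_select <- function(subject, n_components, n_runs = 20L,
                             base_seed = 1L, bootstrap = TRUE) {
  if (!is_count(n_runs))
    vfc_error("voxelfc_parameter_error", "n_runs must be a positive integer")
  if (n_runs == 1L)
    return(run_spatial_ica(subject, n_components, seed = base_seed))
  maps <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r - 1L
    subj_r <- subject
    if (bootstrap && r > 1L) {
      rows <- with_seed(seed_r + 500000L,
                        sample.int(subject$t_points, subject$t_points, replace = TRUE))
      subj_r$data <- subject$data[rows, , drop = FALSE]
      subj_r$t_points <- length(rows)
    }
    dec <- run_spatial_ica(subj_r, n_components, seed = seed_r)
    maps[[r]] <- dec$spatial_maps
  }
  P <- do.call(rbind, maps)
  if (nrow(P) < n_components)
    vfc_error("voxelfc_selection_error", "fewer pooled components than requested clusters")
  R <- abs(cor(t(P)))
  cl <- cutree(hclust(as.dist(1 - R), method = "average"), k = n_components)
  centro <- integer(n_components)
  stab <- numeric(n_components)
  for (c in seq_len(n_components)) {
    members <- which(cl == c)
    if (length(members) == 1L) {
      centro[c] <- members
      stab[c] <- 1 - mean(R[members, -members])
      next
    }
    Rin <- R[members, members, drop = FALSE]
    centro[c] <- members[which.max(rowSums(Rin))]
    within <- mean(Rin[upper.tri(Rin)])
    between <- mean(R[members, setdiff(seq_len(nrow(R)), members), drop = FALSE])
    stab[c] <- within - between
  }
  S <- P[centro, , drop = FALSE]
  S <- S - rowMeans(S)
  S <- S / sqrt(rowMeans(S^2))
  Xc <- sweep(subject$data, 2, colMeans(subject$data))
  M <- t(solve(tcrossprod(S) / ncol(S), S %*% t(Xc) / ncol(S)))  # least-squares time courses
  ord <- order(colSums(M^2), decreasing = TRUE)
  new_ica_decomposition(subject$subject_id, S[ord, , drop = FALSE],
                        M[, ord, drop = FALSE], base_seed, stab[ord])
}

#' Z-score the spatial maps of a decomposition
#'
#' Centers and scales each spatial map to zero mean and unit standard
#' deviation over in-mask voxels (population denominator), the scale on which
#' the activity threshold is applied.
#'
#' @param decomp an `ica_decomposition`.
#' @return An object of class `zmaps` with field `z` (N x V).
#' @export
zscore_maps <- function(decomp) {
  S <- decomp$spatial_maps
  mu <- rowMeans(S)
  Sc <- S - mu
  sdv <- sqrt(rowMeans(Sc^2))
  bad <- which(sdv <= 0)
  if (length(bad))
    vfc_error("voxelfc_degenerate_error",
              sprintf("constant spatial map in component(s): %s",
                      paste(bad, collapse = ", ")))
  structure(list(subject_id = decomp$subject_id, z = Sc / sdv),
            class = "zmaps")
}

#' @export
print.zmaps <- function(x, ...) {
  cat(sprintf("zmaps '%s': %d components x %d voxels\n",
              x$subject_id, nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Export a decomposition as NIfTI maps plus TSV tables
#'
#' Writes the spatial maps as a 4D NIfTI volume (one volume per component,
#' zeros outside the mask), and the mixing matrix and stability indices as
#' TSV files alongside.
#'
#' @param decomp an `ica_decomposition`.
#' @param mask the subject's [brain_mask()].
#' @param prefix output path prefix; writes `<prefix>_maps.nii.gz`,
#'   `<prefix>_mixing.tsv` and, when available, `<prefix>_stability.tsv`.
#' @export
write_decomposition <- function(decomp, mask, prefix) {
  full <- matrix(0, nrow = decomp$n_components, ncol = prod(mask$grid$shape))
  full[, mask_linear_indices(mask)] <- decomp$spatial_maps
  arr <- array(t(full), dim = c(mask$grid$shape, decomp$n_components))
  write_nifti_grid(arr, mask$grid, paste0(prefix, "_maps.nii.gz"))
  write.table(decomp$mixing, paste0(prefix, "_mixing.tsv"),
              sep = "\t", row.names = FALSE, col.names = paste0("IC", seq_len(decomp$n_components)))
  if (!is.null(decomp$stability_index))
    write.table(data.frame(component = seq_along(decomp$stability_index),
                           stability = decomp$stability_index),
                paste0(prefix, "_stability.tsv"), sep = "\t", row.names = FALSE)
  invisible(prefix)
}
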