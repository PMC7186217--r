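# Edge-wise two-sample statistics with FDR correction and selection of the
# differential functional connections used as classification features.

#' Edge-wise two-sample t-test between cohorts
#'
#' Two-sided Student t-test with pooled variance per edge (df = K1 + K2 - 2),
#' vectorized over all edges.  Degenerate edges with zero pooled variance get
#' t = 0, p = 1 when the group means agree and p = 0 (flagged) when they do
#' not.
#'
#' @param fc1,fc2 `group_fc_matrix` objects (or plain subject x edge
#'   matrices) with equal edge counts and at least 2 subjects each.
#' @param welch use Welch's unequal-variance t instead of the pooled test.
#' @return A data.frame with columns `t`, `df`, `p` and `degenerate`.
#' @export
edgewise_ttest <- function(fc1, fc2, welch = FALSE) {
  X1 <- if (inherits(fc1, "group_fc_matrix")) fc1$matrix else as.matrix(fc1)
  X2 <- if (inherits(fc2, "group_fc_matrix")) fc2$matrix else as.matrix(fc2)
  if (ncol(X1) != ncol(X2))
    vfc_error("voxelfc_parameter_error", "edge counts differ between cohorts")
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (n1 < 2L || n2 < 2L)
    vfc_error("voxelfc_sample_size_error", "each cohort needs at least 2 subjects")
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2, m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1),
                        .Machine$double.xmin))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, ncol(X1))
  }
  diff <- m1 - m2
  degen <- se2 <= 0
  tt <- ifelse(degen, ifelse(diff == 0, 0, sign(diff) * Inf), diff / sqrt(se2))
  p <- ifelse(degen, ifelse(diff == 0, 1, 0), 2 * pt(-abs(tt), df))
  data.frame(t = tt, df = df, p = p, degenerate = degen & diff != 0)
}

#' FDR adjustment of p-values
#'
#' Benjamini-Hochberg step-up adjustment over the full edge family: sorted
#' ascending, `adj_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and mapped
#' back to the original order.
#'
#' @param p_raw vector of p-values in \[0, 1\].
#' @param method adjustment procedure (`"BH"` default; any
#'   [stats::p.adjust()] method name is accepted).
#' @return Adjusted p-values in original order.
#' @export
fdr_adjust <- function(p_raw, method = "BH") {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1))
    vfc_error("voxelfc_parameter_error", "p-values must lie in [0, 1]")
  p.adjust(p_raw, method = method)
}

#' Select differential functional connections
#'
#' Runs the edge-wise t-test, applies FDR correction, and selects the edges
#' whose adjusted p-value is strictly below `alpha`; the two cohorts' feature
#' matrices restricted to those edges are the classification inputs.  An
#' empty selection is a typed outcome (`empty = TRUE`), not an error, so
#' callers can fall back to the full connectivity profile.
#'
#' @param fc1,fc2 `group_fc_matrix` objects (or matrices).
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @param method FDR procedure, see [fdr_adjust()].
#' @param welch use Welch's t-test.
#' @param fisher_z apply the Fisher z-transform `atanh(r)` before testing
#'   (selection only; the exported feature values stay on the r scale).
#' @return An object of class `dfc_result` with `t_stats`, `p_raw`, `p_adj`,
#'   `dfci` (increasing selected edge indices), `alpha`, `dfc1`, `dfc2`,
#'   `empty` and the edge index when available.
#' @export
select_dfc <- function(fc1, fc2, alpha = 0.05, method = "BH",
                       welch = FALSE, fisher_z = FALSE) {
  X1 <- if (inherits(fc1, "group_fc_matrix")) fc1$matrix else as.matrix(fc1)
  X2 <- if (inherits(fc2, "group_fc_matrix")) fc2$matrix else as.matrix(fc2)
  T1 <- X1; T2 <- X2
  if (fisher_z) {
    clamp <- function(x) atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
    T1 <- clamp(X1); T2 <- clamp(X2)
  }
  tests <- edgewise_ttest(T1, T2, welch = welch)
  p_adj <- fdr_adjust(tests$p, method = method)
  dfci <- which(p_adj < alpha)
  structure(list(t_stats = tests$t, df = tests$df, p_raw = tests$p,
                 p_adj = p_adj, dfci = dfci, alpha = alpha,
                 dfc1 = X1[, dfci, drop = FALSE],
                 dfc2 = X2[, dfci, drop = FALSE],
                 empty = length(dfci) == 0L,
                 edges = if (inherits(fc1, "group_fc_matrix")) fc1$edges),
            class = "dfc_result")
}

#' @export
print.dfc_result <- function(x, ...) {
  cat(sprintf("dfc_result: %d of %d edges selected at adjusted p < %g\n",
              length(x$dfci), length(x$p_raw), x$alpha))
  invisible(x)
}

#' Count selected edges per atlas region pair
#'
#' Maps each selected edge's two voxels to their atlas labels and counts
#' selected edges per unordered region pair; within-region edges appear as
#' same-region pairs.  Voxels with label 0 are counted under the pseudo-region
#' `"unlabeled"`.
#'
#' @param result a `dfc_result` produced from `group_fc_matrix` inputs.
#' @param cavl12 the `voxel_set` the edges were built over.
#' @param atlas an `atlas_labels` object on the mask grid.
#' @return A data.frame with columns `region1`, `region2`, `n_edges`.
#' @export
aggregate_dfc_by_region <- function(result, cavl12, atlas) {
  if (is.null(result$edges))
    vfc_error("voxelfc_parameter_error", "result carries no edge index")
  if (!all(atlas$grid$shape == cavl12$mask$grid$shape))
    vfc_error("voxelfc_spatial_error", "atlas grid does not match mask grid")
  if (!length(result$dfci))
    return(data.frame(region1 = character(0), region2 = character(0),
                      n_edges = integer(0)))
  lin <- mask_linear_indices(cavl12$mask)
  vp <- result$edges$voxel_pairs[, result$dfci, drop = FALSE]
  region_of <- function(vox) {
    l <- atlas$labels[lin[vox]]
    ifelse(l == 0L, "unlabeled", unname(atlas$region_names[as.character(l)]))
  }
  r1 <- region_of(vp[1, ]); r2 <- region_of(vp[2, ])
  key <- ifelse(r1 <= r2, paste(r1, r2, sep = "\r"), paste(r2, r1, sep = "\r"))
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(region1 = vapply(parts, `[`, character(1), 1),
             region2 = vapply(parts, `[`, character(1), 2),
             n_edges = as.integer(tab), row.names = NULL)
}

#' Export per-edge differential statistics as TSV
#'
#' @param result a `dfc_result` with an edge index.
#' @param path output TSV path.
#' @export
write_dfc_result <- function(result, path) {
  vp <- result$edges$voxel_pairs
  df <- data.frame(edge = seq_along(result$p_raw),
                   voxel_p = vp[1, ], voxel_q = vp[2, ],
                   t = result$t_stats, p_raw = result$p_raw,
                   p_adj = result$p_adj,
                   selected = seq_along(result$p_raw) %in% result$dfci)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
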