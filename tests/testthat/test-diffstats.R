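# Brute-force Benjamini-Hochberg step-up oracle: sort ascending, find the
# largest i with p_(i) <= (i/m) alpha, select those; adjusted values by the
# explicit min-over-tail formula.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- sapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))))
  adj <- numeric(m); adj[o] <- adj_sorted
  ok <- which(ps <= (seq_len(m) / m) * alpha)
  sel <- if (length(ok)) sort(o[seq_len(max(ok))]) else integer(0)
  list(adjusted = adj, selected = sel)
}

test_that("the pooled two-sample t matches hand computation and t.test", {
  a <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1)
  b <- matrix(c(0.5, 0.6, 0.7, 0.8), ncol = 1)
  r <- edgewise_ttest(a, b)
  expect_equal(r$t, -4.3818, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p, 0.00466, tolerance = 1e-3)

  # swapping groups negates t, leaves p unchanged
  r2 <- edgewise_ttest(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # identical groups: t = 0, p = 1 at every edge
  x <- voxelfc:::with_seed(3, matrix(rnorm(40), 5, 8))
  r0 <- edgewise_ttest(x, x)
  expect_equal(r0$t, rep(0, 8))
  expect_equal(r0$p, rep(1, 8))

  # vectorized statistics agree with stats::t.test per edge to 1e-12
  X1 <- voxelfc:::with_seed(4, matrix(rnorm(60), 6, 10))
  X2 <- voxelfc:::with_seed(5, matrix(rnorm(80, mean = 0.3), 8, 10))
  rv <- edgewise_ttest(X1, X2)
  rw <- edgewise_ttest(X1, X2, welch = TRUE)
  for (e in 1:10) {
    tt <- t.test(X1[, e], X2[, e], var.equal = TRUE)
    expect_equal(rv$t[e], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(rv$p[e], tt$p.value, tolerance = 1e-12)
    tw <- t.test(X1[, e], X2[, e])
    expect_equal(rw$t[e], unname(tw$statistic), tolerance = 1e-12)
    expect_equal(rw$df[e], unname(tw$parameter), tolerance = 1e-9)
  }

  # zero pooled variance with unequal means is flagged degenerate with p = 0
  rd <- edgewise_ttest(matrix(1, 3, 1), matrix(2, 3, 1))
  expect_true(rd$degenerate)
  expect_equal(rd$p, 0)

  expect_error(edgewise_ttest(matrix(1, 1, 2), matrix(1, 3, 2)),
               class = "voxelfc_sample_size_error")
})

test_that("BH adjustment matches a brute-force step-up scan exactly", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  adj <- fdr_adjust(p)
  expect_identical(which(adj < 0.05), 1:4)
  expect_equal(adj, oracle_bh(p)$adjusted, tolerance = 1e-15)

  expect_equal(fdr_adjust(rep(1, 7)), rep(1, 7))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_error(fdr_adjust(c(0.1, 1.2)), class = "voxelfc_parameter_error")

  for (i in 1:100) {
    p <- voxelfc:::with_seed(900 + i, runif(sample(1:50, 1))^sample(1:3, 1))
    adj <- fdr_adjust(p)
    orc <- oracle_bh(p)
    expect_equal(adj, orc$adjusted, tolerance = 1e-12)
    # selection by adjusted p < alpha equals the step-up selection unless an
    # adjusted value sits exactly on the alpha boundary
    if (!any(abs(adj - 0.05) < 1e-12))
      expect_identical(which(adj < 0.05), orc$selected)
  }
})

test_that("differential selection keeps exactly the FDR-significant edges", {
  # planted mean shift at edge 1, null edges elsewhere
  hits <- 0; false_fracs <- numeric(0)
  for (i in 1:25) {
    X1 <- voxelfc:::with_seed(2000 + i, matrix(rnorm(30 * 100, sd = 0.2), 30, 100))
    X2 <- voxelfc:::with_seed(3000 + i, matrix(rnorm(30 * 100, sd = 0.2), 30, 100))
    X2[, 1] <- X2[, 1] + 0.5
    res <- select_dfc(X1, X2, alpha = 0.05)
    # independent oracle route: t.test p-values + p.adjust
    p_orc <- sapply(1:100, function(e)
      t.test(X1[, e], X2[, e], var.equal = TRUE)$p.value)
    expect_identical(res$dfci, which(p.adjust(p_orc, "BH") < 0.05))
    hits <- hits + (1 %in% res$dfci)
    false_fracs <- c(false_fracs, sum(res$dfci != 1) / 99)
  }
  expect_equal(hits, 25)
  expect_lte(mean(false_fracs), 0.05)

  # selected columns are pure selections of the input columns
  X1 <- voxelfc:::with_seed(1, matrix(rnorm(200, sd = 0.1), 10, 20))
  X2 <- voxelfc:::with_seed(2, matrix(rnorm(200, sd = 0.1), 10, 20) + 0.4)
  res <- select_dfc(X1, X2)
  expect_false(res$empty)
  expect_identical(res$dfc1, X1[, res$dfci, drop = FALSE])
  expect_identical(res$dfc2, X2[, res$dfci, drop = FALSE])
  expect_true(all(res$p_adj >= res$p_raw))

  # identical cohorts: typed empty outcome, not an error
  null_res <- select_dfc(X1, X1)
  expect_true(null_res$empty)
  expect_length(null_res$dfci, 0)
  expect_equal(ncol(null_res$dfc1), 0L)
})

test_that("selected edges aggregate into region-pair counts", {
  mask <- full_mask(c(3, 3, 3))
  at <- array(0L, c(3, 3, 3))
  at[1:6] <- 1L; at[7:12] <- 2L
  atlas <- load_atlas(at, mask)
  cavl <- voxel_set(c(1, 2, 8, 9, 14), mask, "joint_cavl12")
  subs1 <- lapply(1:3, function(i) noise_subject(12, c(3, 3, 3), seed = 50 + i,
                                                 id = paste0("a", i), group = "g1"))
  subs2 <- lapply(1:3, function(i) noise_subject(12, c(3, 3, 3), seed = 60 + i,
                                                 id = paste0("b", i), group = "g2"))
  fc1 <- stack_group_fc(subs1, cavl); fc2 <- stack_group_fc(subs2, cavl)
  res <- select_dfc(fc1, fc2)
  # force a known selection: edges (1,2), (1,3), (3,4), (2,5)
  res$dfci <- c(1L, 2L, 7L, 8L)
  counts <- aggregate_dfc_by_region(res, cavl, atlas)
  get <- function(r1, r2) {
    hit <- (counts$region1 == r1 & counts$region2 == r2) |
      (counts$region1 == r2 & counts$region2 == r1)
    if (any(hit)) counts$n_edges[hit] else 0L
  }
  # voxels 1,2 -> region 1; voxels 8,9 -> region 2; voxel 14 -> unlabeled;
  # selected edges pair voxels (1,2), (1,8), (2,14), (8,9)
  expect_equal(get("region_1", "region_1"), 1L)
  expect_equal(get("region_1", "region_2"), 1L)
  expect_equal(get("region_2", "region_2"), 1L)
  expect_equal(get("region_1", "unlabeled"), 1L)
  expect_equal(sum(counts$n_edges), 4L)

  empty <- res; empty$dfci <- integer(0)
  expect_equal(nrow(aggregate_dfc_by_region(empty, cavl, atlas)), 0L)
})
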