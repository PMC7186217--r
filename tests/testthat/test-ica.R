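# Independent MDL oracle: direct criterion evaluation from the eigenvalues of
# the temporal covariance of the voxel-mean-removed, row-centred data.
oracle_mdl <- function(data, max_order) {
  Xc <- sweep(data, 2, colMeans(data))
  Xc <- Xc - rowMeans(Xc)
  ev <- sort(eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, .Machine$double.eps)
  T <- length(ev); V <- ncol(data)
  crit <- sapply(seq_len(max_order), function(k) {
    tl <- ev[(k + 1):T]
    -V * (T - k) * log(exp(mean(log(tl))) / mean(tl)) + 0.5 * k * (2 * T - k) * log(V)
  })
  which.min(crit)
}

mixture_subject <- function(k, T, V, sigma, seed, shape = c(10L, 10L, 20L)) {
  stopifnot(prod(shape) == V)
  voxelfc:::with_seed(seed, {
    S <- matrix(0, k, V)
    for (j in seq_len(k)) {
      block <- ((j - 1) * floor(V / k) + 1):(j * floor(V / k))
      S[j, block] <- 1 + 0.2 * sin(seq_along(block) / 20)
    }
    M <- matrix(rnorm(T * k), T, k)
    subject_matrix("mix", "g", M %*% S + sigma * matrix(rnorm(T * V), T, V),
                   full_mask(shape))
  })
}

test_that("MDL recovers the planted model order and matches the direct criterion", {
  s3 <- mixture_subject(3, 40, 2000, 0.01, seed = 11)
  expect_equal(estimate_order_mdl(s3, 20), 3L)

  s1 <- voxelfc:::with_seed(21, {
    X <- matrix(rnorm(40), 40, 1) %*% matrix(runif(2000) + 0.5, 1, 2000) +
      1e-6 * matrix(rnorm(40 * 2000), 40, 2000)
    subject_matrix("r1", "g", X, full_mask(c(10, 10, 20)))
  })
  expect_equal(estimate_order_mdl(s1, 20), 1L)

  # pure white noise: near-monotone criterion keeps the order tiny
  noise_orders <- sapply(1:10, function(i)
    estimate_order_mdl(noise_subject(40, c(10, 10, 20), seed = 100 + i), 20))
  expect_true(all(noise_orders <= 3L))

  # oracle equivalence over randomized instances
  for (i in 1:20) {
    k <- sample(1:5, 1)
    s <- mixture_subject(k, 30 + sample(0:10, 1), 2000, runif(1, 0.005, 0.05),
                         seed = 400 + i)
    expect_equal(estimate_order_mdl(s, 15), oracle_mdl(s$data, 15))
  }

  expect_error(estimate_order_mdl(s3, 40), class = "voxelfc_parameter_error")
})

test_that("fixed-point ICA recovers planted non-Gaussian spatial sources", {
  V <- 2000
  truth <- voxelfc:::with_seed(5, rbind(
    rexp(V) - 1,
    sample(c(-1, 1), V, TRUE) * rexp(V),
    (runif(V) > 0.9) * 3))
  M <- voxelfc:::with_seed(6, matrix(rnorm(60 * 3), 60, 3))
  sub <- subject_matrix("s", "g", M %*% truth, full_mask(c(10, 10, 20)))
  dec <- run_spatial_ica(sub, 3, seed = 5)

  # greedy absolute-correlation assignment oracle
  cc <- abs(cor(t(dec$spatial_maps), t(truth)))
  assigned <- integer(3)
  for (step in 1:3) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    assigned[best[2]] <- best[1]
    cc[best[1], ] <- -1; cc[, best[2]] <- -1
  }
  for (j in 1:3)
    expect_gt(abs(cor(dec$spatial_maps[assigned[j], ], truth[j, ])), 0.99)

  # whitening: rows pairwise uncorrelated
  rc <- cor(t(dec$spatial_maps))
  expect_lt(max(abs(rc[upper.tri(rc)])), 1e-6)

  # determinism: bitwise identical rerun
  expect_identical(run_spatial_ica(sub, 3, seed = 5)$spatial_maps, dec$spatial_maps)

  # rank-1 identity up to scale/sign
  r1 <- voxelfc:::with_seed(7, {
    map <- runif(V)
    subject_matrix("r", "g", matrix(rnorm(30), 30, 1) %*% matrix(map, 1, V) +
                     1e-8 * matrix(rnorm(30 * V), 30, V), full_mask(c(10, 10, 20)))
  })
  d1 <- run_spatial_ica(r1, 1, seed = 2)
  truth_map <- r1$data[1, ] / max(r1$data[1, ])  # proportional to the map
  expect_gt(abs(cor(d1$spatial_maps[1, ], truth_map)), 0.999)
})

test_that("stability selection clusters repeated runs and degrades to plain ICA", {
  V <- 2000
  truth <- voxelfc:::with_seed(9, rbind(rexp(V) - 1,
                                        sample(c(-1, 1), V, TRUE) * rexp(V),
                                        (runif(V) > 0.9) * 3))
  M <- voxelfc:::with_seed(10, matrix(rnorm(60 * 3), 60, 3))
  sub <- subject_matrix("s", "g", M %*% truth, full_mask(c(10, 10, 20)))

  st <- stability_select(sub, 3, n_runs = 5, base_seed = 1, bootstrap = FALSE)
  expect_length(st$stability_index, 3)
  expect_true(all(st$stability_index > 0.95))

  # oracle: pooling the 5 runs and clustering at 1 - |r| gives 5 members each
  pooled <- do.call(rbind, lapply(1:5, function(r)
    run_spatial_ica(sub, 3, seed = r)$spatial_maps))
  cl <- cutree(hclust(as.dist(1 - abs(cor(t(pooled)))), method = "average"), k = 3)
  expect_true(all(table(cl) == 5))

  # n_runs = 1 degrades to the plain run
  plain <- run_spatial_ica(sub, 3, seed = 1)
  one <- stability_select(sub, 3, n_runs = 1, base_seed = 1)
  expect_identical(one$spatial_maps, plain$spatial_maps)
  expect_null(one$stability_index)

  expect_error(stability_select(sub, 100, n_runs = 2, base_seed = 1),
               class = "voxelfc_parameter_error")
})

test_that("z-scoring maps is exact, idempotent and rejects constant maps", {
  d <- voxelfc:::new_ica_decomposition("s", rbind(c(1, 2, 3, 4)), matrix(1, 1, 1), 1L)
  z <- zscore_maps(d)
  expect_equal(z$z[1, ], c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  z2 <- zscore_maps(voxelfc:::new_ica_decomposition("s", z$z, matrix(1, 1, 1), 1L))
  expect_equal(z2$z, z$z, tolerance = 1e-12)

  dc <- voxelfc:::new_ica_decomposition("s", rbind(c(2, 2, 2, 2)), matrix(1, 1, 1), 1L)
  expect_error(zscore_maps(dc), class = "voxelfc_degenerate_error")
})

test_that("activity detection is invariant to component sign flips and permutations", {
  z <- voxelfc:::with_seed(31, matrix(rnorm(4 * 64, sd = 1.2), 4, 64))
  mask <- full_mask(c(4, 4, 4))
  base <- subject_active_voxels(zmaps_from(z), mask, theta = 1.5)
  flipped <- zmaps_from(diag(c(-1, 1, -1, 1)) %*% z[c(3, 1, 4, 2), ])
  expect_identical(subject_active_voxels(flipped, mask, theta = 1.5)$indices,
                   base$indices)
})
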