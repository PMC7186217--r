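test_that("activity voxels are the union over components of |z| >= theta", {
  mask <- full_mask(c(2, 2, 1))
  one <- zmaps_from(rbind(c(0.0, 2.5, -3.0, 1.9)))
  expect_equal(subject_active_voxels(one, mask, theta = 2)$indices, c(2L, 3L))
  # boundary is inclusive
  expect_equal(subject_active_voxels(zmaps_from(rbind(c(2, 0, 0, 0))), mask, 2)$indices, 1L)

  two <- zmaps_from(rbind(c(2.1, 0, 0, 0), c(0, -2.2, 0, 0)))
  expect_equal(subject_active_voxels(two, mask, theta = 2)$indices, c(1L, 2L))

  expect_warning(subject_active_voxels(zmaps_from(rbind(rep(0, 4))), mask, 2),
                 class = "voxelfc_empty_warning")
})

test_that("activity sets shrink monotonically as theta grows", {
  mask <- full_mask(c(4, 4, 4))
  for (i in 1:10) {
    z <- voxelfc:::with_seed(700 + i, matrix(rnorm(3 * 64, sd = 1.5), 3, 64))
    thetas <- sort(runif(4, 0.5, 3))
    sets <- lapply(thetas, function(th)
      suppressWarnings(subject_active_voxels(zmaps_from(z), mask, th))$indices)
    for (j in 2:4) expect_true(all(sets[[j]] %in% sets[[j - 1]]))
  }
})

test_that("cohort and joint intersections obey set semantics and the containment chain", {
  mask <- full_mask(c(3, 3, 3))
  vs <- function(i, prov = "subject_avl") voxel_set(i, mask, prov)
  expect_equal(group_common_voxels(list(vs(1:3), vs(2:4)))$indices, 2:3)
  expect_equal(group_common_voxels(list(vs(c(2, 5)), vs(c(2, 5)), vs(c(2, 5))))$indices,
               c(2L, 5L))
  expect_warning(group_common_voxels(list(vs(1:2), vs(3:4))),
                 class = "voxelfc_empty_warning")

  c1 <- voxel_set(c(2, 3, 7), mask, "group_cavl")
  c2 <- voxel_set(c(3, 7, 9), mask, "group_cavl")
  j <- joint_common_voxels(c1, c2)
  expect_equal(j$indices, c(3L, 7L))
  expect_equal(j$n, 2L)
  expect_identical(joint_common_voxels(c1, c1)$indices, c1$indices)
  expect_error(joint_common_voxels(voxel_set(1, mask, "group_cavl"),
                                   voxel_set(2, mask, "group_cavl")),
               class = "voxelfc_degenerate_error")
  expect_error(joint_common_voxels(vs(1:3), c2), class = "voxelfc_parameter_error")

  # order independence / associativity over the subject list
  sets <- lapply(1:5, function(i) vs(sort(sample(1:20, 12))))
  a <- group_common_voxels(sets)$indices
  b <- group_common_voxels(rev(sets))$indices
  expect_identical(a, b)

  # containment chain: joint set inside each cohort set inside each AVL
  avl1 <- list(vs(1:15), vs(5:20)); avl2 <- list(vs(8:25), vs(3:18))
  g1 <- group_common_voxels(avl1); g2 <- group_common_voxels(avl2)
  j12 <- joint_common_voxels(g1, g2)
  expect_true(all(j12$indices %in% g1$indices))
  expect_true(all(j12$indices %in% g2$indices))
  for (a1 in avl1) expect_true(all(g1$indices %in% a1$indices))
  for (a2 in avl2) expect_true(all(g2$indices %in% a2$indices))
})

test_that("region summaries apply the strict count and fraction filters", {
  shape <- c(12, 12, 12)
  mask <- brain_mask(volume_grid(shape), rep(TRUE, prod(shape)))
  at <- array(0L, shape)
  at[1:100] <- 1L     # region 1: 100 voxels
  at[101:1100] <- 2L  # region 2: 1000 voxels
  at[1101:1111] <- 3L # region 3: 11 voxels
  atlas <- load_atlas(at, mask)

  # region 1: 11 of 100 active -> kept (11 > 10 and 0.11 > 0.01)
  # region 2: 10 of 1000 active -> excluded (strict "> 10" fails)
  # region 3: 11 of 11 active -> kept
  active <- voxel_set(c(1:11, 101:110, 1101:1111), mask, "group_cavl")
  summ <- summarize_regions(active, atlas)
  expect_setequal(summ$label, c(1L, 3L))
  expect_equal(summ$voxel_number[summ$label == 1], 11L)
  expect_equal(summ$voxel_ratio[summ$label == 1], 0.11)

  # exactly 10 active: excluded by "more than 10"
  ten <- voxel_set(1:10, mask, "group_cavl")
  expect_equal(nrow(summarize_regions(ten, atlas)), 0L)

  # large region, small fraction: 12 of 5000 fails the 1% rule
  big <- array(0L, shape); big[1:1500] <- 1L
  atlas_big <- load_atlas(big, mask)
  twelve <- voxel_set(1:12, mask, "group_cavl")
  expect_equal(nrow(summarize_regions(twelve, atlas_big)), 0L)

  # centroid is the world-mm mean of the active voxels
  expect_equal(unlist(summ[summ$label == 3, c("x_mm", "y_mm", "z_mm")], use.names = FALSE),
               colMeans(voxelfc:::grid_world_coords(mask$grid, 1101:1111)))
})

test_that("atlas restriction drops unlabeled voxels and keeps provenance", {
  mask <- full_mask(c(3, 3, 3))
  at <- array(0L, c(3, 3, 3)); at[c(2, 3, 5)] <- 1L
  atlas <- load_atlas(at, mask)
  v <- voxel_set(c(1, 2, 5, 9), mask, "joint_cavl12")
  r <- restrict_to_atlas(v, atlas)
  expect_equal(r$indices, c(2L, 5L))
  expect_equal(r$provenance, "joint_cavl12")
})

test_that("voxel sets round-trip through their text representation", {
  mask <- full_mask(c(3, 3, 3))
  v <- voxel_set(c(3, 8, 20), mask, "group_cavl")
  pre <- tempfile()
  write_voxel_set(v, pre)
  v2 <- read_voxel_set(paste0(pre, ".txt"), mask, "group_cavl")
  expect_identical(v2$indices, v$indices)
  unlink(paste0(pre, c(".txt", ".nii.gz")))
})
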