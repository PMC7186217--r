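# Shared fixture builders. All data are generated in code at test time.

full_mask <- function(shape = c(4L, 4L, 4L)) {
  brain_mask(volume_grid(shape), rep(TRUE, prod(shape)))
}

# Subject with iid noise series on a full mask.
noise_subject <- function(t_points = 20L, shape = c(4L, 4L, 4L), seed = 1L,
                          id = "s1", group = "g1") {
  mask <- full_mask(shape)
  data <- voxelfc:::with_seed(seed,
    matrix(rnorm(t_points * prod(shape)), t_points, prod(shape)))
  subject_matrix(id, group, data, mask)
}

# zmaps object built directly from a component-by-voxel matrix of z values.
zmaps_from <- function(z, id = "s1") {
  structure(list(subject_id = id, z = as.matrix(z)), class = "zmaps")
}

# Small, fast synthetic configuration used by unit tests (the full-size
# default config is exercised by the acceptance suite).
small_config <- function(seed = 1L, n_diff_edges = 4L, ...) {
  synth_config(grid_shape = c(8L, 8L, 8L), t_points = 60L, n_sources = 2L,
               radius = 1.5, n_subjects = c(6L, 6L), n_diff_edges = n_diff_edges,
               seed = seed, ...)
}

small_pipeline_config <- function(seed = 1L, n_runs = 20L, ...) {
  pipeline_config(ica_runs = 1L, seed = seed,
                  protocol = eval_protocol(n_runs = n_runs, base_seed = seed),
                  ...)
}
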