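# Volume input/output, brain-mask construction and the canonical voxel order.
#
# Every downstream stage indexes voxels by their position in the in-mask
# ordering of a shared brain mask.  The linearization is the native R array
# order: x fastest, then y, then z.  In-mask positions are 1-based.

#' Spatial frame of a volume
#'
#' A `volume_grid` records the 3D array shape and the voxel-to-world affine
#' (4x4, mapping 0-based voxel indices to mm coordinates).  All volumes,
#' masks and atlases in one analysis must share a grid.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix; defaults to `spacing_mm`-isotropic voxels
#'   centred on the grid.
#' @param spacing_mm isotropic voxel size used when `affine` is missing.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine = NULL, spacing_mm = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    vfc_error("voxelfc_parameter_error", "grid shape must be 3 positive integers")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing_mm
    affine[1:3, 4] <- -spacing_mm * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    vfc_error("voxelfc_parameter_error", "affine must be an invertible 4x4 matrix")
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Brain mask over a volume grid
#'
#' @param grid a [volume_grid()].
#' @param flags logical vector of length `prod(grid$shape)` in canonical
#'   (x-fastest) order; `TRUE` marks in-mask voxels.
#' @return An object of class `brain_mask` with fields `grid`, `flags` and
#'   `n_voxels` (the number of in-mask voxels, the V of the pipeline).
#' @export
brain_mask <- function(grid, flags) {
  flags <- as.logical(flags)
  if (length(flags) != prod(grid$shape))
    vfc_error("voxelfc_spatial_error", "mask flags do not match grid size")
  n <- sum(flags)
  if (n < 2L)
    vfc_error("voxelfc_degenerate_error", "brain mask has fewer than 2 voxels")
  structure(list(grid = grid, flags = flags, n_voxels = n), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask:", x$n_voxels, "of", prod(x$grid$shape), "voxels in mask\n")
  invisible(x)
}

# Grid linear indices (1-based, x fastest) of in-mask voxels, in canonical order.
mask_linear_indices <- function(mask) which(mask$flags)

# World-mm coordinates (rows) of 1-based grid linear indices.
grid_world_coords <- function(grid, lin_idx) {
  ijk <- arrayInd(lin_idx, grid$shape) - 1L   # 0-based voxel indices
  xyz1 <- cbind(ijk, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

# Accept a file path, a 4D array, or a T x prod(shape) matrix and return the
# T x prod(shape) matrix of full-grid time series (rows = timepoints).
as_grid_series <- function(x, shape) {
  if (is.character(x)) {
    x <- as.array(RNifti::readNifti(x))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    if (!all(dim(x)[1:3] == shape))
      vfc_error("voxelfc_spatial_error", sprintf(
        "volume spatial shape (%s) does not match mask grid (%s)",
        paste(dim(x)[1:3], collapse = ","), paste(shape, collapse = ",")))
    return(t(matrix(x, nrow = prod(shape))))
  }
  if (is.matrix(x)) {
    if (ncol(x) != prod(shape))
      vfc_error("voxelfc_spatial_error", "series matrix does not match mask grid")
    return(x)
  }
  vfc_error("voxelfc_format_error", "volume must be a NIfTI path, 4D array or T x V matrix")
}

#' Load a subject's 4D volume as an in-mask time-by-voxel matrix
#'
#' Extracts the time series of every in-mask voxel in canonical order, so that
#' column j refers to the same spatial voxel in every subject sharing the mask.
#'
#' @param x path to a 4D NIfTI-1 file (.nii or .nii.gz), a 4D array, or a
#'   T x prod(shape) matrix.
#' @param mask a [brain_mask()].
#' @param subject_id subject identifier.
#' @param group_label cohort label.
#' @return An object of class `subject_matrix` with fields `subject_id`,
#'   `group_label`, `data` (T x V matrix), `t_points` and `mask`.
#' @export
load_subject_volume <- function(x, mask, subject_id = "subject", group_label = "group") {
  series <- as_grid_series(x, mask$grid$shape)
  if (nrow(series) < 2L)
    vfc_error("voxelfc_degenerate_error", "volume has fewer than 2 timepoints")
  data <- series[, mask_linear_indices(mask), drop = FALSE]
  bad <- which(!apply(is.finite(data), 2, all))
  if (length(bad))
    vfc_error("voxelfc_data_quality_error", sprintf(
      "non-finite values inside mask at in-mask voxel(s): %s",
      paste(head(bad, 10L), collapse = ", ")))
  subject_matrix(subject_id, group_label, data, mask)
}

#' Construct a subject_matrix from an in-mask data matrix
#'
#' @param subject_id subject identifier.
#' @param group_label cohort label.
#' @param data T x V numeric matrix, columns in canonical in-mask order.
#' @param mask the shared [brain_mask()].
#' @export
subject_matrix <- function(subject_id, group_label, data, mask) {
  data <- as.matrix(data)
  if (ncol(data) != mask$n_voxels)
    vfc_error("voxelfc_spatial_error", "data columns do not match mask voxel count")
  structure(list(subject_id = as.character(subject_id),
                 group_label = as.character(group_label),
                 data = data, t_points = nrow(data), mask = mask),
            class = "subject_matrix")
}

#' @export
print.subject_matrix <- function(x, ...) {
  cat(sprintf("subject_matrix '%s' (%s): %d timepoints x %d voxels\n",
              x$subject_id, x$group_label, x$t_points, ncol(x$data)))
  invisible(x)
}

#' Build the shared brain mask from the data
#'
#' Without an explicit mask, a voxel is in-mask iff its time series has
#' strictly positive variance in every listed volume.  With an explicit mask,
#' its nonzero voxels are kept minus any voxel that is constant over time in
#' some volume.  This guarantees Pearson correlation is defined at every
#' in-mask voxel of every subject.
#'
#' @param volumes list of volumes (paths, 4D arrays or T x V matrices).
#' @param grid the shared [volume_grid()].
#' @param explicit_mask optional path or 3D array of nonzero-inside mask values.
#' @return A [brain_mask()].
#' @export
build_group_mask <- function(volumes, grid, explicit_mask = NULL) {
  if (length(volumes) < 1L)
    vfc_error("voxelfc_parameter_error", "need at least one volume")
  keep <- rep(TRUE, prod(grid$shape))
  if (!is.null(explicit_mask)) {
    m <- explicit_mask
    if (is.character(m)) m <- as.array(RNifti::readNifti(m))
    m <- as.array(m)
    if (!all(dim(m)[1:3] == grid$shape))
      vfc_error("voxelfc_spatial_error", "explicit mask shape does not match grid")
    keep <- as.vector(m != 0)
  }
  for (v in volumes) {
    series <- as_grid_series(v, grid$shape)
    cm <- colMeans(series)
    ss <- colSums(series^2) - nrow(series) * cm^2
    keep <- keep & (ss > 0)
  }
  if (!any(keep))
    vfc_error("voxelfc_degenerate_error",
              "mask is empty: no voxel varies over time in every volume")
  brain_mask(grid, keep)
}

#' Write an in-mask matrix back into its grid as a 4D NIfTI volume
#'
#' Out-of-mask voxels are written as zero.  Values are stored as 64-bit
#' floats, so a reload through [load_subject_volume()] reproduces the matrix
#' bitwise.
#'
#' @param subject a `subject_matrix`.
#' @param path output file (.nii or .nii.gz).
#' @export
write_subject_volume <- function(subject, path) {
  mask <- subject$mask
  full <- matrix(0, nrow = subject$t_points, ncol = prod(mask$grid$shape))
  full[, mask_linear_indices(mask)] <- subject$data
  arr <- array(t(full), dim = c(mask$grid$shape, subject$t_points))
  write_nifti_grid(arr, mask$grid, path)
  invisible(path)
}

write_nifti_grid <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Load an integer-labelled atlas volume
#'
#' @param x path to a 3D NIfTI-1 label volume or a 3D integer array on the
#'   mask grid.  Label 0 means unlabeled.
#' @param mask the shared [brain_mask()].
#' @param names optional data.frame with columns `label` and `name` (or a path
#'   to a two-column TSV); missing labels are auto-named `region_<label>`.
#' @return An object of class `atlas_labels` with per-grid-voxel labels,
#'   region names and in-mask region sizes.
#' @export
load_atlas <- function(x, mask, names = NULL) {
  if (is.character(x)) x <- as.array(RNifti::readNifti(x))
  x <- as.array(x)
  if (length(dim(x)) == 4L && dim(x)[4] == 1L) x <- array(x, dim = dim(x)[1:3])
  if (length(dim(x)) != 3L || !all(dim(x) == mask$grid$shape))
    vfc_error("voxelfc_spatial_error", "atlas shape does not match mask grid")
  lab <- as.vector(x)
  if (max(abs(lab - round(lab))) > 1e-6 || any(lab < 0))
    vfc_error("voxelfc_format_error", "atlas labels must be nonnegative integers")
  lab <- as.integer(round(lab))
  inmask <- lab[mask_linear_indices(mask)]
  sizes <- table(inmask[inmask > 0L])
  labels_present <- as.integer(names(sizes))
  if (is.character(names)) names <- read.delim(names, header = TRUE)
  name_map <- setNames(paste0("region_", labels_present), labels_present)
  if (!is.null(names)) {
    idx <- match(labels_present, names$label)
    hit <- !is.na(idx)
    name_map[hit] <- as.character(names$name[idx[hit]])
  }
  structure(list(grid = mask$grid, labels = lab,
                 region_names = name_map,
                 region_sizes = setNames(as.integer(sizes), labels_present)),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  cat("atlas_labels:", length(x$region_sizes), "regions in mask\n")
  invisible(x)
}

#' Linear detrend and zero-phase band-pass filter
#'
#' Optional light temporal preprocessing: each voxel's series is linearly
#' detrended and then band-pass filtered with an ideal (frequency-domain
#' rectangle) zero-phase filter, the convention common in resting-state
#' pipelines.  Inputs are otherwise assumed fully preprocessed upstream.
#'
#' @param subject a `subject_matrix`.
#' @param low_hz,high_hz pass-band edges in Hz; `0 <= low_hz < high_hz` and
#'   `high_hz` below the Nyquist frequency `0.5 / tr_seconds`.
#' @param tr_seconds repetition time in seconds.
#' @return A `subject_matrix` of the same shape.
#' @export
bandpass_detrend <- function(subject, low_hz = 0.01, high_hz = 0.08, tr_seconds = 3) {
  nyq <- 0.5 / tr_seconds
  if (!is_number(low_hz) || !is_number(high_hz) || low_hz < 0 || low_hz >= high_hz)
    vfc_error("voxelfc_parameter_error", "need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    vfc_error("voxelfc_parameter_error",
              sprintf("high_hz (%g) must be below Nyquist (%g Hz)", high_hz, nyq))
  X <- subject$data
  tt <- seq_len(nrow(X))
  qrd <- qr(cbind(1, tt))
  X <- qr.resid(qrd, X)
  X <- ideal_bandpass(X, low_hz, high_hz, tr_seconds)
  out <- subject
  out$data <- X
  out
}

# Ideal frequency-domain band-pass of the columns of X (T x V).
ideal_bandpass <- function(X, low_hz, high_hz, tr_seconds) {
  T <- nrow(X)
  bin <- 0:(T - 1)
  freq <- pmin(bin, T - bin) / (T * tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz
  Fx <- mvfft(X)
  Fx[!keep, ] <- 0
  Re(mvfft(Fx, inverse = TRUE)) / T
}
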