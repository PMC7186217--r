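# End-to-end orchestration: mask -> per-subject ICA -> activity voxels ->
# cohort intersections -> FC features -> differential selection -> paired
# SVM evaluation, plus the threshold sweep.

#' Pipeline configuration
#'
#' Defaults reproduce the protocol shape of the reference analysis: activity
#' threshold theta = 2, significance level 0.05, SVM with C = 1 and linear
#' kernel, 80/20 stratified hold-out repeated 1000 times, 20-run ICA
#' stability selection with MDL-estimated order.
#'
#' @param theta activity threshold on the z-scored maps (default 2).
#' @param alpha significance level for the FDR-corrected selection (default 0.05).
#' @param ica_order `"mdl"` (estimate per subject) or a fixed integer order.
#' @param max_order cap for the MDL search (default 30, reduced automatically
#'   for short series).
#' @param ica_runs number of ICA runs pooled by stability selection
#'   (default 20; 1 = single plain ICA run).
#' @param ica_bootstrap resample timepoints across ICA runs (default TRUE).
#' @param seed base seed for every stochastic stage.
#' @param bandpass apply [bandpass_detrend()] to each subject (default FALSE;
#'   inputs are assumed preprocessed).
#' @param low_hz,high_hz,tr_seconds band-pass settings when `bandpass = TRUE`.
#' @param atlas_restrict restrict the joint common voxel set to atlas-labelled
#'   (e.g. gray-matter) voxels before computing connectivity (default FALSE).
#' @param nested_selection also re-run the differential selection inside each
#'   training split (leakage-free variant) and report it alongside
#'   (default FALSE).
#' @param welch,fisher_z test options passed to [select_dfc()].
#' @param protocol an [eval_protocol()].
#' @param positive_label cohort treated as positive class; defaults to the
#'   second cohort label encountered.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(theta = 2, alpha = 0.05, ica_order = "mdl",
                            max_order = 30L, ica_runs = 20L,
                            ica_bootstrap = TRUE, seed = 1L,
                            bandpass = FALSE, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = 3, atlas_restrict = FALSE,
                            nested_selection = FALSE, welch = FALSE,
                            fisher_z = FALSE, protocol = eval_protocol(),
                            positive_label = NULL) {
  structure(list(theta = theta, alpha = alpha, ica_order = ica_order,
                 max_order = max_order, ica_runs = ica_runs,
                 ica_bootstrap = ica_bootstrap, seed = as.integer(seed),
                 bandpass = bandpass, low_hz = low_hz, high_hz = high_hz,
                 tr_seconds = tr_seconds, atlas_restrict = atlas_restrict,
                 nested_selection = nested_selection, welch = welch,
                 fisher_z = fisher_z, protocol = protocol,
                 positive_label = positive_label),
            class = "pipeline_config")
}

# Resolve a dataset argument (synth_dataset, manifest path or manifest
# data.frame) into grid + per-subject raw series + labels + atlas.
resolve_dataset <- function(x) {
  if (inherits(x, "synth_dataset")) {
    return(list(grid = x$grid,
                volumes = lapply(x$subjects, `[[`, "series"),
                subject_ids = vapply(x$subjects, `[[`, character(1), "subject_id"),
                labels = vapply(x$subjects, `[[`, character(1), "group_label"),
                atlas_volume = x$atlas))
  }
  if (is.character(x) && length(x) == 1L) x <- read.delim(x, header = TRUE)
  if (is.data.frame(x)) {
    need <- c("subject_id", "group_label", "path")
    if (!all(need %in% names(x)))
      vfc_error("voxelfc_config_error",
                "manifest needs columns subject_id, group_label, path")
    first <- as.array(RNifti::readNifti(x$path[1]))
    grid <- volume_grid(dim(first)[1:3],
                        affine = RNifti::xform(RNifti::readNifti(x$path[1])))
    return(list(grid = grid, volumes = as.list(x$path),
                subject_ids = as.character(x$subject_id),
                labels = as.character(x$group_label), atlas_volume = NULL))
  }
  vfc_error("voxelfc_config_error", "dataset must be a synth_dataset, manifest path or manifest data.frame")
}

#' Prepare a pipeline state: mask, subject matrices and z-scored ICA maps
#'
#' Runs the threshold-independent stages once (mask construction, optional
#' band-pass, per-subject ICA with MDL order and stability selection,
#' z-scoring), so that different activity thresholds can be analyzed without
#' re-estimating the decompositions.
#'
#' @param x a `synth_dataset`, a manifest TSV path, or a manifest data.frame
#'   with columns `subject_id`, `group_label`, `path`.
#' @param config a [pipeline_config()].
#' @param atlas optional atlas (path or 3D array) overriding the dataset's.
#' @param explicit_mask optional explicit mask volume.
#' @return An object of class `pipeline_state`.
#' @export
prepare_pipeline <- function(x, config = pipeline_config(), atlas = NULL,
                             explicit_mask = NULL) {
  ds <- resolve_dataset(x)
  groups <- unique(ds$labels)
  if (length(groups) != 2L)
    vfc_error("voxelfc_config_error", sprintf(
      "expected exactly two cohort labels, got: %s", paste(groups, collapse = ", ")))
  mask <- build_group_mask(ds$volumes, ds$grid, explicit_mask = explicit_mask)
  atlas_volume <- atlas %||% ds$atlas_volume
  atlas_labels <- if (!is.null(atlas_volume)) load_atlas(atlas_volume, mask)
  subjects <- vector("list", length(ds$volumes))
  zmaps <- vector("list", length(ds$volumes))
  orders <- integer(length(ds$volumes))
  for (i in seq_along(ds$volumes)) {
    s <- load_subject_volume(ds$volumes[[i]], mask,
                             subject_id = ds$subject_ids[i],
                             group_label = ds$labels[i])
    if (config$bandpass)
      s <- bandpass_detrend(s, config$low_hz, config$high_hz, config$tr_seconds)
    if (identical(config$ica_order, "mdl")) {
      cap <- min(config$max_order, s$t_points - 1L, ncol(s$data) - 1L)
      orders[i] <- estimate_order_mdl(s, cap)
    } else {
      orders[i] <- as.integer(config$ica_order)
    }
    dec <- stability_select(s, orders[i], n_runs = config$ica_runs,
                            base_seed = config$seed + 1000L * i,
                            bootstrap = config$ica_bootstrap)
    zmaps[[i]] <- zscore_maps(dec)
    subjects[[i]] <- s
  }
  structure(list(mask = mask, subjects = subjects, zmaps = zmaps,
                 labels = ds$labels, groups = groups, orders = orders,
                 atlas = atlas_labels, config = config),
            class = "pipeline_state")
}

#' Analyze a prepared state at one activity threshold
#'
#' Computes per-subject activity voxels, cohort and joint intersections, FC
#' feature matrices, differential selection, and (optionally) the paired
#' classification of differential versus all FC features.
#'
#' @param state a `pipeline_state` from [prepare_pipeline()].
#' @param theta activity threshold; defaults to the state's configured value.
#' @param run_eval run the paired hold-out evaluation (default TRUE).
#' @return A list with the dimension log (`K1`, `K2`, `N_i`, `N1`, `N2`,
#'   `N12`, `edge_count`, `n_dfci`), the intermediate sets and matrices, the
#'   `dfc_result` and the evaluation reports.
#' @export
analyze_state <- function(state, theta = NULL, run_eval = TRUE) {
  config <- state$config
  theta <- theta %||% config$theta
  avls <- lapply(state$zmaps, subject_active_voxels, mask = state$mask, theta = theta)
  g1 <- state$labels == state$groups[1]
  cavl1 <- group_common_voxels(avls[g1])
  cavl2 <- group_common_voxels(avls[!g1])
  cavl12 <- joint_common_voxels(cavl1, cavl2)
  if (config$atlas_restrict) {
    if (is.null(state$atlas))
      vfc_error("voxelfc_config_error", "atlas_restrict requires an atlas")
    cavl12 <- restrict_to_atlas(cavl12, state$atlas)
    if (cavl12$n < 2L)
      vfc_error("voxelfc_degenerate_error", "fewer than 2 atlas-labelled joint common voxels")
  }
  fc1 <- stack_group_fc(state$subjects[g1], cavl12)
  fc2 <- stack_group_fc(state$subjects[!g1], cavl12)
  dfc <- select_dfc(fc1, fc2, alpha = config$alpha, welch = config$welch,
                    fisher_z = config$fisher_z)
  all_features <- rbind(fc1$matrix, fc2$matrix)
  labels <- factor(c(rep(state$groups[1], nrow(fc1$matrix)),
                     rep(state$groups[2], nrow(fc2$matrix))),
                   levels = state$groups)
  protocol <- config$protocol
  protocol$positive_label <- config$positive_label %||% state$groups[2]
  reports <- NULL
  if (run_eval) {
    if (dfc$empty) {
      reports <- list(all_fc = evaluate(all_features, labels, protocol,
                                        feature_label = "all_fc"),
                      dfc = NULL, fallback = "empty differential selection; evaluated all FC features only")
    } else {
      dfc_features <- rbind(dfc$dfc1, dfc$dfc2)
      reports <- compare_feature_sets(all_features, dfc_features, labels, protocol)
      if (config$nested_selection)
        reports$nested <- evaluate_nested_dfc(all_features, labels, protocol, config)
    }
  }
  list(dims = list(K1 = sum(g1), K2 = sum(!g1), N_i = vapply(avls, `[[`, integer(1), "n"),
                   N1 = cavl1$n, N2 = cavl2$n, N12 = cavl12$n,
                   edge_count = if (cavl12$n >= 2) cavl12$n * (cavl12$n - 1) / 2 else 0L,
                   n_dfci = length(dfc$dfci)),
       theta = theta, avls = avls, cavl1 = cavl1, cavl2 = cavl2,
       cavl12 = cavl12, fc1 = fc1, fc2 = fc2, dfc = dfc,
       labels = labels, reports = reports)
}

# Leakage-free variant: re-select differential edges inside each training
# split, evaluate on the held-out subjects with those edges only.
evaluate_nested_dfc <- function(features, labels, protocol, config) {
  acc <- rep(NA_real_, protocol$n_runs)
  for (r in seq_len(protocol$n_runs)) {
    test <- split_test_indices(labels, protocol, r)
    xtr <- features[-test, , drop = FALSE]
    ytr <- labels[-test]
    sel <- select_dfc(xtr[ytr == levels(labels)[1], , drop = FALSE],
                      xtr[ytr == levels(labels)[2], , drop = FALSE],
                      alpha = config$alpha, welch = config$welch,
                      fisher_z = config$fisher_z)
    cols <- if (sel$empty) seq_len(ncol(features)) else sel$dfci
    std <- standardize_by_train(xtr[, cols, drop = FALSE],
                                features[test, cols, drop = FALSE])
    fit <- e1071::svm(std$train, factor(ytr, levels = levels(labels)),
                      kernel = "linear", cost = protocol$svm_c, scale = FALSE)
    pred <- predict(fit, std$test)
    acc[r] <- mean(pred == labels[test])
  }
  c(mean = mean(acc, na.rm = TRUE), sd = sd(acc, na.rm = TRUE))
}

#' Run the full pipeline
#'
#' @inheritParams prepare_pipeline
#' @param output_dir optional directory; when given, a summary JSON and the
#'   stage tables are written there.
#' @return A list: `dims` (all Fig.-1 flow dimensions), `analysis` (the
#'   [analyze_state()] bundle) and `summary` (plain-list summary of settings,
#'   dimensions and metrics).
#' @export
run_pipeline <- function(x, config = pipeline_config(), atlas = NULL,
                         explicit_mask = NULL, output_dir = NULL) {
  state <- prepare_pipeline(x, config, atlas = atlas, explicit_mask = explicit_mask)
  res <- analyze_state(state)
  summary <- c(
    list(theta = res$theta, alpha = config$alpha, seed = config$seed,
         ica_runs = config$ica_runs),
    res$dims[c("K1", "K2", "N1", "N2", "N12", "edge_count", "n_dfci")],
    list(orders = state$orders))
  if (!is.null(res$reports)) {
    summary$all_fc_accuracy <- unname(res$reports$all_fc$accuracy["mean"])
    if (!is.null(res$reports$dfc)) {
      summary$dfc_accuracy <- unname(res$reports$dfc$accuracy["mean"])
      summary$dfc_sensitivity <- unname(res$reports$dfc$sensitivity["mean"])
      summary$dfc_specificity <- unname(res$reports$dfc$specificity["mean"])
    }
    if (!is.null(res$reports$fallback)) summary$fallback <- res$reports$fallback
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_dfc_result(res$dfc, file.path(output_dir, "dfc_edges.tsv"))
    write_voxel_set(res$cavl12, file.path(output_dir, "cavl12"))
  }
  list(dims = res$dims, state = state, analysis = res, summary = summary)
}

#' Threshold-sweep robustness analysis
#'
#' Re-runs the threshold-dependent stages over a grid of activity thresholds
#' (default 1.5 to 2.5 in steps of 0.1) on one prepared state, recording the
#' joint common voxel count, the number of selected edges, and both feature
#' sets' classification metrics per threshold.  Thresholds at which the joint
#' common set degenerates are recorded as such and the sweep continues.
#'
#' @param state a `pipeline_state` (or a dataset, which will be prepared
#'   with `config`).
#' @param theta_values ascending positive thresholds (default `seq(1.5, 2.5, 0.1)`).
#' @param config used only when `state` is not already prepared.
#' @return A data.frame with one row per threshold: `theta`, `n12`,
#'   `edge_count`, `n_dfci`, `acc_dfc`, `acc_all`, `sens_dfc`, `sens_all`,
#'   `spec_dfc`, `spec_all`, `degenerate`.
#' @export
threshold_sweep <- function(state, theta_values = seq(1.5, 2.5, by = 0.1),
                            config = pipeline_config()) {
  if (!inherits(state, "pipeline_state"))
    state <- prepare_pipeline(state, config)
  if (any(theta_values <= 0) || is.unsorted(theta_values))
    vfc_error("voxelfc_parameter_error", "theta values must be positive and ascending")
  rows <- lapply(theta_values, function(th) {
    res <- tryCatch(analyze_state(state, theta = th),
                    voxelfc_degenerate_error = function(e) NULL)
    if (is.null(res))
      return(data.frame(theta = th, n12 = NA_integer_, edge_count = NA_integer_,
                        n_dfci = NA_integer_, acc_dfc = NA_real_, acc_all = NA_real_,
                        sens_dfc = NA_real_, sens_all = NA_real_,
                        spec_dfc = NA_real_, spec_all = NA_real_, degenerate = TRUE))
    rp <- res$reports
    has_dfc <- !is.null(rp$dfc)
    data.frame(theta = th, n12 = res$dims$N12, edge_count = res$dims$edge_count,
               n_dfci = res$dims$n_dfci,
               acc_dfc = if (has_dfc) unname(rp$dfc$accuracy["mean"]) else NA_real_,
               acc_all = unname(rp$all_fc$accuracy["mean"]),
               sens_dfc = if (has_dfc) unname(rp$dfc$sensitivity["mean"]) else NA_real_,
               sens_all = unname(rp$all_fc$sensitivity["mean"]),
               spec_dfc = if (has_dfc) unname(rp$dfc$specificity["mean"]) else NA_real_,
               spec_all = unname(rp$all_fc$specificity["mean"]),
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate and write a synthetic dataset ready for the pipeline
#'
#' Convenience wrapper: [generate_cohorts()] followed by [write_dataset()];
#' the written manifest is directly consumable by [run_pipeline()].
#'
#' @param config a [synth_config()].
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
simulate_dataset <- function(config = synth_config(), dir) {
  write_dataset(generate_cohorts(config), dir)
}
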