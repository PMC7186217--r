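# Repeated hold-out classification: linear SVM by default, paired comparison
# of differential-FC versus all-FC features, threshold-sweep robustness and a
# multi-classifier comparison table.

#' Evaluation protocol for repeated hold-out classification
#'
#' @param train_fraction fraction of each class used for training (default
#'   0.8; the remaining 20% are the test set).
#' @param n_runs number of random splits (default 1000); run r is seeded with
#'   `base_seed + r`, so two evaluations under one protocol see identical
#'   split sequences.
#' @param svm_c SVM soft-margin constant C (default 1).
#' @param kernel `"linear"` (default) or `"gaussian"`.
#' @param stratified sample the split within each class (default TRUE).
#' @param base_seed seed for the split sequence.
#' @param positive_label cohort treated as the positive (patient) class for
#'   sensitivity; defaults to the second factor level of the labels.
#' @param standardize z-score features with training-split statistics before
#'   fitting (default TRUE).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(train_fraction = 0.8, n_runs = 1000L, svm_c = 1,
                          kernel = c("linear", "gaussian"), stratified = TRUE,
                          base_seed = 1L, positive_label = NULL,
                          standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    vfc_error("voxelfc_parameter_error", "train_fraction must lie in (0, 1)")
  if (!is_count(n_runs))
    vfc_error("voxelfc_parameter_error", "n_runs must be a positive integer")
  if (!is_number(svm_c) || svm_c <= 0)
    vfc_error("voxelfc_parameter_error", "svm_c must be positive")
  structure(list(train_fraction = train_fraction, n_runs = as.integer(n_runs),
                 svm_c = svm_c, kernel = kernel, stratified = stratified,
                 base_seed = as.integer(base_seed),
                 positive_label = positive_label, standardize = standardize),
            class = "eval_protocol")
}

# Test-set row indices for run r, deterministic in protocol$base_seed + r.
split_test_indices <- function(labels, protocol, run) {
  with_seed(protocol$base_seed + run, {
    if (protocol$stratified) {
      unlist(lapply(levels(labels), function(l) {
        idx <- which(labels == l)
        n_test <- max(1L, round((1 - protocol$train_fraction) * length(idx)))
        sample(idx, n_test)
      }), use.names = FALSE)
    } else {
      n_test <- max(1L, round((1 - protocol$train_fraction) * length(labels)))
      sample(seq_along(labels), n_test)
    }
  })
}

standardize_by_train <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(xte, 2, mu), 2, sdv, "/"))
}

# Classifier backends. Each takes standardized train/test matrices and a
# 2-level factor, and returns predicted labels for the test rows.
classifier_fun <- function(algorithm, protocol) {
  switch(algorithm,
    lsvm = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = protocol$svm_c,
                        scale = FALSE)
      predict(fit, xte)
    },
    gsvm = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = protocol$svm_c,
                        gamma = 1 / ncol(xtr), scale = FALSE)
      predict(fit, xte)
    },
    dt = function(xtr, ytr, xte) {
      dtr <- data.frame(.y = ytr, xtr, check.names = TRUE)
      dte <- data.frame(xte, check.names = TRUE)
      colnames(dte) <- colnames(dtr)[-1]
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(minsplit = 4, minbucket = 2))
      predict(fit, dte, type = "class")
    },
    ld = function(xtr, ytr, xte) {
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
      predict(fit, xte)$class
    },
    lr = function(xtr, ytr, xte) {
      dtr <- data.frame(.y = ytr, xtr, check.names = TRUE)
      dte <- data.frame(xte, check.names = TRUE)
      colnames(dte) <- colnames(dtr)[-1]
      fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
      pr <- suppressWarnings(predict(fit, dte, type = "response"))
      factor(levels(ytr)[1L + (pr > 0.5)], levels = levels(ytr))
    },
    knn = function(xtr, ytr, xte) {
      class::knn(xtr, xte, cl = ytr, k = 5)
    },
    vfc_error("voxelfc_config_error", sprintf("unknown algorithm '%s'", algorithm))
  )
}

svm_algorithm <- function(protocol) {
  if (protocol$kernel == "linear") "lsvm" else "gsvm"
}

#' Repeated hold-out evaluation of a feature matrix
#'
#' For each of `n_runs` random (by default stratified) train/test splits,
#' fits the classifier on the training rows and computes the test confusion;
#' accuracy, sensitivity (positive-class recall) and specificity are averaged
#' over runs.  Identical inputs and protocol give an identical report.
#'
#' @param features numeric subjects x features matrix.
#' @param labels cohort labels, coercible to a 2-level factor.
#' @param protocol an [eval_protocol()].
#' @param algorithm classifier backend: one of `"lsvm"`, `"gsvm"`, `"dt"`,
#'   `"ld"`, `"lr"`, `"knn"`; defaults to the protocol's SVM kernel.
#' @param feature_label tag recorded in the report (`"all_fc"` or `"dfc"`).
#' @return An object of class `classification_report` with `per_run` metrics
#'   and confusion counts, aggregate means and standard deviations, the
#'   protocol, and the feature-set tag.
#' @export
evaluate <- function(features, labels, protocol = eval_protocol(),
                     algorithm = NULL, feature_label = "all_fc") {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    vfc_error("voxelfc_grouping_error", "labels must have exactly two levels")
  if (nrow(features) != length(labels))
    vfc_error("voxelfc_parameter_error", "feature rows do not match labels")
  if (min(table(labels)) < 2L)
    vfc_error("voxelfc_sample_size_error", "each class needs at least 2 subjects")
  if (ncol(features) < 1L)
    vfc_error("voxelfc_parameter_error", "need at least one feature")
  algorithm <- algorithm %||% svm_algorithm(protocol)
  fit_predict <- classifier_fun(algorithm, protocol)
  positive <- protocol$positive_label %||% levels(labels)[2L]
  if (!positive %in% levels(labels))
    vfc_error("voxelfc_config_error", "positive_label is not one of the cohort labels")
  per_run <- data.frame(run = seq_len(protocol$n_runs), accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        tp = NA_integer_, fn = NA_integer_,
                        tn = NA_integer_, fp = NA_integer_)
  for (r in seq_len(protocol$n_runs)) {
    test <- split_test_indices(labels, protocol, r)
    xtr <- features[-test, , drop = FALSE]
    xte <- features[test, , drop = FALSE]
    ytr <- droplevels(labels[-test])
    if (nlevels(ytr) < 2L) next  # degenerate non-stratified split: no fit possible
    ytr <- factor(ytr, levels = levels(labels))
    if (protocol$standardize) {
      std <- standardize_by_train(xtr, xte)
      xtr <- std$train; xte <- std$test
    }
    pred <- factor(fit_predict(xtr, ytr, xte), levels = levels(labels))
    truth <- labels[test]
    tp <- sum(pred == positive & truth == positive)
    fn <- sum(pred != positive & truth == positive)
    tn <- sum(pred != positive & truth != positive)
    fp <- sum(pred == positive & truth != positive)
    per_run$accuracy[r] <- (tp + tn) / length(test)
    per_run$sensitivity[r] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per_run$specificity[r] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    per_run[r, c("tp", "fn", "tn", "fp")] <- c(tp, fn, tn, fp)
  }
  agg <- function(x) c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  structure(list(per_run = per_run,
                 accuracy = agg(per_run$accuracy),
                 sensitivity = agg(per_run$sensitivity),
                 specificity = agg(per_run$specificity),
                 algorithm = algorithm, positive_label = positive,
                 protocol = protocol, feature_label = feature_label),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report [%s, %s]: accuracy %.3f +/- %.3f, sensitivity %.3f, specificity %.3f (%d runs)\n",
    x$feature_label, x$algorithm, x$accuracy["mean"], x$accuracy["sd"],
    x$sensitivity["mean"], x$specificity["mean"], x$protocol$n_runs))
  invisible(x)
}

#' Paired comparison of all-FC and differential-FC feature sets
#'
#' Evaluates both feature matrices over the identical split sequence (shared
#' seeds), so per-run metric differences are paired.
#'
#' @param all_fc subjects x edges matrix of all FC features.
#' @param dfc subjects x selected-edges matrix of differential FC features.
#' @param labels cohort labels (same subjects, same order, for both sets).
#' @param protocol an [eval_protocol()].
#' @return A list with the two `classification_report`s, a `paired_diff`
#'   data.frame of per-run (dfc - all_fc) metric differences, and their means.
#' @export
compare_feature_sets <- function(all_fc, dfc, labels, protocol = eval_protocol()) {
  if (nrow(as.matrix(all_fc)) != nrow(as.matrix(dfc)))
    vfc_error("voxelfc_parameter_error", "feature sets have different subject rows")
  rep_all <- evaluate(all_fc, labels, protocol, feature_label = "all_fc")
  rep_dfc <- evaluate(dfc, labels, protocol, feature_label = "dfc")
  diff <- data.frame(
    run = rep_all$per_run$run,
    accuracy = rep_dfc$per_run$accuracy - rep_all$per_run$accuracy,
    sensitivity = rep_dfc$per_run$sensitivity - rep_all$per_run$sensitivity,
    specificity = rep_dfc$per_run$specificity - rep_all$per_run$specificity)
  list(all_fc = rep_all, dfc = rep_dfc, paired_diff = diff,
       mean_diff = colMeans(diff[, -1], na.rm = TRUE))
}

#' Compare multiple classification algorithms on one feature set
#'
#' Runs the same paired-split evaluation for each algorithm (identical split
#' sequences) and tabulates mean accuracy, sensitivity and specificity.
#'
#' @param features subjects x features matrix.
#' @param labels cohort labels.
#' @param protocol an [eval_protocol()].
#' @param algorithms subset of `c("dt", "ld", "lr", "knn", "gsvm", "lsvm")`:
#'   decision tree, linear discriminant, logistic regression, k-nearest
#'   neighbour (k = 5), Gaussian-kernel SVM and linear SVM.
#' @return A data.frame with one row per algorithm; the per-algorithm reports
#'   are attached as the `"reports"` attribute.
#' @export
compare_classifiers <- function(features, labels, protocol = eval_protocol(),
                                algorithms = c("dt", "ld", "lr", "knn", "gsvm", "lsvm")) {
  reports <- lapply(algorithms, function(a)
    evaluate(features, labels, protocol, algorithm = a, feature_label = "dfc"))
  names(reports) <- algorithms
  out <- data.frame(
    algorithm = algorithms,
    accuracy = vapply(reports, function(r) unname(r$accuracy["mean"]), numeric(1)),
    sensitivity = vapply(reports, function(r) unname(r$sensitivity["mean"]), numeric(1)),
    specificity = vapply(reports, function(r) unname(r$specificity["mean"]), numeric(1)),
    row.names = NULL)
  attr(out, "reports") <- reports
  out
}
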