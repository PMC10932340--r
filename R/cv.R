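# Stratified k-fold machinery, classification metrics, repeated
# cross-validation reports, and the per-variant error-rate map.

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals samples round-robin, so
#' per-fold class counts differ by at most one from perfect stratification.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (any(table(y) < k)) {
    stop_validation("every class needs at least %d members for %d-fold CV", k, k)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Rank-statistic AUC-ROC
#'
#' Mann-Whitney form with ties averaged: the probability that a random
#' positive scores above a random negative.
#'
#' @param truth binary labels.
#' @param scores predicted probabilities (any monotone score works).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop_validation("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The metric quartet: AUC-ROC, balanced accuracy, sensitivity, specificity
#'
#' Sensitivity is the true-positive rate on the positive class (pathogenic /
#' severe = 1), specificity the true-negative rate, balanced accuracy their
#' mean.
#'
#' @param truth binary labels (both classes present).
#' @param scores predicted probabilities.
#' @param threshold decision threshold applied to `scores`.
#' @return named list with `auc_roc`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) {
    stop_validation("both classes must be present to compute metrics")
  }
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1 & truth == 1) / sum(truth == 1)
  spec <- sum(pred == 0 & truth == 0) / sum(truth == 0)
  list(auc_roc = auc_roc(truth, scores),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens,
       specificity = spec)
}

#' Repeated stratified cross-validation
#'
#' The performance-estimation protocol: stratified `folds`-fold
#' cross-validation repeated `repeats` times with reshuffled splits, metrics
#' aggregated as mean and standard deviation over all `folds * repeats`
#' splits. Every sample lands in a held-out fold exactly `repeats` times; the
#' held-out predictions are stored per repeat for the error-rate map.
#'
#' @param X feature data frame.
#' @param y binary labels.
#' @param config a [model_config()] (or algorithm name).
#' @param folds folds per repeat.
#' @param repeats number of reshuffled repetitions.
#' @param seed master seed; per-repeat shuffle seeds are derived from it.
#' @param threshold decision threshold for the thresholded metrics.
#' @return object of class `cv_report`: list with `splits` (per-split metric
#'   data frame), `summary` (mean/sd per metric), `predictions` (long data
#'   frame of held-out scores), `folds`, `repeats`, `threshold`.
#' @export
repeated_stratified_cv <- function(X, y, config, folds = 5, repeats = 25,
                                   seed = 1L, threshold = 0.5) {
  if (is.character(config)) config <- model_config(config)
  y <- as.integer(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  ids <- rownames(X) %||% as.character(seq_len(n))

  split_rows <- list()
  pred_rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, paste0("repeat", r)))
    for (kf in seq_len(folds)) {
      test <- which(fold_id == kf)
      train <- which(fold_id != kf)
      cfg <- config
      cfg$seed <- derive_seed(seed, sprintf("fit_r%d_f%d", r, kf))
      model <- fit_model(cfg, X[train, , drop = FALSE], y[train])
      p <- predict_prob(model, X[test, , drop = FALSE])
      m <- compute_metrics(y[test], p, threshold)
      split_rows[[length(split_rows) + 1]] <-
        data.frame(repeat_id = r, fold = kf, auc_roc = m$auc_roc,
                   balanced_accuracy = m$balanced_accuracy,
                   sensitivity = m$sensitivity, specificity = m$specificity)
      pred_rows[[length(pred_rows) + 1]] <-
        data.frame(sample = ids[test], repeat_id = r, fold = kf,
                   score = p, truth = y[test], stringsAsFactors = FALSE)
    }
    if (r %% 5 == 0) gc(verbose = FALSE)
  }
  splits <- do.call(rbind, split_rows)
  preds <- do.call(rbind, pred_rows)
  metric_cols <- c("auc_roc", "balanced_accuracy", "sensitivity", "specificity")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(splits[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(splits[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(list(splits = splits, summary = summ, predictions = preds,
                 folds = folds, repeats = repeats, threshold = threshold,
                 algorithm = config$algorithm),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d x %d-fold CV\n",
              x$algorithm %||% "ensemble", x$repeats, x$folds))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Mean of a metric from a CV report
#' @param report a `cv_report`.
#' @param metric metric name.
#' @return scalar mean over splits.
#' @export
cv_metric <- function(report, metric = "auc_roc") {
  report$summary$mean[report$summary$metric == metric]
}

#' Per-variant cross-validation error-rate map
#'
#' For each sample, the ratio of misclassifications (at the report's
#' threshold) over its `repeats` held-out predictions; samples with a ratio
#' above 0.5 — misclassified in the majority of repeats — are flagged as
#' systematically hard.
#'
#' @param report a `cv_report`.
#' @param threshold decision threshold (defaults to the report's).
#' @return data frame with `sample`, `truth`, `errors`, `repeats`, `ratio`,
#'   `flagged`, sorted by decreasing ratio.
#' @export
error_rate_map <- function(report, threshold = NULL) {
  stopifnot(inherits(report, "cv_report"))
  threshold <- threshold %||% report$threshold
  p <- report$predictions
  p$wrong <- as.integer(p$score >= threshold) != p$truth
  agg <- stats::aggregate(wrong ~ sample + truth, data = p, FUN = sum)
  cnt <- stats::aggregate(wrong ~ sample, data = p, FUN = length)
  names(cnt)[2] <- "n"
  out <- merge(agg, cnt, by = "sample")
  out <- data.frame(sample = out$sample, truth = out$truth,
                    errors = out$wrong, repeats = out$n,
                    ratio = out$wrong / out$n,
                    flagged = out$wrong / out$n > 0.5,
                    stringsAsFactors = FALSE)
  out[order(-out$ratio, out$sample), ]
}
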