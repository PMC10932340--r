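# The severity sub-task: three-way label merging, the endpoint-feature
# guard, decision-threshold optimization, and the severity trainer.

#' Merge raw severity labels into the binary severe/benign scheme
#'
#' Variants reported with both benign and severe phenotypes
#' (`"benign/severe"`) are combined with `"severe"` into the positive class;
#' `"benign"` is the negative class.
#'
#' @param labels_raw character vector of `benign`, `benign/severe`, `severe`.
#' @return list with `labels` (integer 0/1), `counts` (named table of the
#'   raw labels) and `merged_counts` (benign / severe after merging).
#' @export
merge_severity_labels <- function(labels_raw) {
  allowed <- c("benign", "benign/severe", "severe")
  bad <- setdiff(unique(labels_raw), allowed)
  if (length(bad) > 0) {
    stop_validation("unknown severity label(s): %s", paste(bad, collapse = ", "))
  }
  merged <- as.integer(labels_raw %in% c("benign/severe", "severe"))
  list(labels = merged,
       counts = table(factor(labels_raw, levels = allowed)),
       merged_counts = c(benign = sum(merged == 0), severe = sum(merged == 1)))
}

#' Optimize the decision threshold for balanced accuracy
#'
#' Scans the candidate cuts — the midpoints between adjacent sorted unique
#' scores, plus 0.5 — and returns the one maximizing balanced accuracy on
#' the given (training) scores. Ties resolve to the candidate closest to
#' 0.5 (then the smaller). Because 0.5 is always a candidate, the optimized
#' threshold never does worse than the default.
#'
#' @param scores training-set probabilities.
#' @param labels binary labels (both classes present).
#' @return the selected threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop_validation("both classes must be present to optimize a threshold")
  }
  u <- sort(unique(scores))
  candidates <- 0.5
  if (length(u) > 1) candidates <- sort(unique(c((u[-1] + u[-length(u)]) / 2, 0.5)))
  bacc <- vapply(candidates, function(t) {
    compute_metrics(labels, scores, t)$balanced_accuracy
  }, numeric(1))
  best <- bacc >= max(bacc) - 1e-12
  cand <- candidates[best]
  cand[order(abs(cand - 0.5), cand)][1]
}

#' Guard against endpoint amino-acid features
#'
#' The severity models overfit when given the initial/final amino-acid
#' one-hots (they memorize mutation identities), so the severity trainer
#' rejects any matrix still carrying them.
#'
#' @param features feature data frame.
#' @return invisibly `TRUE`; errors when endpoint one-hots are present.
#' @export
assert_no_endpoint_features <- function(features) {
  leak <- intersect(endpoint_feature_names(), colnames(features))
  if (length(leak) > 0) {
    stop_validation(paste0("severity models exclude endpoint amino-acid features; ",
                           "drop column(s): %s (build features with include_endpoint_aa = FALSE)"),
                    paste(utils::head(leak, 6), collapse = ", "))
  }
  invisible(TRUE)
}

#' Train the severity model
#'
#' Runs the same protocol as [train_pathogenicity()] (greedy feature
#' selection, hyperparameter search, repeated CV, greedy soft-vote ensemble)
#' on a severity dataset whose feature matrix must exclude the endpoint
#' amino-acid one-hots, then optimizes the decision threshold for balanced
#' accuracy on the training scores of the refit ensemble. Test-set
#' predictions use that training-optimized threshold unchanged.
#'
#' @inheritParams train_pathogenicity
#' @return a `vfipred_bundle` with task `"severity"` and the optimized
#'   `threshold`.
#' @export
train_severity <- function(ds,
                           algorithms = c("logistic_regression", "svm",
                                          "random_forest"),
                           n_draws = 10, folds = 5, repeats = 25,
                           patience = 10, seed = 1L) {
  assert_no_endpoint_features(ds$features)
  bundle <- train_pathogenicity(ds, algorithms = algorithms, n_draws = n_draws,
                                folds = folds, repeats = repeats,
                                patience = patience, seed = seed,
                                task = "severity")
  tr <- training(ds)
  train_scores <- predict_ensemble(bundle$ensemble, tr$X)
  bundle$threshold <- optimize_threshold(train_scores, tr$y)
  bundle
}
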