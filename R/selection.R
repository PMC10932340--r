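# Forward greedy feature selection and random hyperparameter search, both
# scored by stratified 5-fold mean AUC-ROC.

# Mean k-fold AUC for a feature subset; NA when the backing fit cannot
# handle the subset (e.g. within-class constant columns for LDA).
cv_score_features <- function(X, y, algorithm, features, fold_id, hyperparameters = list(),
                              seed = 1L) {
  k <- max(fold_id)
  scores <- numeric(k)
  for (kf in seq_len(k)) {
    train <- which(fold_id != kf)
    test <- which(fold_id == kf)
    cfg <- model_config(algorithm, hyperparameters, selected_features = features,
                        seed = derive_seed(seed, paste0("selfit", kf)))
    res <- tryCatch({
      model <- fit_model(cfg, X[train, , drop = FALSE], y[train])
      p <- predict_prob(model, X[test, , drop = FALSE])
      if (any(!is.finite(p))) NA_real_ else auc_roc(y[test], p)
    }, error = function(e) NA_real_)
    if (is.na(res)) return(NA_real_)
    scores[kf] <- res
  }
  mean(scores)
}

#' Forward greedy feature selection
#'
#' Starting from the empty set, iteratively adds the feature that maximizes
#' the stratified `folds`-fold mean AUC-ROC of the algorithm. The search
#' stops once the score has not improved for `patience` consecutive
#' additions (or candidates run out), and the prefix achieving the maximum
#' score is returned. Ties between candidate features are broken by feature
#' name order, so the search is fully deterministic given the seed.
#'
#' @param X feature data frame.
#' @param y binary labels.
#' @param algorithm zoo member name.
#' @param hyperparameters fixed hyperparameters used during the search.
#' @param patience consecutive non-improving steps tolerated.
#' @param folds CV folds used for scoring.
#' @param seed seed for the fold shuffle and stochastic fits.
#' @return list with `selected` (ordered best prefix), `trace` (data frame of
#'   step, feature added, score), `best_score`.
#' @export
greedy_feature_selection <- function(X, y, algorithm, hyperparameters = list(),
                                     patience = 10, folds = 5, seed = 1L) {
  candidates <- sort(colnames(X))
  if (length(candidates) < 1) stop_validation("no candidate features")
  y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, "greedy_folds"))

  selected <- character(0)
  trace <- data.frame(step = integer(0), feature = character(0), score = numeric(0))
  best_score <- -Inf
  best_len <- 0L
  since_best <- 0L
  step <- 0L
  while (length(candidates) > 0 && since_best < patience) {
    step <- step + 1L
    cand_scores <- vapply(candidates, function(f) {
      cv_score_features(X, y, algorithm, c(selected, f), fold_id,
                        hyperparameters, seed = derive_seed(seed, paste0("step", step)))
    }, numeric(1))
    if (all(is.na(cand_scores))) break
    pick <- which(cand_scores == max(cand_scores, na.rm = TRUE))[1]
    selected <- c(selected, candidates[pick])
    trace <- rbind(trace, data.frame(step = step, feature = candidates[pick],
                                     score = cand_scores[[pick]]))
    # release booster/forest handles eagerly: thousands of rapid external
    # allocations otherwise leave finalization to mid-allocation GC
    gc(verbose = FALSE)
    if (cand_scores[[pick]] > best_score) {
      best_score <- cand_scores[[pick]]
      best_len <- length(selected)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    candidates <- candidates[-pick]
  }
  list(selected = selected[seq_len(best_len)], trace = trace, best_score = best_score)
}

#' Random search over a hyperparameter space
#'
#' Draws `n_draws` combinations from the per-parameter samplers and returns
#' the combination with the highest stratified `folds`-fold mean AUC-ROC;
#' ties are broken by draw order. An empty space evaluates the algorithm's
#' defaults once.
#'
#' @param X feature data frame (already restricted to the selected features).
#' @param y binary labels.
#' @param algorithm zoo member name.
#' @param space named list of samplers `function(n)`; defaults to
#'   [default_search_space()].
#' @param n_draws number of random combinations.
#' @param folds CV folds used for scoring.
#' @param seed seed controlling both the draws and the fold shuffle.
#' @return list with `best_params`, `best_score`, `evaluated` (data frame of
#'   draws and scores).
#' @export
random_grid_search <- function(X, y, algorithm, space = NULL, n_draws = 10,
                               folds = 5, seed = 1L) {
  if (!is_count(n_draws)) stop_validation("n_draws must be a positive integer")
  space <- space %||% default_search_space(algorithm)
  y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, "grid_folds"))

  draws <- if (length(space) == 0) {
    list(list())
  } else {
    cols <- with_seed(derive_seed(seed, "grid_draws"),
                      lapply(space, function(sampler) sampler(n_draws)))
    lapply(seq_len(n_draws), function(i) lapply(cols, `[[`, i))
  }
  scores <- vapply(seq_along(draws), function(i) {
    cv_score_features(X, y, algorithm, colnames(X), fold_id, draws[[i]],
                      seed = derive_seed(seed, paste0("grid_eval", i)))
  }, numeric(1))
  if (all(is.na(scores))) stop_data("no hyperparameter draw produced a valid fit")
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  evaluated <- data.frame(draw = seq_along(draws), score = scores)
  evaluated$params <- vapply(draws, function(d) {
    if (length(d) == 0) "(defaults)" else
      paste(sprintf("%s=%s", names(d), vapply(d, function(v) format(v, digits = 4),
                                              character(1))), collapse = ", ")
  }, character(1))
  list(best_params = draws[[best]], best_score = scores[[best]], evaluated = evaluated)
}
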