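# Ensemble construction: soft/hard voting and stacking, plus greedy
# member selection scored by cross-validated ensemble AUC-ROC.

#' Build an ensemble from fitted members
#'
#' @param members list of fitted `vfipred_model` objects (each carries its
#'   own selected features).
#' @param strategy `"soft_vote"` (mean of member probabilities),
#'   `"hard_vote"` (majority label; ties resolve to the positive class, with
#'   a message), or `"stacked"` (meta-learner over member probabilities).
#' @param meta_model fitted meta-learner for `"stacked"` (see
#'   [fit_stacked_ensemble()]).
#' @return object of class `ensemble_spec`.
#' @export
build_ensemble <- function(members, strategy = c("soft_vote", "hard_vote", "stacked"),
                           meta_model = NULL) {
  strategy <- match.arg(strategy)
  if (length(members) < 1) stop_validation("an ensemble needs at least one member")
  if (!all(vapply(members, inherits, logical(1), "vfipred_model"))) {
    stop_validation("members must be fitted vfipred_model objects")
  }
  if (strategy == "stacked" && is.null(meta_model)) {
    stop_validation("stacked ensembles need a fitted meta_model")
  }
  structure(list(members = members, strategy = strategy, meta_model = meta_model),
            class = "ensemble_spec")
}

#' Predict with an ensemble
#'
#' @param spec an `ensemble_spec`.
#' @param X feature data frame holding every member's features.
#' @param threshold member-level decision threshold for hard voting.
#' @return numeric vector: soft vote returns the mean member probability,
#'   hard vote the majority label (0/1), stacking the meta-learner's
#'   probability.
#' @export
predict_ensemble <- function(spec, X, threshold = 0.5) {
  stopifnot(inherits(spec, "ensemble_spec"))
  probs <- vapply(spec$members, function(m) predict_prob(m, X), numeric(nrow(X)))
  if (nrow(X) == 1) probs <- matrix(probs, nrow = 1)
  switch(spec$strategy,
    soft_vote = rowMeans(probs),
    hard_vote = {
      votes <- rowMeans(probs >= threshold)
      ties <- abs(votes - 0.5) < 1e-12
      if (any(ties)) message(sprintf("%d hard-vote tie(s) resolved to the positive class",
                                     sum(ties)))
      as.numeric(votes >= 0.5)
    },
    stacked = {
      meta_X <- as.data.frame(probs)
      colnames(meta_X) <- paste0("member_", seq_along(spec$members))
      predict_prob(spec$meta_model, meta_X)
    })
}

#' Fit a stacked ensemble with out-of-fold member probabilities
#'
#' Members are refit on each training fold and their held-out probabilities
#' collected, so the logistic-regression meta-learner never sees
#' probabilities produced by a model trained on the same rows (avoids
#' leakage). Final members are refit on all rows.
#'
#' @param configs list of [model_config()]s for the members.
#' @param X feature data frame.
#' @param y binary labels.
#' @param folds folds used to generate out-of-fold probabilities.
#' @param seed master seed.
#' @return an `ensemble_spec` with strategy `"stacked"`.
#' @export
fit_stacked_ensemble <- function(configs, X, y, folds = 5, seed = 1L) {
  y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, "stack_folds"))
  oof <- matrix(NA_real_, nrow(X), length(configs))
  for (kf in seq_len(folds)) {
    train <- which(fold_id != kf)
    test <- which(fold_id == kf)
    for (j in seq_along(configs)) {
      cfg <- configs[[j]]
      cfg$seed <- derive_seed(seed, sprintf("stack_f%d_m%d", kf, j))
      model <- fit_model(cfg, X[train, , drop = FALSE], y[train])
      oof[test, j] <- predict_prob(model, X[test, , drop = FALSE])
    }
  }
  meta_X <- as.data.frame(oof)
  colnames(meta_X) <- paste0("member_", seq_along(configs))
  meta <- fit_model(model_config("logistic_regression",
                                 seed = derive_seed(seed, "stack_meta")),
                    meta_X, y)
  members <- lapply(seq_along(configs), function(j) {
    cfg <- configs[[j]]
    cfg$seed <- derive_seed(seed, sprintf("stack_final_m%d", j))
    fit_model(cfg, X, y)
  })
  build_ensemble(members, "stacked", meta_model = meta)
}

# Cross-validated AUC of a soft-vote ensemble over the given member configs:
# members are refit inside each fold and their held-out probabilities
# averaged.
cv_score_ensemble <- function(configs, X, y, fold_id, seed = 1L) {
  k <- max(fold_id)
  scores <- numeric(k)
  for (kf in seq_len(k)) {
    train <- which(fold_id != kf)
    test <- which(fold_id == kf)
    probs <- vapply(seq_along(configs), function(j) {
      cfg <- configs[[j]]
      cfg$seed <- derive_seed(seed, sprintf("ens_f%d_m%d", kf, j))
      model <- fit_model(cfg, X[train, , drop = FALSE], y[train])
      predict_prob(model, X[test, , drop = FALSE])
    }, numeric(length(test)))
    if (length(test) == 1) probs <- matrix(probs, nrow = 1)
    scores[kf] <- auc_roc(y[test], rowMeans(probs))
  }
  mean(scores)
}

#' Greedy ensemble member selection
#'
#' Starting from the best singleton, iteratively adds the candidate whose
#' inclusion maximizes the cross-validated soft-vote AUC-ROC of the
#' ensemble; the best-scoring subset found along the way is returned (its
#' size emerges from the search, it is not capped). Candidates are
#' identified by name; ties break by candidate order.
#'
#' @param candidates named list of [model_config()]s (typically the
#'   per-algorithm winners of selection + hyperparameter search).
#' @param X feature data frame.
#' @param y binary labels.
#' @param folds CV folds used for scoring.
#' @param seed master seed.
#' @return list with `member_names`, `configs` (the selected subset),
#'   `best_score`, `trace`.
#' @export
greedy_ensemble_selection <- function(candidates, X, y, folds = 5, seed = 1L) {
  if (length(candidates) < 1) stop_validation("need at least one candidate model")
  if (is.null(names(candidates))) names(candidates) <- paste0("m", seq_along(candidates))
  y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, "ens_folds"))

  remaining <- names(candidates)
  chosen <- character(0)
  best_score <- -Inf
  best_subset <- character(0)
  trace <- data.frame(step = integer(0), member = character(0), score = numeric(0))
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    scores <- vapply(remaining, function(nm) {
      cv_score_ensemble(candidates[c(chosen, nm)], X, y, fold_id,
                        seed = derive_seed(seed, paste0("ens_step", step)))
    }, numeric(1))
    pick <- which.max(scores)
    chosen <- c(chosen, remaining[pick])
    trace <- rbind(trace, data.frame(step = step, member = remaining[pick],
                                     score = scores[[pick]]))
    if (scores[[pick]] > best_score) {
      best_score <- scores[[pick]]
      best_subset <- chosen
    }
    remaining <- remaining[-pick]
  }
  list(member_names = best_subset, configs = candidates[best_subset],
       best_score = best_score, trace = trace)
}
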