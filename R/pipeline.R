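# The end-to-end training protocol: split-aware dataset, per-algorithm
# greedy feature selection + random hyperparameter search + repeated CV,
# greedy soft-vote ensembling, and held-out evaluation.

#' Split-aware variant dataset
#'
#' Binds a feature matrix to binary labels and a train/test split. Test rows
#' are locked: [testing()] refuses to return them until [finalize()] is
#' called, which keeps every selection code path (features,
#' hyperparameters, ensemble members) away from held-out data by
#' construction.
#'
#' @param features numeric feature data frame (rownames = variants).
#' @param labels binary labels (0/1), one per row.
#' @param split character vector of `"train"` / `"test"` / `"unassigned"`.
#' @return object of class `variant_dataset`.
#' @export
variant_dataset <- function(features, labels, split) {
  n <- nrow(features)
  labels <- as.integer(labels)
  if (length(labels) != n || length(split) != n) {
    stop_validation("features, labels and split must agree in length")
  }
  if (!all(labels %in% c(0L, 1L))) stop_validation("labels must be binary 0/1")
  if (!all(split %in% c("train", "test", "unassigned"))) {
    stop_validation("split values must be train/test/unassigned")
  }
  structure(list(features = features, labels = labels, split = split,
                 finalized = FALSE),
            class = "variant_dataset")
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat(sprintf("<variant_dataset> %d variants (%d train / %d test / %d unassigned), %d features%s\n",
              nrow(x$features), sum(x$split == "train"), sum(x$split == "test"),
              sum(x$split == "unassigned"), ncol(x$features),
              if (x$finalized) ", finalized" else ""))
  invisible(x)
}

#' Training rows of a dataset
#' @param ds a `variant_dataset`.
#' @return list with `X` and `y`.
#' @export
training <- function(ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  idx <- ds$split == "train"
  list(X = ds$features[idx, , drop = FALSE], y = ds$labels[idx])
}

#' Unlock the held-out test rows
#'
#' Must be called explicitly — and only after all selection is done — before
#' [testing()] will return the test rows.
#' @param ds a `variant_dataset`.
#' @return the dataset with the test rows unlocked.
#' @export
finalize <- function(ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  ds$finalized <- TRUE
  ds
}

#' Held-out test rows of a finalized dataset
#' @param ds a finalized `variant_dataset`.
#' @return list with `X` and `y`.
#' @export
testing <- function(ds) {
  stopifnot(inherits(ds, "variant_dataset"))
  if (!ds$finalized) {
    stop_validation("test rows are locked; call finalize() once model selection is complete")
  }
  idx <- ds$split == "test"
  list(X = ds$features[idx, , drop = FALSE], y = ds$labels[idx])
}

# Repeated stratified CV of a soft-vote ensemble (members refit per split).
repeated_cv_ensemble <- function(X, y, configs, folds = 5, repeats = 25,
                                 seed = 1L, threshold = 0.5) {
  y <- as.integer(y)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  split_rows <- list(); pred_rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, seed = derive_seed(seed, paste0("ens_rep", r)))
    for (kf in seq_len(folds)) {
      train <- which(fold_id != kf); test <- which(fold_id == kf)
      probs <- vapply(seq_along(configs), function(j) {
        cfg <- configs[[j]]
        cfg$seed <- derive_seed(seed, sprintf("enscv_r%d_f%d_m%d", r, kf, j))
        model <- fit_model(cfg, X[train, , drop = FALSE], y[train])
        predict_prob(model, X[test, , drop = FALSE])
      }, numeric(length(test)))
      if (length(test) == 1) probs <- matrix(probs, nrow = 1)
      p <- rowMeans(probs)
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
  metric_cols <- c("auc_roc", "balanced_accuracy", "sensitivity", "specificity")
  summ <- data.frame(metric = metric_cols,
                     mean = vapply(metric_cols, function(m) mean(splits[[m]]), numeric(1)),
                     sd = vapply(metric_cols, function(m) stats::sd(splits[[m]]), numeric(1)),
                     row.names = NULL)
  structure(list(splits = splits, summary = summ,
                 predictions = do.call(rbind, pred_rows),
                 folds = folds, repeats = repeats, threshold = threshold,
                 algorithm = "soft_vote_ensemble"),
            class = "cv_report")
}

#' Run the full pathogenicity training protocol
#'
#' For each algorithm: forward greedy feature selection, random
#' hyperparameter search on the selected features, then repeated stratified
#' cross-validation. The per-algorithm winners become candidates for greedy
#' soft-vote ensemble selection; the chosen ensemble is itself assessed by
#' repeated CV, and its members are finally refit on all training rows.
#' Only training rows are ever touched; the returned bundle carries every
#' intermediate report.
#'
#' @param ds a `variant_dataset` (test rows stay locked throughout).
#' @param algorithms zoo members to train.
#' @param n_draws random hyperparameter draws per algorithm.
#' @param folds CV folds for selection and search.
#' @param repeats repeats for the repeated-CV performance estimates.
#' @param patience greedy-selection patience.
#' @param seed master seed; all stage seeds derive from it.
#' @param threshold decision threshold stored in the bundle.
#' @param task label recorded in the bundle (`"pathogenicity"` or
#'   `"severity"`).
#' @return object of class `vfipred_bundle`.
#' @export
train_pathogenicity <- function(ds,
                                algorithms = c("logistic_regression", "svm",
                                               "random_forest"),
                                n_draws = 10, folds = 5, repeats = 25,
                                patience = 10, seed = 1L, threshold = 0.5,
                                task = "pathogenicity") {
  tr <- training(ds)
  X <- tr$X; y <- tr$y
  candidates <- list()
  algo_reports <- list()
  for (algo in algorithms) {
    sel <- greedy_feature_selection(X, y, algo,
                                    hyperparameters = selection_hyperparameters(algo),
                                    patience = patience, folds = folds,
                                    seed = derive_seed(seed, paste0("sel_", algo)))
    if (length(sel$selected) == 0) next
    Xs <- X[, sel$selected, drop = FALSE]
    search <- random_grid_search(Xs, y, algo, n_draws = n_draws, folds = folds,
                                 seed = derive_seed(seed, paste0("grid_", algo)))
    cfg <- model_config(algo, hyperparameters = search$best_params,
                        selected_features = sel$selected,
                        seed = derive_seed(seed, paste0("cv_", algo)))
    report <- repeated_stratified_cv(X, y, cfg, folds = folds, repeats = repeats,
                                     seed = derive_seed(seed, paste0("cvrep_", algo)),
                                     threshold = threshold)
    candidates[[algo]] <- cfg
    algo_reports[[algo]] <- list(selection = sel, search = search, cv = report)
  }
  if (length(candidates) == 0) stop_data("no algorithm produced a usable model")

  ens <- greedy_ensemble_selection(candidates, X, y, folds = folds,
                                   seed = derive_seed(seed, "ens_sel"))
  ens_report <- repeated_cv_ensemble(X, y, ens$configs, folds = folds,
                                     repeats = repeats,
                                     seed = derive_seed(seed, "ens_cv"),
                                     threshold = threshold)
  members <- lapply(seq_along(ens$configs), function(j) {
    cfg <- ens$configs[[j]]
    cfg$seed <- derive_seed(seed, sprintf("final_m%d", j))
    fit_model(cfg, X, y)
  })
  names(members) <- ens$member_names
  spec <- build_ensemble(members, "soft_vote")
  structure(list(task = task, ensemble = spec,
                 member_configs = ens$configs,
                 algorithm_reports = algo_reports,
                 ensemble_selection = ens[c("member_names", "best_score", "trace")],
                 cv_report = ens_report,
                 threshold = threshold, seed = seed,
                 feature_names = colnames(X),
                 version = as.character(utils::packageVersion("vfipred"))),
            class = "vfipred_bundle")
}

#' @export
print.vfipred_bundle <- function(x, ...) {
  cat(sprintf("<vfipred_bundle> task=%s, ensemble of %d member(s): %s\n",
              x$task, length(x$ensemble$members),
              paste(names(x$ensemble$members), collapse = ", ")))
  print(x$cv_report)
  invisible(x)
}

#' Predict probabilities (and labels) with a trained bundle
#'
#' @param object a `vfipred_bundle`.
#' @param newdata feature data frame.
#' @param ... unused.
#' @return data frame with `variant`, `score`, `threshold`, `label`.
#' @export
predict.vfipred_bundle <- function(object, newdata, ...) {
  missing <- setdiff(unique(unlist(lapply(object$ensemble$members, `[[`, "features"))),
                     colnames(newdata))
  if (length(missing) > 0) {
    stop_data("feature(s) missing from input: %s", paste(missing, collapse = ", "))
  }
  score <- predict_ensemble(object$ensemble, newdata)
  pos <- if (object$task == "severity") "severe" else "pathogenic"
  neg <- if (object$task == "severity") "benign" else "tolerated"
  data.frame(variant = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
             score = score, threshold = object$threshold,
             label = ifelse(score >= object$threshold, pos, neg),
             stringsAsFactors = FALSE)
}

#' Evaluate a bundle on labeled data
#'
#' @param bundle a `vfipred_bundle`.
#' @param X feature data frame.
#' @param y binary labels.
#' @return list with the metric quartet and the per-variant predictions.
#' @export
evaluate_bundle <- function(bundle, X, y) {
  preds <- predict(bundle, X)
  m <- compute_metrics(as.integer(y), preds$score, bundle$threshold)
  list(metrics = m, predictions = cbind(preds, truth = as.integer(y)))
}

#' Save / load a fitted bundle
#' @param bundle a `vfipred_bundle`.
#' @param path destination file.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "vfipred_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @return `load_bundle` returns the `vfipred_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop_data("bundle not found: %s", path)
  b <- readRDS(path)
  if (!inherits(b, "vfipred_bundle")) stop_data("%s is not a vfipred model bundle", path)
  b
}
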