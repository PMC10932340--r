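# Shapley-value feature attribution: exact closed form for linear members,
# exact tree-path contributions for gradient boosting, and a
# permutation-sampling estimator (probability scale) for everything else.
# The permutation estimator telescopes along each sampled chain, so
# local accuracy (base + sum of attributions = model output) holds to
# numerical precision for every method.

#' Shapley attributions for a fitted model or ensemble
#'
#' @param model a `vfipred_model`, an `ensemble_spec`, a `vfipred_bundle`,
#'   or a prediction `function(X) -> probabilities`.
#' @param X feature data frame of samples to explain; for fitted models its
#'   columns must cover the model's features.
#' @param background reference data frame (typically the training matrix);
#'   subsampled to `max_background` rows with `seed` when larger.
#' @param method `"auto"` picks the exact linear form for logistic
#'   regression, exact tree-path contributions for gradient boosting, and
#'   permutation sampling otherwise.
#' @param nsim permutations per sample for the sampling estimator.
#' @param max_background background rows kept for the sampling estimator.
#' @param seed seed for permutation and background sampling.
#' @return object of class `attribution_report`: list with `phi` (samples x
#'   features), `base_value`, `prediction`, `scale` (`"log_odds"` or
#'   `"probability"`), `feature_values`, `method`.
#' @export
attribute_model <- function(model, X, background = X,
                            method = c("auto", "linear", "tree", "sampling"),
                            nsim = 16, max_background = 200, seed = 1L) {
  method <- match.arg(method)
  if (inherits(model, "vfipred_bundle")) model <- model$ensemble
  if (inherits(model, "vfipred_model")) {
    missing <- setdiff(model$features, colnames(X))
    if (length(missing) > 0) {
      stop_validation("feature names mismatch; missing: %s", paste(missing, collapse = ", "))
    }
    if (method == "auto") {
      method <- switch(model$algorithm,
                       logistic_regression = "linear",
                       gradient_boosting = "tree",
                       "sampling")
    }
  } else if (method %in% c("linear", "tree")) {
    stop_validation("exact '%s' attribution needs a fitted vfipred_model", method)
  } else {
    method <- "sampling"
  }

  switch(method,
    linear = attribute_linear(model, X, background),
    tree = attribute_xgb(model, X),
    sampling = attribute_sampling(model, X, background, nsim, max_background, seed))
}

# Exact Shapley values of an additive (logistic-link) model with respect to
# a background: phi_i = w_i * (x_i - mean(background_i)), on the log-odds
# scale where the model truly is additive.
attribute_linear <- function(model, X, background) {
  stopifnot(model$algorithm == "logistic_regression")
  co <- stats::coef(model$fit)
  co[is.na(co)] <- 0
  w <- co[model$features]
  w[is.na(w)] <- 0
  Xm <- as_matrix_X(X[, model$features, drop = FALSE])
  bg_mean <- colMeans(as_matrix_X(background[, model$features, drop = FALSE]))
  phi <- sweep(Xm, 2, bg_mean) %*% diag(w, nrow = length(w))
  colnames(phi) <- model$features
  base <- unname(co["(Intercept)"] + sum(w * bg_mean))
  new_attribution_report(phi, base, base + rowSums(phi), "log_odds",
                         X[, model$features, drop = FALSE], "linear")
}

# Exact tree-path contributions from xgboost (log-odds scale); the bias
# column is the base value (background-independent).
attribute_xgb <- function(model, X) {
  stopifnot(model$algorithm == "gradient_boosting")
  Xm <- as_matrix_X(X[, model$features, drop = FALSE])
  contrib <- stats::predict(model$fit, Xm, type = "contrib")
  bias_col <- which(colnames(contrib) == "(Intercept)")
  phi <- contrib[, -bias_col, drop = FALSE]
  base <- unname(contrib[1, bias_col])
  new_attribution_report(phi, base, base + rowSums(phi), "log_odds",
                         X[, model$features, drop = FALSE], "tree")
}

# Permutation-sampling Shapley estimate on the probability scale. For each
# sample and each sampled permutation, features are switched from background
# to the explained value one at a time; successive prediction differences
# are credited to the switched feature. Marginal contributions telescope,
# so base + rowSums(phi) equals the model output exactly.
attribute_sampling <- function(model, X, background, nsim, max_background, seed) {
  predict_fun <- if (is.function(model)) {
    model
  } else if (inherits(model, "ensemble_spec")) {
    function(M) predict_ensemble(model, M)
  } else {
    function(M) predict_prob(model, M)
  }
  feats <- colnames(X)
  p <- length(feats)
  bg <- background[, feats, drop = FALSE]
  if (nrow(bg) > max_background) {
    keep <- with_seed(derive_seed(seed, "shap_bg"),
                      sample.int(nrow(bg), max_background))
    bg <- bg[keep, , drop = FALSE]
  }
  B <- nrow(bg)
  n <- nrow(X)
  phi <- matrix(0, n, p, dimnames = list(rownames(X), feats))
  base <- mean(predict_fun(bg))
  for (i in seq_len(n)) {
    x <- X[i, , drop = FALSE]
    acc <- numeric(p)
    for (s in seq_len(nsim)) {
      ord <- with_seed(derive_seed(seed, sprintf("perm_%d_%d", i, s)), sample.int(p))
      # chain of (p + 1) blocks of B rows: background with the first k
      # features (in permutation order) replaced by x
      chain <- bg[rep(seq_len(B), p + 1), , drop = FALSE]
      for (k in seq_len(p)) {
        cols <- ord[seq_len(k)]
        rows <- (k * B + 1):((k + 1) * B)
        chain[rows, cols] <- x[rep(1, B), cols]
      }
      v <- predict_fun(chain)
      block_means <- vapply(seq_len(p + 1), function(k) {
        mean(v[((k - 1) * B + 1):(k * B)])
      }, numeric(1))
      acc[ord] <- acc[ord] + diff(block_means)
    }
    phi[i, ] <- acc / nsim
  }
  new_attribution_report(phi, base, base + rowSums(phi), "probability", X, "sampling")
}

new_attribution_report <- function(phi, base, prediction, scale, feature_values, method) {
  structure(list(phi = phi, base_value = base, prediction = as.numeric(prediction),
                 scale = scale, feature_values = feature_values, method = method),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d sample(s) x %d feature(s), %s method, %s scale\n",
              nrow(x$phi), ncol(x$phi), x$method, x$scale))
  invisible(x)
}

#' Rank features by mean absolute Shapley value
#'
#' @param report an `attribution_report`.
#' @return data frame with `feature`, `mean_abs_shap`, `rank`, sorted by
#'   decreasing mean absolute attribution (ties broken by feature name).
#' @export
summarize_attribution <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  if (ncol(report$phi) == 0) stop_validation("empty attribution report")
  m <- colMeans(abs(report$phi))
  ord <- order(-m, names(m))
  data.frame(feature = names(m)[ord], mean_abs_shap = unname(m[ord]),
             rank = seq_along(m), stringsAsFactors = FALSE)
}

#' Long-format export for beeswarm plots
#'
#' @param report an `attribution_report`.
#' @return data frame with one row per (sample, feature): `sample`,
#'   `feature`, `shap_value`, `feature_value`.
#' @export
beeswarm_data <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  n <- nrow(report$phi); p <- ncol(report$phi)
  samples <- rownames(report$phi) %||% as.character(seq_len(n))
  data.frame(
    sample = rep(samples, times = p),
    feature = rep(colnames(report$phi), each = n),
    shap_value = as.vector(report$phi),
    feature_value = as.vector(as.matrix(report$feature_values[, colnames(report$phi),
                                                              drop = FALSE])),
    stringsAsFactors = FALSE
  )
}
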