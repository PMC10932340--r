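# The model zoo: a uniform fit/predict interface over established
# implementations (glm, e1071, ranger, xgboost, MASS, kernlab), plus an
# in-package k-nearest-neighbour probability model.

MODEL_ZOO <- c("logistic_regression", "svm", "random_forest",
               "gradient_boosting", "knn", "lda", "naive_bayes",
               "gaussian_process")

#' Model configuration
#'
#' @param algorithm one of `logistic_regression`, `svm` (probability-
#'   calibrated RBF), `random_forest`, `gradient_boosting` (xgboost), `knn`,
#'   `lda`, `naive_bayes` (Gaussian), `gaussian_process`.
#' @param hyperparameters named list understood by the backing fit.
#' @param selected_features ordered feature names used at fit time (`NULL`
#'   means all columns passed to [fit_model()]).
#' @param seed integer seed for the stochastic fits.
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm, hyperparameters = list(),
                         selected_features = NULL, seed = 1L) {
  if (!algorithm %in% MODEL_ZOO) {
    stop_validation("unknown algorithm '%s'; registered zoo: %s",
                    algorithm, paste(MODEL_ZOO, collapse = ", "))
  }
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 selected_features = selected_features, seed = as.integer(seed)),
            class = "model_config")
}

as_matrix_X <- function(X) {
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

#' Fit a classifier from the zoo
#'
#' @param config a [model_config()], or an algorithm name.
#' @param X numeric feature data frame / matrix (training rows).
#' @param y binary labels, 0 = tolerated/benign, 1 = pathogenic/severe.
#' @param ... overrides merged into the config's hyperparameters.
#' @return fitted object of class `vfipred_model`.
#' @export
fit_model <- function(config, X, y, ...) {
  if (is.character(config)) config <- model_config(config)
  hp <- utils::modifyList(config$hyperparameters, list(...))
  feats <- config$selected_features %||% colnames(X)
  missing <- setdiff(feats, colnames(X))
  if (length(missing) > 0) {
    stop_validation("feature(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  if (length(feats) == 0) stop_validation("selected_features must be non-empty at fit time")
  X <- X[, feats, drop = FALSE]
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_validation("labels must be binary 0/1")
  if (length(unique(y)) < 2) stop_validation("both classes must be present to fit")

  fit <- with_seed(config$seed,
                   fit_backend(config$algorithm, as_matrix_X(X), y, hp, config$seed))
  structure(list(algorithm = config$algorithm, fit = fit, features = feats,
                 hyperparameters = hp, seed = config$seed),
            class = "vfipred_model")
}

fit_backend <- function(algorithm, X, y, hp, seed = 1L) {
  switch(algorithm,
    logistic_regression = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                  control = list(maxit = hp$maxit %||% 50)))
    },
    svm = {
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = hp$cost %||% 1,
                 gamma = hp$gamma %||% (1 / ncol(X)),
                 probability = TRUE, scale = apply(X, 2, stats::sd) > 0)
    },
    random_forest = {
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     probability = TRUE,
                     num.trees = hp$num.trees %||% 300,
                     mtry = max(1, min(ncol(X), round((hp$mtry_frac %||% 0.6) * ncol(X)))),
                     min.node.size = hp$min.node.size %||% 5,
                     seed = seed,
                     num.threads = 1)
    },
    gradient_boosting = {
      xgboost::xgboost(X, factor(y, levels = c(0, 1)),
                       nrounds = hp$nrounds %||% 100,
                       max_depth = hp$max_depth %||% 4,
                       learning_rate = hp$eta %||% 0.1,
                       subsample = hp$subsample %||% 1,
                       objective = "binary:logistic",
                       nthreads = 1, verbosity = 0,
                       seed = seed)
    },
    knn = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      list(train = scale(X, ctr, scl), y = y, k = hp$k %||% 7,
           center = ctr, scale = scl)
    },
    lda = {
      # collinear one-hot blocks are expected; posteriors remain usable
      suppressWarnings(MASS::lda(X, grouping = factor(y, levels = c(0, 1))))
    },
    naive_bayes = {
      e1071::naiveBayes(data.frame(X, check.names = FALSE),
                        factor(y, levels = c(0, 1)),
                        laplace = hp$laplace %||% 0)
    },
    gaussian_process = {
      kp <- if (is.null(hp$sigma)) "automatic" else list(sigma = hp$sigma)
      suppressMessages(
        kernlab::gausspr(X, factor(y, levels = c(0, 1)), type = "classification",
                         kernel = "rbfdot", kpar = kp, var = hp$var %||% 1)
      )
    },
    stop_validation("unknown algorithm '%s'", algorithm))
}

#' Predicted probability of the positive class
#'
#' @param model a `vfipred_model`.
#' @param X feature data frame / matrix holding (at least) the model's
#'   feature columns.
#' @return numeric vector of P(class = 1).
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "vfipred_model"))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) > 0) {
    stop_validation("feature(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  Xm <- as_matrix_X(X[, model$features, drop = FALSE])
  fit <- model$fit
  p <- switch(model$algorithm,
    logistic_regression = {
      # rank-deficient fits (collinear one-hots) still predict fine here
      suppressWarnings(
        as.numeric(stats::predict(fit, newdata = data.frame(Xm, check.names = FALSE),
                                  type = "response")))
    },
    svm = {
      pr <- stats::predict(fit, Xm, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = {
      stats::predict(fit, data = Xm, num.threads = 1)$predictions[, "1"]
    },
    gradient_boosting = {
      as.numeric(stats::predict(fit, Xm, type = "response"))
    },
    knn = {
      d2 <- outer(rowSums(scale(Xm, fit$center, fit$scale)^2),
                  rowSums(fit$train^2), `+`) -
        2 * scale(Xm, fit$center, fit$scale) %*% t(fit$train)
      k <- min(fit$k, length(fit$y))
      apply(d2, 1, function(row) {
        nn <- order(row)[seq_len(k)]
        mean(fit$y[nn])
      })
    },
    lda = {
      stats::predict(fit, Xm)$posterior[, "1"]
    },
    naive_bayes = {
      stats::predict(fit, data.frame(Xm, check.names = FALSE), type = "raw")[, "1"]
    },
    gaussian_process = {
      kernlab::predict(fit, Xm, type = "probabilities")[, "1"]
    },
    stop_validation("unknown algorithm '%s'", model$algorithm))
  unname(as.numeric(p))
}

#' @export
print.vfipred_model <- function(x, ...) {
  cat(sprintf("<vfipred_model> %s on %d feature(s)\n", x$algorithm, length(x$features)))
  invisible(x)
}

#' Screening hyperparameters used during greedy feature selection
#'
#' Feature screening evaluates hundreds of candidate fits, so the ensemble
#' learners run with reduced capacity there (fewer trees / boosting rounds);
#' the full defaults and the searched space apply from the hyperparameter
#' search onwards.
#'
#' @param algorithm zoo member name.
#' @return named list of hyperparameters.
#' @export
selection_hyperparameters <- function(algorithm) {
  switch(algorithm,
         random_forest = list(num.trees = 100),
         gradient_boosting = list(nrounds = 60),
         list())
}

#' Default random-search hyperparameter space for an algorithm
#'
#' Each entry is a sampler `function(n)` drawing `n` values. Spaces follow
#' conventional ranges (regularization and kernel widths log-uniform, tree
#' counts and depths over small grids) and can be replaced wholesale in
#' [random_grid_search()].
#'
#' @param algorithm zoo member name.
#' @return named list of sampler functions (empty list when the algorithm has
#'   nothing worth searching at this scale).
#' @export
default_search_space <- function(algorithm) {
  switch(algorithm,
    logistic_regression = list(),
    lda = list(),
    svm = list(
      cost = function(n) 10^stats::runif(n, -1, 2),
      gamma = function(n) 10^stats::runif(n, -3, 0)
    ),
    random_forest = list(
      num.trees = function(n) sample(c(200L, 400L, 600L, 800L), n, replace = TRUE),
      mtry_frac = function(n) stats::runif(n, 0.2, 0.9),
      min.node.size = function(n) sample(c(1L, 3L, 5L, 10L), n, replace = TRUE)
    ),
    gradient_boosting = list(
      nrounds = function(n) sample(seq(50L, 300L, by = 50L), n, replace = TRUE),
      eta = function(n) 10^stats::runif(n, -2, -0.5),
      max_depth = function(n) sample(2:8, n, replace = TRUE),
      subsample = function(n) stats::runif(n, 0.6, 1)
    ),
    knn = list(k = function(n) sample(seq(3L, 25L, by = 2L), n, replace = TRUE)),
    naive_bayes = list(laplace = function(n) sample(c(0, 1), n, replace = TRUE)),
    gaussian_process = list(sigma = function(n) 10^stats::runif(n, -2, 1)),
    stop_validation("unknown algorithm '%s'", algorithm))
}
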