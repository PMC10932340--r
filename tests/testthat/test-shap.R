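test_that("linear attribution matches the closed form w_i * (x_i - mean bg_i)", {
  # deterministic weights: fit on noiseless logistic-separable data, then
  # check the closed form against the fitted coefficients directly
  set.seed(51)
  X <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  y <- as.integer(X$x1 + 0.5 * rnorm(80) > 0)
  m <- fit_model(model_config("logistic_regression"), X, y)
  bg <- X
  att <- attribute_model(m, X[1:5, ], bg)
  expect_equal(att$scale, "log_odds")
  w <- coef(m$fit)[c("x1", "x2")]
  for (i in 1:5) {
    expect_equal(unname(att$phi[i, ]),
                 unname(w * (as.numeric(X[i, ]) - colMeans(bg))), tolerance = 1e-10)
  }
  # local accuracy on the link scale
  expect_equal(unname(att$base_value + rowSums(att$phi)),
               qlogis(predict_prob(m, X[1:5, ])), tolerance = 1e-8)
})

test_that("a model with weights (1, 0) at x = (2, 5) attributes (2, 0)", {
  # exact linear route: hand-built coefficient vector, background means (0, 0)
  fake <- structure(list(
    algorithm = "logistic_regression",
    fit = structure(list(coefficients = c("(Intercept)" = 0, x1 = 1, x2 = 0)),
                    class = "lm"),
    features = c("x1", "x2")), class = "vfipred_model")
  X <- data.frame(x1 = 2, x2 = 5)
  bg <- data.frame(x1 = c(-1, 1, 0), x2 = c(-2, 2, 0))  # means (0, 0)
  att <- attribute_model(fake, X, bg, method = "linear")
  expect_equal(unname(att$phi[1, ]), c(2, 0))
  expect_equal(att$base_value, 0)

  # sampling route on the same structure: the inert feature still gets zero
  f <- function(M) plogis(M[["x1"]])
  samp <- attribute_model(f, X, bg, nsim = 8, seed = 1)
  expect_equal(unname(samp$phi[1, "x2"]), 0, tolerance = 1e-12)
  expect_equal(unname(samp$phi[1, "x1"]), plogis(2) - mean(plogis(bg$x1)),
               tolerance = 1e-12)
})

test_that("a constant model attributes zero everywhere", {
  f <- function(M) rep(0.7, nrow(M))
  X <- data.frame(a = rnorm(6), b = rnorm(6))
  att <- attribute_model(f, X, X, nsim = 4, seed = 2)
  expect_equal(max(abs(att$phi)), 0)
  expect_equal(att$base_value, 0.7)
})

test_that("duplicated features share credit and ignored features get none", {
  # exact linear case: equal weights on identical columns receive equal
  # attribution, and a zero-weight feature receives none
  fake <- structure(list(
    algorithm = "logistic_regression",
    fit = structure(list(coefficients = c("(Intercept)" = 0.2, a = 0.7, b = 0.7,
                                          dummy = 0)), class = "lm"),
    features = c("a", "b", "dummy")), class = "vfipred_model")
  set.seed(53)
  x <- rnorm(60)
  X <- data.frame(a = x, b = x, dummy = rnorm(60))
  att <- attribute_model(fake, X[1:8, ], X, method = "linear")
  expect_equal(unname(att$phi[, "a"]), unname(att$phi[, "b"]))
  expect_equal(unname(att$phi[, "dummy"]), rep(0, 8))

  # the sampling estimator also zeroes a feature the model provably ignores
  samp <- attribute_model(function(M) plogis(M[["a"]] + M[["b"]]),
                          X[1:5, ], X, nsim = 20, seed = 3)
  expect_equal(unname(samp$phi[, "dummy"]), rep(0, 5), tolerance = 1e-12)
})

test_that("local accuracy holds exactly for sampled attributions of a forest", {
  syn <- tiny_synthetic()
  tr <- training(syn$dataset)
  keep <- c("vfi", "plddt", "conservation_entropy", "delta_hydrophobicity")
  m <- fit_model(model_config("random_forest", list(num.trees = 80), seed = 3),
                 tr$X[, keep], tr$y)
  att <- attribute_model(m, tr$X[1:12, keep], tr$X[, keep],
                         nsim = 6, max_background = 25, seed = 4)
  expect_equal(att$scale, "probability")
  expect_lt(max(abs(att$base_value + rowSums(att$phi) - att$prediction)), 1e-6)
  # prediction column matches the model's own output
  expect_equal(att$prediction, predict_prob(m, tr$X[1:12, keep]), tolerance = 1e-6)
})

test_that("gradient-boosting attribution uses exact tree contributions", {
  syn <- tiny_synthetic()
  tr <- training(syn$dataset)
  keep <- c("vfi", "plddt", "conservation_entropy")
  m <- fit_model(model_config("gradient_boosting", list(nrounds = 40), seed = 5),
                 tr$X[, keep], tr$y)
  att <- attribute_model(m, tr$X[1:10, keep], tr$X[, keep])
  expect_equal(att$method, "tree")
  expect_equal(att$scale, "log_odds")
  expect_equal(unname(att$base_value + rowSums(att$phi)),
               qlogis(predict_prob(m, tr$X[1:10, keep])), tolerance = 1e-4)
})

test_that("attribution summaries rank deterministically and export long format", {
  phi <- matrix(c(0.5, -0.5, 0.1, 0.3, 0.3, -0.1), nrow = 2,
                dimnames = list(c("s1", "s2"), c("big", "tie_a", "tie_b")))
  att <- vfipred:::new_attribution_report(
    phi, 0.4, 0.4 + rowSums(phi), "probability",
    as.data.frame(matrix(1:6, 2, dimnames = dimnames(phi))), "sampling")
  s <- summarize_attribution(att)
  expect_equal(s$feature[1], "big")
  expect_equal(s$feature[2:3], c("tie_a", "tie_b"))   # tie broken by name

  bw <- beeswarm_data(att)
  expect_equal(nrow(bw), 6L)
  expect_equal(bw$shap_value[bw$sample == "s1" & bw$feature == "big"], 0.5)

  # ranking is invariant to sample order
  rep_flip <- vfipred:::new_attribution_report(
    phi[2:1, ], 0.4, (0.4 + rowSums(phi))[2:1], "probability",
    as.data.frame(matrix(1:6, 2, dimnames = dimnames(phi)))[2:1, ], "sampling")
  expect_equal(summarize_attribution(rep_flip)$feature, s$feature)
})

test_that("feature-name mismatches are rejected", {
  set.seed(55)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  m <- fit_model(model_config("logistic_regression"), X, rep(c(0L, 1L), 10))
  expect_error(attribute_model(m, data.frame(a = rnorm(5)), X), "mismatch")
})
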