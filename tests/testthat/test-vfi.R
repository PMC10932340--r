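toy_alleles <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  allele_table(df)
}

test_that("source merging keeps the record from the larger panel", {
  tbl <- toy_alleles(list(
    list(variant = "W1R", allele_count = 3, total_alleles = 150000, source = "v2"),
    list(variant = "W1R", allele_count = 5, total_alleles = 280000, source = "v3"),
    list(variant = "W1C", allele_count = 2, total_alleles = 150000, source = "v2")
  ))
  merged <- merge_frequency_sources(tbl)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$source[merged$variant == "W1R"], "v3")
  expect_equal(merged$allele_count[merged$variant == "W1R"], 5L)
  # disjoint sources concatenate; a single source passes through unchanged
  expect_equal(merged$allele_count[merged$variant == "W1C"], 2L)
  single <- toy_alleles(list(list(variant = "W1R", allele_count = 1,
                                  total_alleles = 100, source = "v3")))
  expect_equal(nrow(merge_frequency_sources(single)), 1L)
})

test_that("position tolerance implements observed / (N * possible)", {
  # single Trp codon: 5 reachable missense variants (R, G, S, L, C)
  cds <- coding_sequence("TGG")
  tbl <- toy_alleles(list(
    list(variant = "W1R", allele_count = 20, total_alleles = 1000, source = "v3"),
    list(variant = "W1C", allele_count = 30, total_alleles = 1000, source = "v3")
  ))
  f <- position_tolerance(merge_frequency_sources(tbl), cds, N = 1000)
  expect_equal(f, 50 / (1000 * 5))

  # no observed variants -> 0; distinct-variant counting mode
  expect_equal(position_tolerance(merge_frequency_sources(toy_alleles(list(
    list(variant = "W1R", allele_count = 1, total_alleles = 10, source = "v3")))),
    coding_sequence("TGGTGG"), N = 10)[2], 0)
  f_var <- position_tolerance(merge_frequency_sources(tbl), cds, N = 1000,
                              count_mode = "variants")
  expect_equal(f_var, 2 / (1000 * 5))
})

test_that("saturated observation with N = 1 gives f = 1", {
  cds <- coding_sequence("TGG")
  pool <- possible_missense_variants(cds)
  tbl <- allele_table(data.frame(variant = pool$variant, allele_count = 1,
                                 total_alleles = 1, source = "v3"))
  f <- position_tolerance(merge_frequency_sources(tbl), cds, N = 1)
  expect_equal(f, 1)
})

test_that("the rational squash has its fixed point and stays in [0,1)", {
  for (alpha in c(0.001, 0.1, 1, 17)) {
    expect_equal(squash(alpha, alpha), 0.5)
    expect_equal(squash(3 * alpha, alpha), 0.75)
  }
  expect_equal(squash(0, 2), 0)
  expect_error(squash(1, 0), "positive")
  expect_error(squash(-1, 1), "non-negative")
  # strictly monotone, order preserving, bounded below 1
  f <- sort(runif(50, 0, 100))
  Fv <- squash(f, 0.3)
  expect_true(all(diff(Fv) > 0))
  expect_true(all(Fv >= 0 & Fv < 1))
})

test_that("the Gaussian kernel is symmetric, normalized, with the right decay", {
  k <- gaussian_kernel(2)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(unname(k[as.character(-3)]), unname(k[as.character(3)]))
  expect_equal(unname(k["2"] / k["0"]), exp(-0.5), tolerance = 1e-12)
  expect_length(gaussian_kernel(1, radius = 4), 9L)
  expect_error(gaussian_kernel(0), "positive")
  expect_error(gaussian_kernel(2, radius = 0), "positive integer")
})

test_that("VFI smoothing preserves constants and reproduces the kernel on an impulse", {
  v <- compute_vfi(rep(0.3, 40), sigma = 3)
  expect_equal(as.numeric(v), rep(0.3, 40), tolerance = 1e-12)

  L <- 101
  x <- numeric(L); x[51] <- 1
  v <- compute_vfi(x, sigma = 2)
  k <- gaussian_kernel(2)
  r <- (length(k) - 1) / 2
  expect_equal(as.numeric(v[(51 - r):(51 + r)]), unname(rev(k)), tolerance = 1e-12)
  expect_error(compute_vfi(numeric(0), 2), "at least one")
})

test_that("VFI equals the naive convolution oracle on random profiles", {
  set.seed(11)
  for (i in 1:30) {
    L <- sample(5:60, 1)
    x <- runif(L)
    sigma <- runif(1, 0.5, 4)
    k <- gaussian_kernel(sigma)
    expect_equal(as.numeric(compute_vfi(x, sigma)), oracle_convolve(x, k),
                 tolerance = 1e-12)
  }
})

test_that("a near-degenerate narrow kernel returns the input profile", {
  x <- runif(30)
  v <- compute_vfi(x, sigma = 0.05, radius = 1)
  expect_equal(as.numeric(v), x, tolerance = 1e-6)
})

test_that("increasing one allele count never decreases f, F or VFI", {
  cds <- coding_sequence("TGGATGAAACCC")
  pool <- possible_missense_variants(cds)
  set.seed(3)
  base <- allele_table(data.frame(variant = pool$variant,
                                  allele_count = rpois(nrow(pool), 2),
                                  total_alleles = 1000, source = "v3"))
  f0 <- position_tolerance(merge_frequency_sources(base), cds, N = 1000)
  F0 <- squash(f0, 0.002)
  v0 <- compute_vfi(F0, 2)
  for (i in sample(nrow(base), 5)) {
    bumped <- base
    bumped$allele_count[i] <- bumped$allele_count[i] + 10L
    f1 <- position_tolerance(merge_frequency_sources(bumped), cds, N = 1000)
    expect_true(all(f1 >= f0))
    F1 <- squash(f1, 0.002)
    expect_true(all(F1 >= F0))
    expect_true(all(as.numeric(compute_vfi(F1, 2)) >= as.numeric(v0) - 1e-14))
  }
})

test_that("the sliding-window score is the edge-renormalized running mean", {
  x <- c(0, 1, 0, 0, 0, 0, 0)
  expect_equal(sliding_window_score(x, 3), c(1/2, 1/3, 1/3, 0, 0, 0, 0))
  expect_equal(sliding_window_score(rep(0.4, 50), 31), rep(0.4, 50), tolerance = 1e-12)
  expect_error(sliding_window_score(x, 4), "odd")
  # identical to convolution with a uniform kernel of the same support
  set.seed(2)
  y <- runif(40)
  expect_equal(sliding_window_score(y, 7), oracle_convolve(y, rep(1/7, 7)),
               tolerance = 1e-12)
})

test_that("vfi_profile chains the full computation with auto alpha", {
  cds <- coding_sequence("TGGATGAAACCCGGGTTT")
  pool <- possible_missense_variants(cds)
  set.seed(8)
  tbl <- allele_table(data.frame(variant = pool$variant,
                                 allele_count = rpois(nrow(pool), 3),
                                 total_alleles = 2000, source = "v3"))
  prof <- vfi_profile(tbl, cds, sigma = 2, window = 3)
  expect_equal(names(prof), c("position", "f", "F", "vfi", "window31"))
  expect_equal(attr(prof, "alpha"), median(prof$f[prof$f > 0]))
  expect_equal(prof$F, squash(prof$f, attr(prof, "alpha")))
  expect_true(all(prof$vfi >= min(prof$F) - 1e-12 & prof$vfi <= max(prof$F) + 1e-12))
})
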