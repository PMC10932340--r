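# The Variant Frequency Index: per-position tolerance f, rational squash F,
# and Gaussian-kernel smoothing along the protein sequence.

#' Merge allele-frequency sources, discarding redundant records
#'
#' When a variant is reported by several releases (e.g. gnomAD v2 and v3),
#' only the record from the larger sequencing panel — the source with the
#' larger `total_alleles` — is kept, so each variant contributes exactly one
#' frequency.
#'
#' @param tbl an `allele_table` with a `source` column.
#' @return an `allele_table` with one row per variant.
#' @export
merge_frequency_sources <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl)
  ord <- order(tbl$variant, -tbl$total_alleles, -tbl$allele_count, tbl$source)
  out <- tbl[ord, , drop = FALSE]
  out <- out[!duplicated(out$variant), , drop = FALSE]
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Per-position tolerance f
#'
#' `f[p] = missense_observed[p] / (N * missense_possible[p])`, where
#' `missense_observed` is the summed allele count over observed missense
#' variants at position `p`, `missense_possible` the number of distinct
#' missense variants reachable by single-nucleotide substitution at that
#' codon, and `N` the gene-wide total-alleles denominator ("the total number
#' of sequences in the dataset"). Positions where no missense variant is
#' reachable get `f = 0` with a warning.
#'
#' @param merged allele table with one row per variant (see
#'   [merge_frequency_sources()]).
#' @param cds the gene's `coding_sequence` (supplies `missense_possible`).
#' @param N total-alleles denominator; defaults to the largest
#'   `total_alleles` in the merged table.
#' @param count_mode `"alleles"` (default) sums allele counts;
#'   `"variants"` counts distinct observed variants instead.
#' @return numeric vector `f` of length `codon_count`.
#' @export
position_tolerance <- function(merged, cds, N = NULL,
                               count_mode = c("alleles", "variants")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(cds, "coding_sequence"))
  L <- cds$codon_count
  if (nrow(merged) > 0 && anyDuplicated(merged$variant)) {
    stop_validation("allele table must hold one row per variant; run merge_frequency_sources() first")
  }
  if (nrow(merged) > 0 && any(merged$position > L)) {
    stop_data("allele table refers to positions beyond the %d-codon sequence", L)
  }
  if (is.null(N)) {
    if (nrow(merged) == 0) stop_validation("N must be given for an empty allele table")
    N <- max(merged$total_alleles)
  }
  if (!is.numeric(N) || N <= 0) stop_validation("N must be a positive number")
  possible <- missense_possible(cds)
  counts <- if (count_mode == "alleles") merged$allele_count else rep(1L, nrow(merged))
  observed <- numeric(L)
  if (nrow(merged) > 0) {
    agg <- tapply(counts, factor(merged$position, levels = seq_len(L)), sum)
    observed <- ifelse(is.na(agg), 0, agg)
  }
  if (any(possible == 0 & observed > 0)) {
    stop_data("observed variants at position(s) with no reachable missense variant")
  }
  if (any(possible == 0)) {
    warning(sprintf("no reachable missense variant at %d position(s); f set to 0",
                    sum(possible == 0)))
  }
  f <- numeric(L)
  ok <- possible > 0
  f[ok] <- observed[ok] / (N * possible[ok])
  f
}

#' Rational squash of the tolerance score
#'
#' `F = f / (f + alpha)` maps the non-negative tolerance onto `[0, 1)`;
#' `alpha` sets the curvature by fixing the point at which `F = 0.5`
#' (namely `f = alpha`). Strictly increasing in `f`.
#'
#' @param f non-negative tolerance value(s).
#' @param alpha positive curvature coefficient.
#' @return value(s) in `[0, 1)`.
#' @export
squash <- function(f, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    stop_validation("alpha must be a single positive number")
  }
  if (any(f < 0)) stop_validation("f must be non-negative")
  f / (f + alpha)
}

#' Default curvature coefficient
#'
#' The median of the non-zero per-position tolerances, which centers the
#' squash (`F = 0.5`) on a typical tolerated position of the gene.
#'
#' @param f per-position tolerance vector.
#' @return a positive scalar.
#' @export
alpha_auto <- function(f) {
  nz <- f[f > 0]
  if (length(nz) == 0) {
    warning("all per-position tolerances are zero; alpha defaults to 1")
    return(1)
  }
  stats::median(nz)
}

#' Normalized Gaussian kernel over integer offsets
#'
#' Weights proportional to `exp(-n^2 / (2 sigma^2))` for
#' `n = -radius..radius`, normalized to sum to one.
#'
#' @param sigma kernel standard deviation, in sequence positions.
#' @param radius kernel half-width; defaults to `ceiling(4 * sigma)`, which
#'   captures essentially all of the Gaussian mass.
#' @return numeric vector of length `2 * radius + 1`, named by offset.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop_validation("sigma must be a single positive number")
  }
  if (!is_count(radius)) stop_validation("radius must be a positive integer")
  n <- seq(-radius, radius)
  w <- exp(-n^2 / (2 * sigma^2))
  w <- w / sum(w)
  names(w) <- n
  w
}

# Convolve a per-position signal with a symmetric kernel; at the sequence
# ends the kernel is truncated to in-range positions and renormalized, so a
# constant signal is preserved everywhere.
convolve_profile <- function(x, kernel) {
  L <- length(x)
  radius <- (length(kernel) - 1L) %/% 2L
  out <- numeric(L)
  for (p in seq_len(L)) {
    lo <- max(1L, p - radius)
    hi <- min(L, p + radius)
    idx <- lo:hi
    w <- kernel[(idx - p) + radius + 1L]
    out[p] <- sum(w * x[idx]) / sum(w)
  }
  out
}

#' Gaussian-smoothed Variant Frequency Index profile
#'
#' Applies a discrete convolution of the squashed tolerance `F` with a
#' normalized Gaussian kernel, aggregating information from neighboring
#' sequence positions; nearer positions get more weight. At the ends the
#' kernel is truncated to in-range positions and renormalized.
#'
#' @param F per-position squashed tolerance (values in `[0, 1)`).
#' @param sigma Gaussian standard deviation, in positions.
#' @param radius kernel half-width; defaults to `ceiling(4 * sigma)`.
#' @return object of class `vfi_profile`: numeric vector of smoothed values
#'   with attributes `sigma`, `radius`, `edge_policy`.
#' @export
compute_vfi <- function(F, sigma = 2, radius = ceiling(4 * sigma)) {
  if (length(F) < 1) stop_validation("profile must have at least one position")
  k <- gaussian_kernel(sigma, radius)
  out <- convolve_profile(F, k)
  structure(out, sigma = sigma, radius = as.integer(radius),
            edge_policy = "truncate_renormalize", class = "vfi_profile")
}

#' Rectangular sliding-window (running-mean) score
#'
#' The MTR-style baseline: a running average over an odd window (default 31
#' residues, i.e. the 15 preceding and 15 following positions), truncated and
#' renormalized at the sequence ends. Equivalent to [compute_vfi()] with a
#' uniform kernel of the same support.
#'
#' @param F per-position values.
#' @param window odd window size `>= 3`.
#' @return numeric vector of running means.
#' @export
sliding_window_score <- function(F, window = 31) {
  if (!is_count(window) || window < 3 || window %% 2 == 0) {
    stop_validation("window must be an odd integer >= 3")
  }
  radius <- (window - 1L) %/% 2L
  k <- rep(1 / window, window)
  convolve_profile(F, k)
}

#' Build the full per-position profile from an allele table and CDS
#'
#' Convenience wrapper chaining [merge_frequency_sources()],
#' [position_tolerance()], [squash()], [compute_vfi()] and
#' [sliding_window_score()]; its output TSV (via
#' [write_position_profile()]) is the exchange format consumed by the
#' feature engine.
#'
#' @param alleles an `allele_table` (may hold several sources).
#' @param cds the gene's `coding_sequence`.
#' @param sigma Gaussian kernel standard deviation.
#' @param alpha curvature coefficient, or `"auto"` for the median of the
#'   non-zero tolerances.
#' @param radius kernel half-width.
#' @param N total-alleles denominator (default: largest panel after merging).
#' @param window sliding-window width for the rectangular baseline.
#' @param count_mode see [position_tolerance()].
#' @return data frame with columns `position`, `f`, `F`, `vfi`, `window31`,
#'   plus attributes `alpha`, `sigma`, `radius`, `N`.
#' @export
vfi_profile <- function(alleles, cds, sigma = 2, alpha = "auto",
                        radius = ceiling(4 * sigma), N = NULL, window = 31,
                        count_mode = c("alleles", "variants")) {
  merged <- merge_frequency_sources(alleles)
  f <- position_tolerance(merged, cds, N = N, count_mode = match.arg(count_mode))
  if (identical(alpha, "auto")) alpha <- alpha_auto(f)
  Fv <- squash(f, alpha)
  vfi <- compute_vfi(Fv, sigma = sigma, radius = radius)
  win <- sliding_window_score(Fv, window = window)
  out <- data.frame(position = seq_along(f), f = f, F = Fv,
                    vfi = as.numeric(vfi), window31 = win)
  attr(out, "alpha") <- alpha
  attr(out, "sigma") <- sigma
  attr(out, "radius") <- as.integer(radius)
  attr(out, "N") <- if (is.null(N) && nrow(merged) > 0) max(merged$total_alleles) else N
  out
}
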