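# Independent oracles and small fixture builders used across the suite.

# Brute-force single-nucleotide substitution classifier, written against
# seqinr's translation (independent of the package's Biostrings path):
# iterates the 9L substitutions one string at a time.
oracle_enumerate <- function(nt) {
  nt <- toupper(nt)
  L <- nchar(nt) %/% 3
  res <- list(nonsyn = 0L, stop = 0L, syn = 0L, missense_keys = character(0))
  if (L == 0) {
    return(list(nonsyn_substitutions = 0L, stop_introducing = 0L,
                distinct_missense_variants = 0L, synonymous = 0L))
  }
  for (i in seq_len(nchar(nt))) {
    ref_base <- substr(nt, i, i)
    for (b in setdiff(c("A", "C", "G", "T"), ref_base)) {
      mut <- nt
      substr(mut, i, i) <- b
      codon_idx <- (i - 1) %/% 3 + 1
      from <- seqinr::translate(strsplit(substr(nt, 3 * codon_idx - 2, 3 * codon_idx), "")[[1]])
      to <- seqinr::translate(strsplit(substr(mut, 3 * codon_idx - 2, 3 * codon_idx), "")[[1]])
      if (to == from) {
        res$syn <- res$syn + 1L
      } else if (to == "*") {
        res$stop <- res$stop + 1L
        res$nonsyn <- res$nonsyn + 1L
      } else {
        res$nonsyn <- res$nonsyn + 1L
        res$missense_keys <- c(res$missense_keys, paste0(codon_idx, to))
      }
    }
  }
  list(nonsyn_substitutions = res$nonsyn, stop_introducing = res$stop,
       distinct_missense_variants = length(unique(res$missense_keys)),
       synonymous = res$syn)
}

# Random stop-free coding sequence of `n_codon` codons.
random_cds_string <- function(n_codon) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codon, replace = TRUE), collapse = "")
}

# Naive O(L * m) double-loop convolution with truncated-and-renormalized
# edges; the reference for the package's kernel smoothing.
oracle_convolve <- function(x, weights) {
  L <- length(x)
  radius <- (length(weights) - 1) / 2
  out <- numeric(L)
  for (p in seq_len(L)) {
    num <- 0; den <- 0
    for (j in -radius:radius) {
      q <- p + j
      if (q >= 1 && q <= L) {
        w <- weights[j + radius + 1]
        num <- num + w * x[q]
        den <- den + w
      }
    }
    out[p] <- num / den
  }
  out
}

# Exhaustive threshold scan (all midpoints plus 0.5), maximizing balanced
# accuracy; returns the attained maximum.
oracle_best_bacc <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- 0.5
  if (length(u) > 1) cands <- c((u[-1] + u[-length(u)]) / 2, 0.5)
  best <- -Inf
  for (t in cands) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    best <- max(best, (sens + spec) / 2)
  }
  best
}

# A small ready-made gene + dataset shared by the heavier tests (built once
# per test run).
tiny_synthetic <- local({
  cache <- NULL
  function(seed = 5) {
    if (is.null(cache)) {
      cache <<- synthetic_dataset("tiny", "pathogenicity", seed = seed)
    }
    cache
  }
})
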