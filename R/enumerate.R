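# Coding sequences and single-nucleotide missense enumeration.

#' Construct a validated coding sequence
#'
#' @param nucleotides DNA string (A/C/G/T), length divisible by 3. A trailing
#'   stop codon is allowed; internal stop codons trigger a warning, not an
#'   error.
#' @return object of class `coding_sequence` with fields `nucleotides` and
#'   `codon_count`.
#' @export
coding_sequence <- function(nucleotides) {
  if (!is.character(nucleotides) || length(nucleotides) != 1 || is.na(nucleotides)) {
    stop_validation("nucleotides must be a single string")
  }
  nt <- toupper(nucleotides)
  if (nchar(nt) %% 3 != 0) {
    stop_validation("coding sequence length %d is not divisible by 3", nchar(nt))
  }
  if (nchar(nt) > 0 && grepl("[^ACGT]", nt)) {
    stop_validation("coding sequence contains characters outside A/C/G/T")
  }
  n_codon <- nchar(nt) %/% 3
  if (n_codon > 0) {
    codons <- substring(nt, seq(1, nchar(nt), by = 3), seq(3, nchar(nt), by = 3))
    aas <- unname(Biostrings::GENETIC_CODE[codons])
    internal_stop <- which(aas == "*")
    internal_stop <- internal_stop[internal_stop < n_codon]
    if (length(internal_stop) > 0) {
      warning(sprintf("internal stop codon(s) at codon position(s): %s",
                      paste(internal_stop, collapse = ", ")))
    }
  }
  structure(list(nucleotides = nt, codon_count = n_codon),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %d codons (%d nt)\n", x$codon_count, nchar(x$nucleotides)))
  invisible(x)
}

#' Translate a coding sequence to protein
#'
#' Coding positions that translate to a stop codon are returned as `"*"`.
#' @param cds a `coding_sequence`.
#' @return single protein string (one character per codon).
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (cds$codon_count == 0) return("")
  codons <- substring(cds$nucleotides, seq(1, nchar(cds$nucleotides), by = 3),
                      seq(3, nchar(cds$nucleotides), by = 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# All 9 * codon_count single-nucleotide substitutions, classified.
# Returns a data.frame with one row per substitution.
enumerate_substitutions <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  L <- cds$codon_count
  if (L == 0) {
    return(data.frame(position = integer(0), ref_aa = character(0),
                      alt_aa = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  codons <- substring(cds$nucleotides, seq(1, nchar(cds$nucleotides), by = 3),
                      seq(3, nchar(cds$nucleotides), by = 3))
  ref_aa <- unname(Biostrings::GENETIC_CODE[codons])
  bases <- c("A", "C", "G", "T")

  # expand: position x codon-offset x alternative base (3 per site); the 9
  # rows per codon follow the pattern (offset 1, alt 1..3), (offset 2, ...)
  pos <- rep(seq_len(L), each = 9)
  offset <- rep(rep(1:3, each = 3), times = L)
  alt_rank <- rep(1:3, times = 3 * L)
  ref_codon <- codons[pos]
  ref_base <- substring(ref_codon, offset, offset)
  alts <- vapply(bases, function(b) setdiff(bases, b), character(3))
  alt_base <- alts[cbind(alt_rank, match(ref_base, bases))]
  alt_codon <- ref_codon
  substring(alt_codon, offset, offset) <- alt_base
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  cls <- ifelse(alt_aa == ref_aa[pos], "synonymous",
                ifelse(alt_aa == "*", "stop_introducing", "missense"))
  data.frame(position = pos, ref_aa = ref_aa[pos], alt_aa = alt_aa,
             class = cls, stringsAsFactors = FALSE)
}

#' Enumerate all single-nucleotide substitutions of a coding sequence
#'
#' Classifies every one of the `9 * codon_count` single-base substitutions
#' under the standard genetic code. `nonsyn_substitutions` counts all
#' non-synonymous substitutions including stop-introducing ones, so the
#' partition `nonsyn_substitutions + synonymous = 9 * codon_count` always
#' holds. `distinct_missense_variants` counts unique `(position, alt_aa)`
#' pairs, excluding stops and synonyms — the number of reachable missense
#' variants.
#'
#' @param cds a `coding_sequence`.
#' @return list with `nonsyn_substitutions`, `stop_introducing`,
#'   `distinct_missense_variants`, `synonymous`, and `per_position` (data
#'   frame of distinct reachable missense variants per codon).
#' @export
enumerate_missense <- function(cds) {
  subs <- enumerate_substitutions(cds)
  L <- cds$codon_count
  per_pos <- integer(L)
  if (nrow(subs) > 0) {
    mis <- subs[subs$class == "missense", , drop = FALSE]
    if (nrow(mis) > 0) {
      key <- paste(mis$position, mis$alt_aa)
      uniq <- mis[!duplicated(key), , drop = FALSE]
      tab <- table(factor(uniq$position, levels = seq_len(L)))
      per_pos <- as.integer(tab)
    }
  }
  n_syn <- sum(subs$class == "synonymous")
  n_stop <- sum(subs$class == "stop_introducing")
  n_mis_subs <- sum(subs$class == "missense")
  list(
    nonsyn_substitutions = n_mis_subs + n_stop,
    stop_introducing = n_stop,
    distinct_missense_variants = sum(per_pos),
    synonymous = n_syn,
    per_position = data.frame(position = seq_len(L), possible_missense = per_pos)
  )
}

#' Distinct reachable missense variants per codon position
#'
#' @param cds a `coding_sequence`.
#' @return integer vector of length `codon_count`.
#' @export
missense_possible <- function(cds) {
  enumerate_missense(cds)$per_position$possible_missense
}

#' All distinct reachable missense variants of a coding sequence
#'
#' @param cds a `coding_sequence`.
#' @return data frame with `variant`, `ref_aa`, `position`, `alt_aa`, one row
#'   per unique `(position, alt_aa)` pair.
#' @export
possible_missense_variants <- function(cds) {
  subs <- enumerate_substitutions(cds)
  mis <- subs[subs$class == "missense", , drop = FALSE]
  if (nrow(mis) == 0) {
    return(data.frame(variant = character(0), ref_aa = character(0),
                      position = integer(0), alt_aa = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(mis$position, mis$alt_aa)
  uniq <- mis[!duplicated(key), c("position", "ref_aa", "alt_aa")]
  uniq <- uniq[order(uniq$position, uniq$alt_aa), , drop = FALSE]
  rownames(uniq) <- NULL
  data.frame(variant = sprintf("%s%d%s", uniq$ref_aa, uniq$position, uniq$alt_aa),
             ref_aa = uniq$ref_aa, position = uniq$position, alt_aa = uniq$alt_aa,
             stringsAsFactors = FALSE)
}
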