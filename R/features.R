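# Feature engineering: physico-chemical deltas, transition flags,
# conservation entropy, and assembly of the full named feature vector.

#' Physico-chemical delta features and transition flags for one substitution
#'
#' Each delta is `scale[alt] - scale[ref]` (final minus initial). Transition
#' flags: `p_to_np` (polar reference to non-polar alternate), `np_to_p` (the
#' reverse), `charge_gain` (neutral to charged), `charge_loss` (charged to
#' neutral), `aromatic_change` (aromaticity class differs).
#'
#' @param ref_aa,alt_aa one-letter residue codes.
#' @param scales scale tables from [load_scales()].
#' @return named numeric vector of 6 deltas and 5 flags.
#' @export
physchem_delta <- function(ref_aa, alt_aa, scales = load_scales()) {
  if (!ref_aa %in% AA_ALPHABET || !alt_aa %in% AA_ALPHABET) {
    stop_validation("residues must be among the 20 standard amino acids")
  }
  d <- function(s) unname(scales[[s]][alt_aa] - scales[[s]][ref_aa])
  pol <- scales$polarity; chg <- scales$charge; aro <- scales$aromaticity
  c(delta_charge = d("charge"),
    delta_hydrophobicity = d("hydrophobicity"),
    delta_mw = d("molecular_weight"),
    delta_polarity = d("polarity"),
    delta_aromaticity = d("aromaticity"),
    delta_accessibility = d("accessibility"),
    p_to_np = as.numeric(pol[[ref_aa]] == 1 && pol[[alt_aa]] == 0),
    np_to_p = as.numeric(pol[[ref_aa]] == 0 && pol[[alt_aa]] == 1),
    charge_gain = as.numeric(chg[[ref_aa]] == 0 && chg[[alt_aa]] != 0),
    charge_loss = as.numeric(chg[[ref_aa]] != 0 && chg[[alt_aa]] == 0),
    aromatic_change = as.numeric(aro[[ref_aa]] != aro[[alt_aa]]))
}

#' Start-codon flag
#' @param position 1-based residue index (vectorized).
#' @return 1 where the substitution hits the first residue, else 0.
#' @export
first_position_flag <- function(position) {
  as.numeric(position == 1)
}

#' Shannon conservation entropy of alignment columns
#'
#' `H = -sum(p_i log2 p_i)` over the residue frequencies of the column, with
#' gap characters (`-`, `.`) excluded from the denominator. Ranges from 0
#' (fully conserved) to `log2(20)` bits.
#'
#' @param msa character matrix (rows = sequences, columns = positions).
#' @param position column index, or `NULL` for all columns.
#' @return entropy in bits (scalar or vector).
#' @export
conservation_entropy <- function(msa, position = NULL) {
  stopifnot(is.matrix(msa))
  cols <- if (is.null(position)) seq_len(ncol(msa)) else position
  if (any(cols < 1 | cols > ncol(msa))) {
    stop_validation("alignment column out of range (alignment has %d columns)", ncol(msa))
  }
  ent <- vapply(cols, function(j) {
    col <- msa[, j]
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0) stop_data("alignment column %d holds only gaps", j)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  }, numeric(1))
  if (is.null(position) || length(position) > 1) ent else ent[[1]]
}

# Canonical feature-name blocks (stable order).
delta_names <- c("delta_charge", "delta_hydrophobicity", "delta_mw",
                 "delta_polarity", "delta_aromaticity", "delta_accessibility")
flag_names <- c("p_to_np", "np_to_p", "charge_gain", "charge_loss", "aromatic_change")
topo_names <- c("topo_extracellular", "topo_transmembrane", "topo_cytoplasmic")
domain_flag_names <- c("unknown_function", "calmodulin_interaction", "selectivity_filter")
ss_names <- c("ss_H", "ss_E", "ss_C")

endpoint_feature_names <- function() {
  c(paste0("initial_aa_", AA_ALPHABET), paste0("final_aa_", AA_ALPHABET))
}

#' Assemble the named feature matrix for a set of variants
#'
#' Combines physico-chemical deltas and transition flags, the start-codon
#' flag, one-hot topology and functional-domain encodings (including the
#' `unknown_function`, `calmodulin_interaction` and `selectivity_filter`
#' flags), conservation entropy, the VFI and pLDDT profiles, a 3-state
#' secondary-structure one-hot, and (optionally) one-hot encodings of the
#' initial and final amino acids. Deterministic: identical inputs give
#' bit-identical matrices with a stable column order.
#'
#' @param variants data frame with `ref_aa`, `position`, `alt_aa` (e.g. from
#'   [parse_variants()]).
#' @param profiles list with per-residue tracks `vfi`, `plddt`, `entropy`,
#'   `secondary` (character H/E/C), all of the protein's length.
#' @param domains a `domain_map`.
#' @param scales scale tables from [load_scales()].
#' @param include_endpoint_aa include the 40 initial/final amino-acid
#'   one-hots; set `FALSE` for the severity task.
#' @return numeric data frame, one row per variant (rownames = variant
#'   strings), columns in canonical order.
#' @export
assemble_features <- function(variants, profiles, domains,
                              scales = load_scales(),
                              include_endpoint_aa = TRUE) {
  L <- attr(domains, "protein_length")
  for (track in c("vfi", "plddt", "entropy", "secondary")) {
    if (is.null(profiles[[track]])) stop_validation("profiles lacks track '%s'", track)
    if (length(profiles[[track]]) != L) {
      stop_validation("track '%s' has length %d, expected %d",
                      track, length(profiles[[track]]), L)
    }
  }
  if (any(variants$position < 1 | variants$position > L)) {
    stop_data("variant position outside the 1..%d profile range", L)
  }

  n <- nrow(variants)
  pc <- t(vapply(seq_len(n), function(i) {
    physchem_delta(variants$ref_aa[i], variants$alt_aa[i], scales)
  }, numeric(11)))

  row_idx <- domain_at(domains, variants$position)
  topo <- matrix(0, n, 3, dimnames = list(NULL, topo_names))
  topo[cbind(seq_len(n), match(paste0("topo_", domains$topology[row_idx]), topo_names))] <- 1
  dflags <- vapply(domain_flag_names, function(fl) as.numeric(domains[[fl]][row_idx]),
                   numeric(n))
  if (n == 1) dflags <- matrix(dflags, nrow = 1, dimnames = list(NULL, domain_flag_names))

  dom_labels <- sort(setdiff(unique(domains$label), "none"))
  dom_onehot <- NULL
  if (length(dom_labels) > 0) {
    dom_onehot <- vapply(dom_labels, function(lb) {
      as.numeric(domains$label[row_idx] == lb)
    }, numeric(n))
    if (n == 1) dom_onehot <- matrix(dom_onehot, nrow = 1)
    colnames(dom_onehot) <- paste0("domain_", dom_labels)
  }

  ss <- matrix(0, n, 3, dimnames = list(NULL, ss_names))
  ss_state <- profiles$secondary[variants$position]
  ss[cbind(seq_len(n), match(paste0("ss_", ss_state), ss_names))] <- 1

  out <- data.frame(pc,
                    first_position = first_position_flag(variants$position),
                    topo, dflags, check.names = FALSE)
  if (!is.null(dom_onehot)) out <- cbind(out, as.data.frame(dom_onehot, check.names = FALSE))
  out$conservation_entropy <- profiles$entropy[variants$position]
  out$vfi <- as.numeric(profiles$vfi)[variants$position]
  out$plddt <- profiles$plddt[variants$position]
  out <- cbind(out, as.data.frame(ss, check.names = FALSE))

  if (include_endpoint_aa) {
    init <- matrix(0, n, 20, dimnames = list(NULL, paste0("initial_aa_", AA_ALPHABET)))
    init[cbind(seq_len(n), match(variants$ref_aa, AA_ALPHABET))] <- 1
    fin <- matrix(0, n, 20, dimnames = list(NULL, paste0("final_aa_", AA_ALPHABET)))
    fin[cbind(seq_len(n), match(variants$alt_aa, AA_ALPHABET))] <- 1
    out <- cbind(out, as.data.frame(init, check.names = FALSE),
                 as.data.frame(fin, check.names = FALSE))
  }
  rownames(out) <- make.unique(sprintf("%s%d%s", variants$ref_aa,
                                       variants$position, variants$alt_aa))
  out
}

#' Write a feature matrix to CSV
#' @param features data frame from [assemble_features()].
#' @param path output path; variants go into a leading `variant` column.
#' @export
write_feature_matrix <- function(features, path) {
  df <- cbind(variant = rownames(features), features)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#' @param path file written by [write_feature_matrix()].
#' @return numeric data frame with variant rownames.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"variant" %in% names(df)) stop_data("feature matrix lacks a 'variant' column")
  rn <- df$variant
  df$variant <- NULL
  rownames(df) <- rn
  df
}
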