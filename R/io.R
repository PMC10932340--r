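# Readers and writers for the external input formats: FASTA sequences and
# alignments, gnomAD-style allele tables (TSV), pLDDT profiles (PDB B-factor
# or per-residue JSON), domain/topology maps (TSV), secondary-structure
# tracks (TSV), and labeled variant datasets (CSV).

#' Read a single protein sequence from FASTA
#' @param path FASTA file with exactly one record.
#' @return protein string.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1) stop_data("expected one sequence in %s, found %d", path, length(set))
  as.character(set[[1]])
}

#' Read a single coding (DNA) sequence from FASTA
#' @param path FASTA file with exactly one record.
#' @return a `coding_sequence`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1) stop_data("expected one sequence in %s, found %d", path, length(set))
  coding_sequence(as.character(set[[1]]))
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path aligned FASTA; all records must share one width.
#' @return character matrix, one row per sequence, one column per alignment
#'   position; gaps are `"-"`.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1) stop_data("empty alignment: %s", path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1) {
    stop_data("alignment rows differ in width (%s)", paste(unique(widths), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(as.character(set), ""))
  rownames(mat) <- names(set)
  mat
}

#' Read a gnomAD-style allele table
#'
#' Tab-separated with header columns `variant`, `allele_count`,
#' `total_alleles`, `source`. Rows are validated (parsable missense variant,
#' `0 <= allele_count <= total_alleles`, `total_alleles > 0`) and duplicate
#' `(variant, source)` pairs rejected. Rows from different releases (e.g. v2
#' and v3) are all retained here; deduplication across sources happens in
#' [merge_frequency_sources()].
#'
#' @param path TSV file.
#' @param sources optional character vector restricting accepted source tags.
#' @return data frame of class `allele_table` with columns `variant`,
#'   `ref_aa`, `position`, `alt_aa`, `allele_count`, `total_alleles`,
#'   `source`.
#' @export
read_allele_table <- function(path, sources = NULL) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant", "allele_count", "total_alleles", "source")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_data("allele table %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  }
  allele_table(df[need], sources = sources, context = path)
}

#' Construct a validated allele table from a data frame
#'
#' @param df data frame with columns `variant`, `allele_count`,
#'   `total_alleles`, `source`.
#' @param sources optional allowed source tags.
#' @param context label used in error messages.
#' @return validated `allele_table` data frame.
#' @export
allele_table <- function(df, sources = NULL, context = "allele table") {
  for (col in c("allele_count", "total_alleles")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0) {
      stop_data("%s: malformed %s at row(s) %s", context, col,
                paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[col]] <- as.integer(v)
  }
  bad <- which(df$allele_count < 0)
  if (length(bad) > 0) {
    stop_data("%s: negative allele_count at row(s) %s", context,
              paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(df$total_alleles < 1)
  if (length(bad) > 0) {
    stop_data("%s: non-positive total_alleles at row(s) %s", context,
              paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(df$allele_count > df$total_alleles)
  if (length(bad) > 0) {
    stop_data("%s: allele_count exceeds total_alleles at row(s) %s", context,
              paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(sources)) {
    bad <- which(!df$source %in% sources)
    if (length(bad) > 0) {
      stop_data("%s: unexpected source tag(s): %s", context,
                paste(unique(df$source[bad]), collapse = ", "))
    }
  }
  key <- paste(df$variant, df$source)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_data("%s: duplicate (variant, source) row(s) %s", context,
              paste(utils::head(dup, 5), collapse = ", "))
  }
  parsed <- parse_variants(df$variant)
  out <- data.frame(parsed,
                    allele_count = df$allele_count,
                    total_alleles = df$total_alleles,
                    source = as.character(df$source),
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Write an allele table to TSV
#' @param tbl an `allele_table`.
#' @param path output path.
#' @export
write_allele_table <- function(tbl, path) {
  utils::write.table(tbl[, c("variant", "allele_count", "total_alleles", "source")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue pLDDT profile
#'
#' Two encodings are supported: `"pdb"` takes the B-factor of each residue's
#' CA atom from a (single-chain) AlphaFold-style model, resolving alternate
#' locations by highest occupancy; `"json"` reads an AlphaFold per-residue
#' confidence JSON (either a bare array or an object with a `plddt` field).
#'
#' @param path input file.
#' @param mode `"pdb"` or `"json"`.
#' @param chain chain identifier; required when the PDB holds several chains.
#' @return numeric vector of per-residue confidences in `[0, 100]`.
#' @export
read_plddt <- function(path, mode = c("pdb", "json"), chain = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_data("file not found: %s", path)
  if (mode == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    vals <- if (is.list(raw) && !is.null(raw$plddt)) raw$plddt else raw
    vals <- as.numeric(vals)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    atoms <- pdb$atom
    chains <- unique(atoms$chain)
    if (is.null(chain)) {
      if (length(chains) > 1) {
        stop_data("PDB %s holds chains %s; give `chain`", path, paste(chains, collapse = ", "))
      }
      chain <- chains[1]
    }
    ca <- atoms[atoms$chain == chain & atoms$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) stop_data("no CA atoms for chain %s in %s", chain, path)
    # alternate locations: keep highest occupancy per residue
    ca <- ca[order(ca$resno, -ca$o), , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    resno <- ca$resno
    expected <- seq(min(resno), max(resno))
    gaps <- setdiff(expected, resno)
    if (min(resno) != 1) gaps <- c(seq_len(min(resno) - 1), gaps)
    if (length(gaps) > 0) {
      stop_data("missing residue(s) in %s: %s", path,
                paste(utils::head(sort(gaps), 10), collapse = ", "))
    }
    vals <- ca$b[order(ca$resno)]
  }
  if (any(is.na(vals))) stop_data("non-numeric pLDDT values in %s", path)
  if (any(vals < 0 | vals > 100)) {
    stop_data("pLDDT values outside [0,100] in %s (range %.2f..%.2f)",
              path, min(vals), max(vals))
  }
  as.numeric(vals)
}

#' Construct a validated domain/topology map
#'
#' Each interval carries a topology class (extracellular, transmembrane or
#' cytoplasmic), an optional functional-domain label (`"none"` for linkers),
#' and boolean flags (`unknown_function`, `calmodulin_interaction`,
#' `selectivity_filter`). The intervals must partition `1..length` exactly,
#' so every residue resolves to one topology and at most one functional
#' domain.
#'
#' @param df data frame with columns `start`, `end`, `label`, `topology`,
#'   `unknown_function`, `calmodulin_interaction`, `selectivity_filter`.
#' @param length protein length the map must cover.
#' @return data frame of class `domain_map`.
#' @export
domain_map <- function(df, length) {
  need <- c("start", "end", "label", "topology",
            "unknown_function", "calmodulin_interaction", "selectivity_filter")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_data("domain map lacks column(s): %s", paste(missing, collapse = ", "))
  }
  df <- df[order(df$start), need, drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end < df$start)) stop_data("domain map has end < start")
  if (!all(df$topology %in% c("extracellular", "transmembrane", "cytoplasmic"))) {
    stop_data("topology must be extracellular/transmembrane/cytoplasmic")
  }
  for (fl in c("unknown_function", "calmodulin_interaction", "selectivity_filter")) {
    df[[fl]] <- as.logical(df[[fl]])
    if (any(is.na(df[[fl]]))) stop_data("flag column %s must be logical", fl)
  }
  expected_start <- c(1L, df$end[-nrow(df)] + 1L)
  if (df$start[1] != 1L || df$end[nrow(df)] != length ||
      any(df$start != expected_start)) {
    stop_data("domain intervals must cover 1..%d without gaps or overlap", length)
  }
  attr(df, "protein_length") <- as.integer(length)
  class(df) <- c("domain_map", "data.frame")
  df
}

#' Read a domain/topology map from TSV
#' @param path TSV with the [domain_map()] columns.
#' @param length protein length the map must cover.
#' @return a `domain_map`.
#' @export
read_domain_map <- function(path, length) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  domain_map(df, length)
}

#' Write a domain map to TSV
#' @param map a `domain_map`.
#' @param path output path.
#' @export
write_domain_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve the domain-map row covering a position
#' @param map a `domain_map`.
#' @param position 1-based residue index (vectorized).
#' @return integer row indices into `map`.
#' @export
domain_at <- function(map, position) {
  idx <- findInterval(position, map$start)
  out_of_range <- position < 1 | position > attr(map, "protein_length")
  if (any(out_of_range)) {
    stop_data("position(s) outside domain map: %s",
              paste(position[out_of_range], collapse = ", "))
  }
  idx
}

#' Read a per-residue secondary-structure track
#'
#' @param path TSV with columns `position`, `ss` (H/E/C), one row per residue.
#' @param length expected protein length.
#' @return character vector of H/E/C states.
#' @export
read_secondary <- function(path, length) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "ss") %in% names(df))) {
    stop_data("secondary-structure track needs columns position, ss")
  }
  if (nrow(df) != length || !all(sort(as.integer(df$position)) == seq_len(length))) {
    stop_data("secondary-structure track must cover positions 1..%d exactly", length)
  }
  ss <- df$ss[order(df$position)]
  if (!all(ss %in% c("H", "E", "C"))) stop_data("ss states must be H, E or C")
  ss
}

#' Read a labeled variant dataset
#'
#' CSV with columns `variant`, `label`, `split`. Pathogenicity labels are
#' `tolerated`/`pathogenic`; severity labels are `benign`, `benign/severe`,
#' `severe`. Splits are `train`, `test` or `unassigned`.
#'
#' @param path CSV file.
#' @param task `"pathogenicity"` or `"severity"`.
#' @return data frame with parsed variant columns plus `label` and `split`.
#' @export
read_labeled_dataset <- function(path, task = c("pathogenicity", "severity")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "label", "split")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_data("dataset %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  }
  allowed <- if (task == "pathogenicity") c("tolerated", "pathogenic")
             else c("benign", "benign/severe", "severe")
  bad <- which(!df$label %in% allowed)
  if (length(bad) > 0) {
    stop_data("unknown label(s) for task %s: %s", task,
              paste(unique(df$label[bad]), collapse = ", "))
  }
  bad <- which(!df$split %in% c("train", "test", "unassigned"))
  if (length(bad) > 0) {
    stop_data("unknown split value(s): %s", paste(unique(df$split[bad]), collapse = ", "))
  }
  parsed <- parse_variants(df$variant)
  cbind(parsed, df[c("label", "split")])
}

#' Write a per-position profile TSV (the position-profile exchange format)
#' @param profile data frame with a `position` column (e.g. from
#'   [vfi_profile()]).
#' @param path output path.
#' @export
write_position_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-position profile TSV
#' @param path TSV written by [write_position_profile()].
#' @return data frame.
#' @export
read_position_profile <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
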