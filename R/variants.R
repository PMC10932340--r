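# Protein variant parsing and formatting.

#' Construct a protein missense variant
#'
#' @param ref_aa,alt_aa one-letter codes among the 20 standard residues.
#' @param position 1-based residue index.
#' @return an object of class `protein_variant`.
#' @export
protein_variant <- function(ref_aa, position, alt_aa) {
  if (!ref_aa %in% AA_ALPHABET) stop_validation("unknown residue code '%s'", ref_aa)
  if (!alt_aa %in% AA_ALPHABET) stop_validation("unknown residue code '%s'", alt_aa)
  if (!is_count(position)) stop_validation("position must be a positive integer, got '%s'", position)
  if (identical(ref_aa, alt_aa)) {
    stop_validation("synonymous substitution '%s%d%s' is not a missense variant",
                    ref_aa, position, alt_aa)
  }
  structure(list(ref_aa = ref_aa, position = as.integer(position), alt_aa = alt_aa),
            class = "protein_variant")
}

#' Parse a missense variant string
#'
#' Accepts short form (`"G256E"`), three-letter form (`"Gly256Glu"`), and
#' either with an HGVS `"p."` prefix (`"p.Asp488Glu"`). Stop-gain, frameshift
#' and synonymous notations are rejected: only single amino-acid substitutions
#' enter the pipeline.
#'
#' @param text variant string.
#' @return a `protein_variant`.
#' @examples
#' parse_variant("G256E")
#' parse_variant("p.Asp488Glu")
#' @export
parse_variant <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop_validation("variant must be a non-empty string")
  }
  s <- sub("^p\\.", "", trimws(text))
  m <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z*]{1,3})$", s))[[1]]
  if (length(m) == 0) stop_validation("cannot parse variant string '%s'", text)
  ref <- normalize_aa(m[2], text)
  alt <- normalize_aa(m[4], text)
  pos <- suppressWarnings(as.integer(m[3]))
  if (is.na(pos) || pos < 1) stop_validation("invalid position '%s' in variant '%s'", m[3], text)
  protein_variant(ref, pos, alt)
}

normalize_aa <- function(tok, context) {
  if (nchar(tok) == 1) {
    up <- toupper(tok)
    if (!up %in% AA_ALPHABET) {
      stop_validation("unknown residue code '%s' in variant '%s'", tok, context)
    }
    return(up)
  }
  if (nchar(tok) == 3) {
    idx <- match(tolower(tok), tolower(AA_THREE))
    if (is.na(idx)) {
      stop_validation("unknown residue code '%s' in variant '%s'", tok, context)
    }
    return(names(AA_THREE)[idx])
  }
  stop_validation("unknown residue code '%s' in variant '%s'", tok, context)
}

#' @export
format.protein_variant <- function(x, ...) {
  sprintf("%s%d%s", x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.protein_variant <- function(x, ...) {
  cat("<protein_variant>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.protein_variant <- function(x, ...) format(x)

#' Parse a vector of variant strings into a data frame
#'
#' @param texts character vector of variant strings.
#' @return data frame with columns `variant`, `ref_aa`, `position`, `alt_aa`.
#' @export
parse_variants <- function(texts) {
  parsed <- lapply(texts, parse_variant)
  data.frame(
    variant = vapply(parsed, format, character(1)),
    ref_aa = vapply(parsed, `[[`, character(1), "ref_aa"),
    position = vapply(parsed, `[[`, integer(1), "position"),
    alt_aa = vapply(parsed, `[[`, character(1), "alt_aa"),
    stringsAsFactors = FALSE
  )
}

# Check parsed variants against a protein sequence; errors on out-of-range
# positions or reference mismatches.
check_variants_against_protein <- function(vars, protein) {
  L <- nchar(protein)
  bad <- vars$position > L
  if (any(bad)) {
    stop_data("variant position(s) beyond protein length %d: %s",
              L, paste(vars$variant[bad], collapse = ", "))
  }
  ref_seq <- substring(protein, vars$position, vars$position)
  mism <- ref_seq != vars$ref_aa
  if (any(mism)) {
    stop_data("reference residue mismatch for: %s",
              paste(vars$variant[mism], collapse = ", "))
  }
  invisible(TRUE)
}
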