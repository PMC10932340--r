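# Amino-acid alphabet and physico-chemical scale tables.

#' The 20 standard amino acids (one-letter codes)
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Load amino-acid property scales
#'
#' Reads the per-residue tables used by the physico-chemical feature deltas:
#' charge at pH 7 (His neutral), Kyte-Doolittle hydrophobicity, residue
#' molecular weight (Da), binary polarity and aromaticity, and mean solvent
#' accessibility (theoretical maximum accessible surface areas normalized to
#' `[0, 1]`). The defaults ship as an editable YAML file; pass `path` to
#' substitute your own tables.
#'
#' @param path YAML file with one map per scale; defaults to the packaged
#'   tables.
#' @return a named list of named numeric vectors, one entry per scale, each
#'   covering exactly the 20 standard residues.
#' @export
load_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scales.yaml", package = "vfipred")
  }
  if (!file.exists(path)) stop_data("scales file not found: %s", path)
  raw <- yaml::read_yaml(path)
  required <- c("charge", "hydrophobicity", "molecular_weight", "polarity",
                "aromaticity", "accessibility")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_validation("scales file lacks tables: %s", paste(missing, collapse = ", "))
  }
  scales <- lapply(raw[required], function(tab) {
    v <- unlist(tab)
    if (!setequal(names(v), AA_ALPHABET)) {
      stop_validation("scale table must cover exactly the 20 standard residues")
    }
    v[AA_ALPHABET]
  })
  for (b in c("polarity", "aromaticity")) {
    if (!all(scales[[b]] %in% c(0, 1))) {
      stop_validation("scale '%s' must be binary (0/1)", b)
    }
  }
  scales
}
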