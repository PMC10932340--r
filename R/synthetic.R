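# Synthetic gene generator: produces every input the pipeline consumes
# (CDS, allele table, MSA, pLDDT, domain map, secondary structure, labeled
# datasets) with a designed tolerance landscape and controllable signal, so
# the whole artifact builds and tests without any download.

norm01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Frozen synthetic gene presets
#'
#' `"default"` emulates the structure of the curated KCNQ2-style study set:
#' an 872-residue channel-like protein and a labeled dataset of 554 variants
#' (285 tolerated / 269 pathogenic) whose held-out test split holds 27
#' tolerated and 62 pathogenic variants, plus a 274-variant severity subset
#' (62 benign / 32 benign-severe / 180 severe), with a 5% label-noise rate.
#' `"strong_signal"` is a balanced 500-variant set on a 500-residue gene at
#' the same noise level. `"tiny"` is a fast small-scale preset for unit
#' tests. Presets are versioned and frozen; override individual fields via
#' `...`.
#'
#' @param name preset name.
#' @param ... named overrides of preset fields.
#' @return list of generator parameters.
#' @export
gene_preset <- function(name = c("default", "strong_signal", "tiny"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    L = 872, n_msa = 40, lambda0 = 4, sigma_true = 2,
    noise_rate = 0.05, plddt_noise = 0.5,
    counts = c(tolerated = 285, pathogenic = 269,
               test_tolerated = 27, test_pathogenic = 62),
    severity_counts = c(benign = 62, benign_severe = 32, severe = 180),
    severity_test_frac = 0.25,
    # label-model coefficients: pathogenicity leans on intolerance (the
    # quantity VFI estimates); severity on positional context only
    patho_coef = c(intercept = -12, intolerance = 25, selectivity_filter = 2,
                   calmodulin_interaction = 1.5),
    severity_coef = c(calmodulin_interaction = 2.2, selectivity_filter = 3.0,
                      transmembrane = 1.2, unknown_function = -1.0)
  )
  tweaks <- switch(name,
    default = list(),
    strong_signal = list(L = 500,
                         counts = c(tolerated = 250, pathogenic = 250,
                                    test_tolerated = 25, test_pathogenic = 25)),
    tiny = list(L = 120, n_msa = 12,
                counts = c(tolerated = 40, pathogenic = 40,
                           test_tolerated = 10, test_pathogenic = 10),
                severity_counts = c(benign = 12, benign_severe = 6, severe = 22))
  )
  preset <- utils::modifyList(base, tweaks)
  preset <- utils::modifyList(preset, list(...))
  if (preset$noise_rate < 0 || preset$noise_rate >= 0.5) {
    stop_validation("noise_rate must lie in [0, 0.5)")
  }
  preset
}

# Channel-like region layout as fractions of the protein length; each row
# becomes one interval of the domain map. Coordinates are invented (the
# real domain boundaries are not tabulated anywhere we draw from); the
# layout only needs to provide plausible topology and functional context.
region_layout <- function() {
  data.frame(
    frac = c(0.105, 0.035, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030, 0.030,
             0.030, 0.030, 0.020, 0.015, 0.055, 0.130, 0.150, 0.100, 0.150),
    label = c("nterm", "s1", "s1s2_loop", "s2", "s2s3_loop", "s3", "s3s4_loop",
              "s4", "s4s5_linker", "s5", "turret", "pore_helix",
              "selectivity_filter", "s6", "helix_ab_cam", "unknown_region",
              "helix_c_sid", "cterm"),
    topology = c("cytoplasmic", "transmembrane", "extracellular", "transmembrane",
                 "cytoplasmic", "transmembrane", "extracellular", "transmembrane",
                 "cytoplasmic", "transmembrane", "extracellular", "transmembrane",
                 "transmembrane", "transmembrane", "cytoplasmic", "cytoplasmic",
                 "cytoplasmic", "cytoplasmic"),
    tol = c(0.85, 0.25, 0.70, 0.25, 0.80, 0.25, 0.70, 0.20, 0.60,
            0.25, 0.70, 0.15, 0.05, 0.25, 0.30, 0.75, 0.50, 0.90),
    ss = c("C", "H", "C", "H", "C", "H", "C", "H", "H",
           "H", "C", "H", "E", "H", "H", "C", "H", "C"),
    stringsAsFactors = FALSE
  )
}

synthetic_domain_map <- function(L) {
  lay <- region_layout()
  ends <- round(cumsum(lay$frac) / sum(lay$frac) * L)
  ends[length(ends)] <- L
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- ends >= starts
  df <- data.frame(start = starts[keep], end = ends[keep], label = lay$label[keep],
                   topology = lay$topology[keep],
                   unknown_function = lay$label[keep] == "unknown_region",
                   calmodulin_interaction = lay$label[keep] == "helix_ab_cam",
                   selectivity_filter = lay$label[keep] == "selectivity_filter",
                   stringsAsFactors = FALSE)
  domain_map(df, L)
}

#' Generate a synthetic gene and all its per-residue inputs
#'
#' Builds, from a designed smooth tolerance landscape tied to a channel-like
#' domain layout: a random coding sequence (uniform codon usage), an allele
#' table whose per-variant counts are Poisson with rate proportional to the
#' local tolerance (split across two gnomAD-style releases), an MSA whose
#' column conservation tracks intolerance, a pLDDT profile built as an
#' affine transform of the smoothed tolerance plus seeded noise (Pearson
#' correlation with the landscape >= 0.7 by construction), the domain map,
#' and a deterministic secondary-structure track. Fully deterministic under
#' a fixed seed.
#'
#' @param preset from [gene_preset()].
#' @param seed master seed.
#' @return list with `cds`, `protein`, `tolerance` (the true landscape),
#'   `alleles`, `msa`, `plddt`, `domains`, `secondary`, `preset`, `seed`.
#' @export
make_gene <- function(preset = gene_preset(), seed = 1L) {
  L <- preset$L
  domains <- synthetic_domain_map(L)

  # landscape: per-region base tolerance, smoothed into a gradual profile
  lay <- region_layout()
  base_tol <- numeric(L)
  for (i in seq_len(nrow(domains))) {
    base_tol[domains$start[i]:domains$end[i]] <- lay$tol[match(domains$label[i], lay$label)]
  }
  tol <- convolve_profile(base_tol, gaussian_kernel(6))
  tol <- pmin(pmax(tol, 0.02), 0.95)

  # coding sequence: ATG start, uniform sense codons after that
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- with_seed(derive_seed(seed, "cds"), {
    c("ATG", sample(setdiff(sense, "ATG"), L - 1, replace = TRUE))
  })
  cds <- coding_sequence(paste(codons, collapse = ""))
  protein <- translate_cds(cds)

  # allele table: per reachable missense variant, Poisson counts with rate
  # proportional to local tolerance; observed variants split across two
  # releases with redundant records between them
  pool <- possible_missense_variants(cds)
  counts <- with_seed(derive_seed(seed, "alleles"), {
    stats::rpois(nrow(pool), preset$lambda0 * tol[pool$position])
  })
  obs <- pool[counts > 0, , drop = FALSE]
  obs_counts <- counts[counts > 0]
  alleles <- with_seed(derive_seed(seed, "sources"), {
    in_v2 <- stats::runif(nrow(obs)) < 0.3
    v3 <- data.frame(variant = obs$variant, allele_count = obs_counts,
                     total_alleles = 280000L, source = "v3",
                     stringsAsFactors = FALSE)
    v2_counts <- stats::rbinom(nrow(obs), obs_counts, 0.4)
    keep <- in_v2 & v2_counts > 0
    v2 <- data.frame(variant = obs$variant[keep], allele_count = v2_counts[keep],
                     total_alleles = 150000L, source = "v2",
                     stringsAsFactors = FALSE)
    allele_table(rbind(v3, v2), context = "synthetic alleles")
  })

  # pLDDT: affine in the smoothed landscape plus noise at half the signal
  # spread (Pearson r ~ 0.9 by construction)
  smooth_tol <- convolve_profile(tol, gaussian_kernel(4))
  signal <- 35 + 55 * norm01(smooth_tol)
  plddt <- with_seed(derive_seed(seed, "plddt"), {
    signal + stats::rnorm(L, 0, preset$plddt_noise * stats::sd(signal))
  })
  plddt <- pmin(pmax(plddt, 0), 100)

  # MSA: column conservation anti-tracks tolerance (intolerant positions are
  # conserved, hence low entropy); sparse gaps
  protein_chars <- strsplit(protein, "")[[1]]
  conserve <- 0.97 - 0.55 * tol
  msa <- with_seed(derive_seed(seed, "msa"), {
    m <- matrix("", preset$n_msa, L)
    for (p in seq_len(L)) {
      match_ref <- stats::runif(preset$n_msa) < conserve[p]
      others <- sample(setdiff(AA_ALPHABET, protein_chars[p]), preset$n_msa,
                       replace = TRUE)
      col <- ifelse(match_ref, protein_chars[p], others)
      gap <- stats::runif(preset$n_msa) < 0.02
      # keep the first row gap-free so no column is all-gap
      gap[1] <- FALSE
      col[gap] <- "-"
      m[, p] <- col
    }
    rownames(m) <- sprintf("homolog_%02d", seq_len(preset$n_msa))
    m
  })

  # secondary structure: per-region states plus 20% misassignment, matching
  # the reliability of a 3-state prediction rather than a clean region map
  secondary <- character(L)
  for (i in seq_len(nrow(domains))) {
    secondary[domains$start[i]:domains$end[i]] <- lay$ss[match(domains$label[i], lay$label)]
  }
  secondary <- with_seed(derive_seed(seed, "ss_noise"), {
    flip <- stats::runif(L) < 0.2
    wrong <- vapply(secondary[flip], function(s) sample(setdiff(c("H", "E", "C"), s), 1),
                    character(1))
    secondary[flip] <- wrong
    secondary
  })

  list(cds = cds, protein = protein, tolerance = tol, alleles = alleles,
       msa = msa, plddt = plddt, domains = domains, secondary = secondary,
       preset = preset, seed = seed)
}

# Rank-based label assignment with exact class counts: adds standard Gumbel
# noise to the linear predictor (equivalent to sampling without replacement
# proportional to the logistic odds) and takes the top `n_pos` as positive.
rank_assign <- function(eta, n_pos, seed, tag) {
  g <- with_seed(derive_seed(seed, tag), -log(-log(stats::runif(length(eta)))))
  rank(-(eta + g), ties.method = "first") <= n_pos
}

# Swap labels between `n_swap` random cross-class pairs: mislabels 2*n_swap
# samples while preserving the class counts exactly.
swap_noise <- function(y, n_swap, seed, tag) {
  if (n_swap == 0) return(y)
  with_seed(derive_seed(seed, tag), {
    pos <- sample(which(y == 1), n_swap)
    neg <- sample(which(y == 0), n_swap)
    y[pos] <- 0L
    y[neg] <- 1L
  })
  y
}

#' Generate a labeled variant dataset for a synthetic gene
#'
#' Pathogenicity labels follow a logistic model of the true intolerance
#' (`1 - tolerance`) plus functional-domain flags, assigned by ranking so
#' class counts match the preset exactly, then noised by swapping labels
#' between random cross-class pairs at the preset rate (count-preserving).
#' Severity labels are driven by positional context only (domain flags and
#' topology), never by residue identity, so the endpoint amino acids carry
#' no severity signal by construction. Splits: the pathogenicity test set
#' holds exactly the preset's test counts; the severity test set is a
#' stratified fraction.
#'
#' @param gene from [make_gene()].
#' @param task `"pathogenicity"` or `"severity"`.
#' @param seed master seed (defaults to the gene's).
#' @return data frame with `variant`, `ref_aa`, `position`, `alt_aa`,
#'   `label`, `split`; attribute `signal` holds the pre-noise linear
#'   predictor used for label assignment.
#' @export
make_labels <- function(gene, task = c("pathogenicity", "severity"),
                        seed = gene$seed) {
  task <- match.arg(task)
  preset <- gene$preset
  pool <- possible_missense_variants(gene$cds)
  dom_idx <- domain_at(gene$domains, pool$position)
  flags <- gene$domains[dom_idx, c("unknown_function", "calmodulin_interaction",
                                   "selectivity_filter")]
  topo <- gene$domains$topology[dom_idx]

  if (task == "pathogenicity") {
    n <- sum(preset$counts[c("tolerated", "pathogenic")])
    take <- with_seed(derive_seed(seed, "patho_pool"), sample.int(nrow(pool), n))
    vars <- pool[take, , drop = FALSE]
    co <- preset$patho_coef
    eta <- co["intercept"] +
      co["intolerance"] * (1 - gene$tolerance[vars$position]) +
      co["selectivity_filter"] * flags$selectivity_filter[take] +
      co["calmodulin_interaction"] * flags$calmodulin_interaction[take]
    y <- as.integer(rank_assign(eta, preset$counts[["pathogenic"]], seed, "patho_rank"))
    # noise_rate is the chance a label is re-drawn at random; half of the
    # re-draws flip, so the expected mislabeled fraction is noise_rate / 2.
    # Swapping cross-class pairs keeps the class counts exact.
    y <- swap_noise(y, round(preset$noise_rate * n / 4), seed, "patho_noise")
    split <- rep("train", n)
    with_seed(derive_seed(seed, "patho_split"), {
      split[sample(which(y == 0), preset$counts[["test_tolerated"]])] <- "test"
      split[sample(which(y == 1), preset$counts[["test_pathogenic"]])] <- "test"
    })
    out <- data.frame(vars, label = ifelse(y == 1, "pathogenic", "tolerated"),
                      split = split, stringsAsFactors = FALSE)
  } else {
    sc <- preset$severity_counts
    n <- sum(sc)
    take <- with_seed(derive_seed(seed, "sev_pool"), sample.int(nrow(pool), n))
    vars <- pool[take, , drop = FALSE]
    co <- preset$severity_coef
    eta <- co["calmodulin_interaction"] * flags$calmodulin_interaction[take] +
      co["selectivity_filter"] * flags$selectivity_filter[take] +
      co["transmembrane"] * (topo[take] == "transmembrane") +
      co["unknown_function"] * flags$unknown_function[take]
    sev <- rank_assign(eta, sc[["severe"]], seed, "sev_rank1")
    mid_eta <- eta
    mid_eta[sev] <- -Inf
    mid <- rank_assign(mid_eta, sc[["benign_severe"]], seed, "sev_rank2") & !sev
    label <- ifelse(sev, "severe", ifelse(mid, "benign/severe", "benign"))
    split <- rep("train", n)
    with_seed(derive_seed(seed, "sev_split"), {
      for (lb in unique(label)) {
        idx <- which(label == lb)
        split[sample(idx, round(preset$severity_test_frac * length(idx)))] <- "test"
      }
    })
    out <- data.frame(vars, label = label, split = split, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "signal") <- as.numeric(eta)
  out
}

#' Write all synthetic inputs to disk in their external formats
#'
#' Emits the six inputs the pipeline consumes — CDS and protein FASTA, MSA
#' FASTA, allele table TSV, pLDDT as both per-residue JSON and a CA-only
#' PDB (B-factor column), domain map TSV, secondary-structure TSV — plus
#' the labeled pathogenicity and severity CSVs and a run manifest.
#' Byte-identical across runs with the same preset and seed.
#'
#' @param out_dir output directory (created if needed).
#' @param preset preset name or [gene_preset()] list.
#' @param seed master seed.
#' @return invisibly, the list of written paths.
#' @export
make_fixtures <- function(out_dir, preset = "default", seed = 7L) {
  if (is.character(preset)) preset <- gene_preset(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gene <- make_gene(preset, seed)
  paths <- list()
  w <- function(name) file.path(out_dir, name)

  dna <- Biostrings::DNAStringSet(stats::setNames(gene$cds$nucleotides, "synthetic_gene"))
  Biostrings::writeXStringSet(dna, w("cds.fasta"))
  prot <- Biostrings::AAStringSet(stats::setNames(gene$protein, "synthetic_protein"))
  Biostrings::writeXStringSet(prot, w("protein.fasta"))
  msa_seqs <- apply(gene$msa, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(msa_seqs), w("msa.fasta"))
  write_allele_table(gene$alleles, w("alleles.tsv"))
  jsonlite::write_json(list(plddt = round(gene$plddt, 3)), w("plddt.json"),
                       auto_unbox = TRUE, digits = NA)
  write_plddt_pdb(gene$plddt, gene$protein, w("plddt.pdb"))
  write_domain_map(gene$domains, w("domains.tsv"))
  utils::write.table(data.frame(position = seq_along(gene$secondary), ss = gene$secondary),
                     w("secondary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (task in c("pathogenicity", "severity")) {
    labs <- make_labels(gene, task, seed)
    utils::write.csv(labs[, c("variant", "label", "split")],
                     w(paste0(task, ".csv")), row.names = FALSE, quote = FALSE)
  }
  write_manifest(out_dir, command = "make-fixtures", seed = seed,
                 config = list(preset = preset$name, L = preset$L),
                 inputs = character(0))
  invisible(list.files(out_dir, full.names = TRUE))
}

# Minimal CA-only PDB writer used to encode a per-residue profile in the
# B-factor column (the AlphaFold convention).
write_plddt_pdb <- function(plddt, protein, path) {
  aa3 <- toupper(AA_THREE[strsplit(protein, "")[[1]]])
  lines <- vapply(seq_along(plddt), function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, aa3[i], i, i * 3.8, 0, 0, 1.00, plddt[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a ready-to-train dataset from a synthetic gene
#'
#' Convenience glue for tests, examples and the command line: computes the
#' VFI profile (at the preset's true kernel width), conservation entropy and
#' the full feature matrix, and binds them to generated labels as a
#' split-aware [variant_dataset()].
#'
#' @param preset preset name or [gene_preset()] list.
#' @param task `"pathogenicity"` or `"severity"`.
#' @param seed master seed.
#' @param include_endpoint_aa forwarded to [assemble_features()]; defaults
#'   to `TRUE` for pathogenicity and `FALSE` for severity.
#' @return list with `dataset` (a `variant_dataset`), `gene`, `labels`,
#'   `profile` (the per-position VFI profile data frame).
#' @export
synthetic_dataset <- function(preset = "default",
                              task = c("pathogenicity", "severity"),
                              seed = 1L, include_endpoint_aa = NULL) {
  task <- match.arg(task)
  if (is.character(preset)) preset <- gene_preset(preset)
  if (is.null(include_endpoint_aa)) include_endpoint_aa <- task == "pathogenicity"
  gene <- make_gene(preset, seed)
  profile <- vfi_profile(gene$alleles, gene$cds, sigma = preset$sigma_true)
  labels <- make_labels(gene, task, seed)
  profiles <- list(vfi = profile$vfi,
                   plddt = gene$plddt,
                   entropy = conservation_entropy(gene$msa),
                   secondary = gene$secondary)
  features <- assemble_features(labels, profiles, gene$domains,
                                include_endpoint_aa = include_endpoint_aa)
  y <- if (task == "pathogenicity") {
    as.integer(labels$label == "pathogenic")
  } else {
    merge_severity_labels(labels$label)$labels
  }
  ds <- variant_dataset(features, y, labels$split)
  list(dataset = ds, gene = gene, labels = labels, profile = profile)
}
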