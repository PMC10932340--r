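test_that("presets are validated and overridable", {
  p <- gene_preset("default")
  expect_equal(p$L, 872L)
  expect_equal(unname(p$counts[c("tolerated", "pathogenic")]), c(285, 269))
  expect_equal(unname(p$severity_counts), c(62, 32, 180))
  p2 <- gene_preset("tiny", noise_rate = 0)
  expect_equal(p2$noise_rate, 0)
  expect_error(gene_preset("tiny", noise_rate = 0.6), "noise_rate")
})

test_that("generated genes are deterministic and internally consistent", {
  g1 <- make_gene(gene_preset("tiny"), seed = 5)
  g2 <- make_gene(gene_preset("tiny"), seed = 5)
  expect_identical(g1$cds$nucleotides, g2$cds$nucleotides)
  expect_identical(g1$alleles, g2$alleles)
  expect_identical(g1$plddt, g2$plddt)
  expect_identical(g1$msa, g2$msa)

  L <- g1$cds$codon_count
  expect_equal(nchar(g1$protein), L)
  expect_length(g1$tolerance, L)
  expect_length(g1$plddt, L)
  expect_equal(ncol(g1$msa), L)
  expect_equal(attr(g1$domains, "protein_length"), L)
  expect_true(all(g1$secondary %in% c("H", "E", "C")))
  # every allele-table variant maps onto the protein
  check_variants_against_protein(g1$alleles, g1$protein)
})

test_that("intolerant regions carry lower per-position tolerance f", {
  g <- make_gene(gene_preset("tiny"), seed = 5)
  f <- position_tolerance(merge_frequency_sources(g$alleles), g$cds, N = 280000)
  intolerant <- g$tolerance < quantile(g$tolerance, 0.3)
  tolerant <- g$tolerance > quantile(g$tolerance, 0.7)
  # zero-count positions tie, so use the normal approximation explicitly
  w <- wilcox.test(f[intolerant], f[tolerant], alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("pLDDT correlates with the VFI profile by construction", {
  g <- make_gene(gene_preset("tiny"), seed = 5)
  prof <- vfi_profile(g$alleles, g$cds, sigma = g$preset$sigma_true)
  expect_gte(cor(g$plddt, prof$vfi), 0.7)
})

test_that("the VFI recovery chain tracks the true tolerance landscape", {
  g <- make_gene(gene_preset("default"), seed = 5)
  prof <- vfi_profile(g$alleles, g$cds, sigma = g$preset$sigma_true)
  expect_gte(cor(prof$vfi, g$tolerance), 0.9)
})

test_that("MSA column entropy is anti-correlated with intolerance", {
  g <- make_gene(gene_preset("tiny"), seed = 5)
  ent <- conservation_entropy(g$msa)
  expect_gt(cor(ent, g$tolerance), 0.5)   # intolerance = 1 - tolerance
})

test_that("pathogenicity labels hit the preset counts and split exactly", {
  g <- make_gene(gene_preset("default"), seed = 2)
  labs <- make_labels(g, "pathogenicity", seed = 2)
  expect_equal(nrow(labs), 554L)
  expect_equal(sum(labs$label == "tolerated"), 285L)
  expect_equal(sum(labs$label == "pathogenic"), 269L)
  expect_equal(sum(labs$split == "test" & labs$label == "tolerated"), 27L)
  expect_equal(sum(labs$split == "test" & labs$label == "pathogenic"), 62L)
  expect_false(anyDuplicated(labs$variant) > 0)
})

test_that("severity labels mirror the 62/32/180 structure and ignore residue identity", {
  g <- make_gene(gene_preset("default"), seed = 2)
  labs <- make_labels(g, "severity", seed = 2)
  expect_equal(as.integer(table(labs$label)[c("benign", "benign/severe", "severe")]),
               c(62L, 32L, 180L))
  # the label-generating signal is a function of position only: variants at
  # the same residue share it regardless of the substituting amino acid
  sig <- attr(labs, "signal")
  by_pos <- split(sig, labs$position)
  expect_true(all(vapply(by_pos, function(v) max(v) - min(v), numeric(1)) == 0))
})

test_that("zero noise with a strong effect separates labels by true intolerance", {
  p <- gene_preset("tiny", noise_rate = 0,
                   patho_coef = c(intercept = 0, intolerance = 1e6,
                                  selectivity_filter = 0, calmodulin_interaction = 0))
  g <- make_gene(p, seed = 4)
  labs <- make_labels(g, "pathogenicity", seed = 4)
  intol <- 1 - g$tolerance[labs$position]
  # every pathogenic variant is at least as intolerant as every tolerated one
  # (equality only on clipped-landscape plateaus straddling the cut)
  expect_gte(min(intol[labs$label == "pathogenic"]),
             max(intol[labs$label == "tolerated"]) - 1e-12)
})

test_that("fixture files are byte-identical across runs with one seed", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  make_fixtures(d1, "tiny", seed = 9)
  make_fixtures(d2, "tiny", seed = 9)
  files <- setdiff(list.files(d1), "manifest-make-fixtures.json")  # manifest holds a timestamp
  expect_gt(length(files), 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("written fixtures read back through the package parsers", {
  d <- file.path(tempdir(), "fx_roundtrip")
  make_fixtures(d, "tiny", seed = 9)
  cds <- read_cds_fasta(file.path(d, "cds.fasta"))
  protein <- read_protein_fasta(file.path(d, "protein.fasta"))
  expect_equal(translate_cds(cds), protein)
  L <- nchar(protein)
  tbl <- read_allele_table(file.path(d, "alleles.tsv"), sources = c("v2", "v3"))
  expect_gt(nrow(tbl), 0)
  expect_equal(length(read_plddt(file.path(d, "plddt.json"), "json")), L)
  expect_equal(read_plddt(file.path(d, "plddt.pdb"), "pdb"),
               read_plddt(file.path(d, "plddt.json"), "json"), tolerance = 0.01)
  expect_equal(ncol(read_msa(file.path(d, "msa.fasta"))), L)
  map <- read_domain_map(file.path(d, "domains.tsv"), L)
  expect_s3_class(map, "domain_map")
  expect_length(read_secondary(file.path(d, "secondary.tsv"), L), L)
  labs <- read_labeled_dataset(file.path(d, "pathogenicity.csv"), "pathogenicity")
  check_variants_against_protein(labs, protein)
})
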