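Package: vfipred
Title: Gene-Specific Missense Variant Pathogenicity and Severity Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-specific classifiers of missense variant pathogenicity
    and phenotypic severity around the Variant Frequency Index (VFI), a
    per-residue tolerance score derived from population allele frequencies,
    squashed by a rational function and smoothed with a Gaussian kernel along
    the protein sequence. Provides parsers for the required inputs (coding
    sequences, gnomAD-style allele tables, multiple sequence alignments,
    AlphaFold per-residue confidence, domain maps, labeled variant sets), a
    feature-engineering layer (physico-chemical deltas, conservation entropy,
    domain and topology encodings), a training protocol with forward greedy
    feature selection, random hyperparameter search, repeated stratified
    cross-validation and greedy soft-voting ensembles, a severity sub-task with
    decision-threshold optimization, Shapley-value feature attribution, and a
    fully synthetic data generator so the whole pipeline runs end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    MASS,
    e1071,
    kernlab,
    ranger,
    xgboost,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    seqinr,
    knitr
Config/testthat/edition: 3
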