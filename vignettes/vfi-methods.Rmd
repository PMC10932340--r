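---
title: "Methods: the Variant Frequency Index and the ensemble training protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Variant Frequency Index and the ensemble training protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfipred)
```

# The problem

For many disease genes, genome-wide variant effect predictors overcall
pathogenicity at conserved positions and undercall it elsewhere, and none
address phenotype severity. `vfipred` implements a gene-specific
alternative: a per-residue tolerance score learned from population allele
frequencies (the Variant Frequency Index, VFI), a defined feature scheme,
and a fixed model-selection protocol that together produce a pathogenicity
classifier and a severity classifier for a single gene. The design follows
the K_V_7.2 potassium channel as the motivating case — a neonatal-epilepsy
gene whose phenotypes range from self-limited seizures to severe
developmental and epileptic encephalopathy — but nothing in the code is
specific to it.

# The VFI score

## Per-position tolerance

For residue $p$,

$$f_p = \frac{\text{missense\_observed}_p}{N \cdot \text{missense\_possible}_p},$$

where the numerator sums the allele counts of missense variants observed at
$p$ after merging frequency sources, the denominator's
$\text{missense\_possible}_p$ counts distinct missense variants reachable
from the codon by one nucleotide change (0–9, typically 5–7), and $N$ is a
single gene-wide total-alleles denominator.

Three choices here were genuinely open:

* **What "observed" counts.** Summed allele counts (default) rather than
  the number of distinct observed variants: dividing by $N$, the number of
  sequenced alleles, yields a frequency only if the numerator is an allele
  count. Both interpretations are implemented
  (`position_tolerance(count_mode = "variants")`).
* **The denominator $N$.** A single gene-wide value — by default the
  largest panel size among the merged sources — not a per-position value;
  per-position panel sizes vary by coverage, but the score is meant to be
  comparable along the sequence.
* **Source merging.** When a variant is reported by two releases (e.g.
  gnomAD v2 and v3), the record from the larger panel (larger
  `total_alleles`) is kept; the releases overlap in samples, so summing
  would double-count carriers.

## Squash and smoothing

$F = f/(f+\alpha)$ maps tolerance onto $[0,1)$; $\alpha$ is the tolerance at
which $F = 0.5$. By default $\alpha$ is the median of the non-zero $f_p$
over the gene, which centers the squash on a typical tolerated position;
any fixed positive value can be supplied instead.

$F$ is treated as a noisy estimate of the true local tolerance and denoised
by discrete convolution with a normalized Gaussian kernel of standard
deviation $\sigma$ (default 2 positions, the width at which wider kernels
begin to blur the signal without adding robustness). The kernel half-width
is $\lceil 4\sigma \rceil$, which carries essentially all Gaussian mass; at
the sequence ends the kernel is truncated to in-range positions and
renormalized, so a constant profile is preserved exactly — the invariant the
convolution tests pin down. A 31-residue rectangular running mean
(`sliding_window_score`) is provided as the MTR-style baseline; it is the
same convolution with a uniform kernel.

# Features

Each variant is described by: six physico-chemical deltas (final minus
initial residue under editable scale tables — charge at pH 7 with histidine
neutral, Kyte–Doolittle hydrophobicity, residue mass, binary polarity and
aromaticity, normalized theoretical maximum solvent accessibility); five
transition flags (`p_to_np`, `np_to_p`, `charge_gain`, `charge_loss`,
`aromatic_change`); a start-codon flag; one-hot topology
(extracellular/transmembrane/cytoplasmic) and functional-domain context
including `unknown_function`, `calmodulin_interaction` and
`selectivity_filter` flags; Shannon conservation entropy of the MSA column
(base 2, gaps excluded from the denominator — gap-rich columns would
otherwise have inflated entropy); the VFI; the AlphaFold pLDDT of the
residue; a 3-state secondary-structure one-hot (consumed as an annotation
track, not predicted); and, optionally, 40 one-hots for the initial and
final amino acids. Categorical context is one-hot encoded so that linear
members of the zoo can use it. Feature assembly is a pure function:
identical inputs give bit-identical matrices with a stable column order.

# Training protocol

The dataset object locks its test rows; selection code cannot touch them
until an explicit `finalize()`, which mirrors the bias discussion around
repeated cross-validation: feature and hyperparameter selection reuse the
training folds, so CV estimates are optimistically biased and the held-out
split is the honest check.

Per algorithm (the registered zoo: logistic regression,
probability-calibrated RBF-SVM, random forest, gradient boosting via
xgboost, k-NN, LDA, Gaussian naive Bayes, Gaussian process; the default
set trained by the pipeline is logistic regression + SVM + random forest —
see the limitations section):

1. **Forward greedy feature selection**, adding the feature that maximizes
   stratified 5-fold mean AUC-ROC, stopping after 10 consecutive
   non-improving steps, returning the best prefix. Ties break by feature
   name; fold assignment is fixed across candidates; tree learners screen
   with reduced capacity (100 trees / 60 rounds) for speed.
2. **Random hyperparameter search** over shipped per-algorithm spaces
   (regularization and kernel widths log-uniform, tree counts and depths on
   small grids), best mean 5-fold AUC-ROC wins, ties by draw order.
3. **Repeated stratified CV** (default 25 × 5-fold; folds deal each class
   round-robin after a per-repeat shuffle, so per-fold class counts differ
   by at most one). Every sample is held out exactly 25 times, which is
   what makes the per-variant error-rate map (`error_rate_map`)
   well-defined: the fraction of its 25 held-out predictions that were
   wrong, flagged above 0.5.

The per-algorithm winners feed **greedy ensemble selection**: members are
added one at a time to maximize cross-validated soft-vote AUC-ROC, and the
best subset found is kept — its size emerges from the search. Soft voting
(mean of member probabilities) is the default combiner; hard voting
(majority, ties to the positive class) and stacking (logistic meta-learner
on out-of-fold member probabilities, out-of-fold to avoid leakage) are also
implemented. All randomness derives from one master seed through tagged
child seeds, so every stage is independently reproducible.

# Severity

Raw severity labels `benign`, `benign/severe`, `severe` are merged to
binary with `benign/severe` counted as severe (the clinically conservative
merge; severe is the positive class). The same protocol then runs with two
changes: the feature matrix must exclude the endpoint amino-acid one-hots —
`train_severity` rejects matrices that still carry them, because with ~270
examples those 40 indicators let models memorize mutation identities — and
after training, the decision threshold is re-optimized for balanced
accuracy on the training scores. Candidate thresholds are the midpoints of
adjacent sorted unique scores plus 0.5, so the optimized threshold can
never do worse than the default; ties resolve toward 0.5. The severity
sets are imbalanced toward severe, so at threshold 0.5 sensitivity far
exceeds specificity; the optimized threshold shrinks that gap, which the
tests assert on synthetic data.

# Shapley attribution

Attributions are exact where exactness is cheap and sampled elsewhere:
closed form $\phi_i = w_i (x_i - \bar{b}_i)$ on the log-odds scale for
logistic members; exact tree-path contributions (xgboost's `contrib`
predictions, log-odds scale) for gradient boosting; and a
permutation-sampling estimator on the probability scale for every other
model, ensemble or bare prediction function. The sampling scheme switches
features from a background row to the explained row along random
permutations and credits each feature with the prediction change; the
contributions of one permutation chain telescope, so local accuracy
(base value plus attributions equals the model output) holds to numerical
precision for the estimator too — only the split between correlated
features is approximate at finite sample size. The output scale is recorded
in each report. The background is the full training matrix, subsampled with
a seed above 200 rows.

# The synthetic data generator

The generator is the package's study system, not a mock: it defines the
conditions under which the pipeline's recovery claims are tested.

* **Landscape.** A channel-like region layout (N-terminus, six
  transmembrane segments with loops, pore with a short selectivity filter,
  calmodulin-binding helices, a cytoplasmic region of unknown function,
  subunit-interaction helix, C-terminus) assigns each region a base
  tolerance; smoothing with a Gaussian of width 6 makes the landscape
  gradual, clipped to $[0.02, 0.95]$. The region coordinates are invented;
  only their statistical roles matter.
* **Inputs.** The CDS has uniform sense-codon usage (only positional
  structure matters downstream). Per reachable missense variant, allele
  counts are Poisson with mean $\lambda_0 \cdot \text{tol}_p$
  ($\lambda_0 = 4$), split across two releases with overlapping records so
  the merge rule has work to do. pLDDT is an affine transform of the
  smoothed landscape plus Gaussian noise at half the signal spread
  (correlation with the landscape ≈ 0.9 by construction, well above the
  0.7 the tests require) — emulating the empirical observation that
  AlphaFold confidence tracks regional tolerance. MSA columns match the
  reference residue with probability $0.97 - 0.55\,\text{tol}_p$, so
  entropy rises with tolerance; 2% gaps, first row gap-free.
* **Labels.** The default preset fixes 554 variants at 285 tolerated / 269
  pathogenic with a held-out test split of 27 tolerated + 62 pathogenic and
  the remainder in training, and a severity subset of 62 benign / 32
  benign-severe / 180 severe with a stratified 25% test fraction. (The
  published split arithmetic these counts emulate is not fully
  self-consistent — training and test subsets do not sum to the full set —
  so the generator keeps the total, the class balance and the test split
  exact and assigns everything else to training.) Pathogenicity labels come
  from a logistic model of true intolerance plus selectivity-filter and
  calmodulin flags, assigned by Gumbel-noised ranking so class counts are
  exact; the effect sizes are scaled so that ranking noise is negligible
  and explicit label noise dominates. The label-noise rate (default 0.05)
  is the chance a variant's label is re-drawn at random — half of re-draws
  flip, so ~2.5% of labels end up wrong — realized as cross-class pair
  swaps, which preserve the class counts exactly. This emulates
  heuristically-labeled (e.g. primate-derived) tolerated variants and
  bounds the achievable AUC-ROC near 0.975.
  Severity labels depend on positional context only — never on residue
  identity — so endpoint one-hots carry no severity signal by construction,
  which is what makes the endpoint-guard demonstration meaningful.
* **What it does not emulate.** Real linkage between physico-chemical
  change and pathogenicity, realistic codon usage, phylogenetic structure
  in the MSA, or position-dependent sequencing coverage. Passing tests
  demonstrate that the machinery recovers planted signal at realistic
  sizes and noise, not clinical performance on real variants.

# Problem sizes and numerical choices

The test suite exercises the full protocol at two scales chosen as
representative desk-scale problems: a "tiny" 120-residue gene with 80
variants for unit tests, and the default 872-residue / 554-variant preset
for the end-to-end recovery check (three-algorithm zoo, 6 hyperparameter
draws, 25 × 5 CV). Elsewhere: convolution and enumeration oracles run on
100 random inputs each; AUC uses the rank statistic with ties averaged
(cross-checked against pROC); degenerate fits during greedy selection
(e.g. LDA on a within-class-constant column) score `NA` and the candidate
is skipped; positions with no reachable missense variant get $f = 0$ with a
warning; hard-vote ties go to the positive class and are logged. Missing
feature values are an error, never imputed — no imputation scheme is part
of the method.

# Known limitations

Gradient boosting (xgboost) is a registered zoo member with full fit,
search-space, CV and exact-attribution support, but it is not in the
default algorithm set: greedy feature screening generates on the order of
ten thousand sequential fits per algorithm, and the xgboost R bindings are
not reliable at that call volume (rare native crashes in booster creation
that an R process cannot recover from). Include
`"gradient_boosting"` explicitly for moderate workloads — direct fits,
hyperparameter search and repeated CV at default sizes are unaffected.

The VFI depends on population coverage: at ~7% of possible missense
variants observed, regional smoothing is obligatory, and narrower kernels
trade statistical robustness for resolution. The severity task remains
data-limited and context-driven; its honest test-set accuracy is far below
the pathogenicity task's. Gain- vs loss-of-function, clinical covariates
(onset, inheritance), deep-learning sequence models and 3D structural
features beyond pLDDT are out of scope.
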