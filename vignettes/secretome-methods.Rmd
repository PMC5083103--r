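---
title: "Methods: paired spectral-count secretome analysis"
author: "adjSecretome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired spectral-count secretome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and procedures, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical and design
choices made where more than one defensible option existed.

## The experimental design being modelled

Monocytes from paired newborn and adult donors are cultured with vehicle
(control) or one of three adjuvants (Alum, MPLA, R848); conditioned
supernatants are profiled by LC-MS/MS and each protein is quantified as a
spectral count (SpC) per sample. The design is paired twice over: each
subject contributes a control sample and treated samples (the pairing the
count model exploits), and newborn/adult donors are recruited as pairs
(the pairing behind the age comparison). The modelled study had six
complete subject pairs per age plus one unpaired newborn, which is why
`validateDesign()` keeps subjects without a control sample but flags them
`incomplete`; they are excluded from per-subject fold changes and from
the paired count model, while still contributing to imputation,
normalization and detection counting.

A spectral-count cell can be *missing* (the protein was not
detected/reported in that run) or a literal *zero*. Both mean "no
spectral evidence"; the distinction matters because the preprocessing
imputes missing cells explicitly. Detection calls (used by the filters
and the Venn accounting) always mean: observed and positive in the raw
counts — imputed cells never count as detections.

## Preprocessing

**Half-minimum imputation.** Missing cells are set to half the minimum
positive observed count of the whole data set — 0.5 when the minimum is
1, the constant the source analysis printed. Computing the half-minimum
over the whole data set (not per sample) is what makes that constant
reproducible. At the experiment level the same floor is applied to
observed zeros (`floorZeros = TRUE`): a zero-spectra cell carries no more
evidence than an absent one, and the floor is precisely what keeps
fold-change denominators positive. The plain-matrix method leaves
observed cells untouched for callers who want the strict rule.

**Total-SpC normalization.** Each sample is scaled by (maximum column
total) / (its column total), so all totals equal the pre-scaling maximum.
The operation is idempotent, and fold changes are invariant to its global
constant. Normalization is per age cohort by default (`byAge = TRUE`)
because each cohort constitutes its own data set in the modelled
analysis; joint normalization is a flag.

**Fold change.** Per subject and protein, treated / control on the
normalized scale; the condition summary is the arithmetic mean of log2
fold changes across that condition's subjects. Unpaired subjects are
excluded from fold changes but not from imputation or normalization.

**Row z-scoring** uses the sample standard deviation (n − 1). Constant
rows map to all-zero rather than being dropped, so matrix shape is
stable; they are excluded from clustering by the inclusion filter in any
case.

## Filters and overlap accounting

The exclusion rule drops proteins whose entire evidence is a single count
of exactly 1 in one sample. The cluster-inclusion rule admits a protein
to a condition's clustering iff (a) total raw spectra across the
condition's treated samples are at least 2, (b) it is detected in at
least two samples, and (c) its per-subject fold change reaches the
threshold (default 2) in *strictly* more than half of the condition's
replicates — 4 of 7 passes, 3 of 6 fails; the boundary is tested
explicitly. Rule (a) sums spectra across the condition's samples by
default; a stricter per-sample reading is available (`perSample = TRUE`).
Each rule is evaluated on the raw evidence independently, so the report
is order-free.

Condition-overlap summaries report, per age group, the nonredundant
total, the all-condition intersection, per-condition unique counts and
their mean, with percentages rounded half-up to integer percent — the
convention that reproduces the published 617/1519 → 41% and 565/1717 →
33%. Whether the overlap is computed before or after the exclusion
filter was not specified in the source; the default applies the
exclusion first, with a flag to disable.

## Two-way clustering

Distances are 1 − Pearson correlation; aggregation is Ward's
minimum-variance in its Ward.D2 form (Lance–Williams recursion on
squared distances), which the test suite pins to an independent
from-scratch greedy oracle and to `stats::hclust(method = "ward.D2")`.
Determinism is part of the contract: exact ties on the merge criterion
(within 1e-12) are broken by the lexicographically smallest pair of
cluster indices, and within each merge the subtree containing the
smaller minimal original leaf index comes first. No optimal leaf
ordering is applied — the tested contract is topology and heights; leaf
order differences against seriation-based tools are cosmetic. Rows are
z-scored jointly across all condition columns present in the matrix
(both ages), matching the single imported matrix of the modelled
analysis. A single-row matrix cannot yield Pearson distances between its
scalar columns, so that degenerate case falls back to absolute
differences.

## The paired count model

Counts for protein *i* in subject *s* follow a Poisson log-linear model
with the sample's total SpC as exposure offset and a subject fixed
effect; the treatment coefficient `beta_i` is the target. Conditioning on
each pair's total eliminates the subject effect exactly and leaves a
binomial likelihood whose success logit is `beta_i` plus the pair's log
offset ratio; the conditional MLE (a one-dimensional Newton iteration,
vectorized across proteins) equals the fixed-effects profile MLE.
Protein length enters the offset as a per-protein constant, so it cancels
within pairs and the likelihood stays on integer counts — this is how
"length-normalized" comparison and an integer count model coexist.

The Wald variance is moderated by empirical-Bayes shrinkage toward the
20%-trimmed mean variance across the data set's proteins with prior
degrees of freedom `d0 = 4` (pooling strength comparable to the number of
residual degrees of freedom at six pairs; at d0 = 4 a protein's own
variance still dominates). The moderated `Z = beta / SE*` is referred to
the standard normal; BH step-up FDR is thresholded at 0.05. Proteins
with no counts anywhere are flagged `uninformative` (Z = 0, p = 1);
proteins with all counts on one side (the unpenalized MLE diverges) are
refit with a Jeffreys-style continuity adjustment (+0.25 per arm, +0.5
per pair total) and flagged `boundary`.

Two caveats are worth stating. First, total-SpC offsets are
compositional: if treatment shifted a large share of total spectral mass
in one direction, every null protein would inherit an opposite apparent
shift. The model does not correct for this (the offset definition is part
of the method); the generator's signed effects keep the simulated mass
shift small, as discussed below. Second, the normal reference for the
moderated Z is an approximation whose exact-test counterpart (the
conditional binomial) is heavier-tailed; on the single-protein example in
the test suite the Wald p is within a small factor of the exact
conditional p (about 3x at |Z| ≈ 3.5) and the two rankings agree
closely (Kendall tau ≥ 0.8). Calibration is therefore asserted where it
matters operationally: the frequency of p < 0.05 and of FDR-level false
calls on null simulations.

## Over-representation

Enrichment builds, per gene set, the 2x2 table over the *measured*
universe (all quantified proteins, the defensible default when the query
is itself defined by the experiment; a broader universe can be
supplied). The default alternative is one-sided ("greater"), the
over-representation convention; two-sided is a flag. The pathway-report
filter keeps sets with overlap ≥ 2 in at least one age data set and
p < 0.05, with a user-supplied exclusion list for e.g. disease-specific
pathway names. The EASE variant removes one success from the overlap
cell before a one-sided Fisher test; it is provably conservative
(EASE p ≥ Fisher p, property-tested) and a single-protein overlap can
never be significant. Enrichment p-values are reported raw, matching the
modelled report; BH adjustment is available separately via
`fdrAdjust()`.

## Exact test kernel

All pipeline p-values route through one kernel with explicit exact
regimes:

- signed-rank: exact by generating-polynomial convolution over doubled
  mid-ranks for n ≤ 25 (ties handled exactly, zeros dropped); above,
  normal approximation with tie correction and continuity correction;
- rank-sum: exact by enumeration of label assignments for combined
  n ≤ 20; tie-corrected normal approximation above;
- Fisher: exact two-sided by point-probability summation (the
  `fisher.test` convention), one-sided tails available; odds ratio
  ad/bc with zero-product tables flagged;
- Kendall tau-b: tie-corrected tau from the contingency representation;
  exact permutation p for n ≤ 8, tie-term normal approximation above;
- pooled-variance two-tailed t.

Every exact path is pinned bit-for-bit to a brute-force enumeration
oracle in the tests; approximate paths are checked against the exact
ones at the regime boundary (max |Δp| < 0.01).

## Cross-omics concordance

The transcriptome arm quantile-normalizes a probe x sample matrix
(classic order-statistic-mean mapping, ties receiving the mean of their
would-be reference quantiles; the probe-level summarization of array
preprocessing is out of scope). Per probe, an exact paired signed-rank
test on (T2 − T1) across participants; direction is the sign of the
median paired difference; per gene, the minimum-p probe is the unique
representative; significance at p < 0.05. Genes are matched to secretome
proteins through an id map (many-to-many kept as distinct pairs), each
layer's call is encoded ternary (+1 significant-up, −1 significant-down,
0 otherwise), background genes absent from the matched set are padded as
(0, 0), and association is tested with Kendall tau-b.

One property discovered while calibrating this module deserves emphasis:
with padded background genes, the tau-b test reacts to mere co-location
of the measured panel — nonzero calls in both layers can only occur on
matched molecules, so even direction-randomized null data reject far too
often (a measured null rejection fraction of about 75% at a 12,893-gene
background over a 120-gene panel). When the measured panel spans the
background (no structural padding), the same test is well calibrated
(null fraction ≈ 5%). The package therefore runs its null-calibration
simulations with `background_n` equal to the matched-panel size, and
users comparing small panels against large fixed backgrounds should read
small tau-b p-values with this in mind. The GO-term co-occurrence
fraction uses the secretome term set as denominator
(|intersection| / |secretome terms|); union- or transcriptome-denominator
conventions can be computed by swapping arguments.

## The synthetic-data generator

`simulateSpcExperiment()` emulates: paired subjects per age (default 6,
optional seventh unpaired newborn), four treatments, log-normal protein
baselines (geometric mean 5 SpC, sdlog 1) and subject factors (sdlog
0.3), protein-by-subject gamma heterogeneity with dispersion 0.05 shared
across a subject's columns — so marginal counts are negative binomial
around subject baselines while the within-pair comparison stays
Poisson, the regime the paired model assumes for donor-level biological
variation — Poisson sampling per cell, and detection-limited dropout
(default rate 0.15): a masked cell must have been below its drawn
detection limit, making missingness low-count-dependent (MNAR), which is
why half-minimum imputation rather than zero-filling is the matched
preprocessing.

Treatment effects are signed: responsive proteins (default 20% per
treatment) are up-regulated with probability 0.7, drawn from the
below-median baseline pool (induced mediators start near the detection
floor), and down-regulated otherwise from the above-median pool
(suppression of constitutively secreted abundant proteins). This mirrors
the modelled study's differential plots, which show both induced and
suppressed proteins, and it keeps per-sample totals — the model's
exposure offsets — stable; `effect_log2fc` (default 2, the fold-change
threshold the study used elsewhere) is the mean log2 fold-change
*magnitude*. The MPLA- and R848-responsive sets share 80% of their
members with identical effects while the Alum set is independent,
reproducing the qualitative clustering result (TLR agonists together,
Alum apart). The transcriptome generator emits one gene per protein with
2–3 probes sharing a gene signal, paired participants at T1..Tk, and a
configurable fraction of responsive-protein genes shifting at T2 in the
protein's true direction with decay at later timepoints.

A single seed fans out to named substreams (proteins, truth, counts,
dropout, expression, genesets), so adding a downstream stage never
perturbs earlier draws, and identical configurations are byte-identical.

What the generator does **not** emulate: peptide-level evidence and
protein inference ambiguity, retention-time or run-order effects,
shared-peptide count correlations between homologous proteins,
age-by-treatment interaction structure (truth is shared across ages),
and real pathway structure in the gene-set fixture. Passing tests
therefore demonstrate correctness of the pipeline's computations and
calibration under the stated generative assumptions, not performance on
real LC-MS data.

Inter-subject variance, detection limits and dispersion for the modelled
cohort were never published; the defaults above are calibration choices
fixed once for this package, not estimates of that study.

## Numerical choices

- Newton iterations stop at |step| < 1e-10 (max 50, steps damped to
  ±5); the conditional-likelihood score is globally concave so this is
  benign.
- Ward tie detection uses an absolute 1e-12 on squared distances
  (bounded by 4 for correlation distances).
- Percentages round half-up (`floor(x + 0.5)`), never banker's rounding.
- Two-sided exact p-values are `min(1, 2 * min(lower, upper))`; Fisher
  two-sided sums point probabilities ≤ observed × (1 + 1e-7).
- Degenerate inputs are flagged, not errored, where the pipeline can
  continue: all-zero differences (p = 1), constant tau vectors (p = 1),
  zero pooled variance (p = 1), all-zero proteins (`uninformative`).

## Problem sizes used by the test and acceptance suites

Unit tests run on 30–300-protein simulations. The deep suites use: 200
null data sets of 500 proteins and 25 powered data sets for differential
calibration; 510 random instances against the exact-test enumeration
oracles; 100 instances against the exhaustive Ward oracle; 200 null
concordance simulations of 120-gene panels with 12 participants; and 60
clustering-recovery simulations of 250 proteins. These sizes give
binomial standard errors comfortably inside the asserted bands while
keeping the default test run to a few minutes.

## Known limitations

- The Poisson model has no residual dispersion parameter; overdispersion
  *within* pairs (e.g. technical run variation) would inflate the Z
  statistics. The interface reserves a negative-binomial extension.
- Total-SpC offsets are compositional (above).
- Tau-b concordance against a padded background is anticonservative
  (above); the reported n_concordant is unaffected.
- Leaf order, not being seriation-optimized, may differ from
  PermutMatrix-style displays even when topology matches.
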