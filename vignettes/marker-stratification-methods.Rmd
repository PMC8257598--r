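---
title: "Methods: marker-based stratification, oncoactivity and nearest-template prediction"
author: "OncoStrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based stratification, oncoactivity and nearest-template prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OncoStrat)
```

# The analysis model

OncoStrat implements a stratified-transcriptome analysis that is common in
tumor molecular pathology: a cohort of tumors is split into two strata by the
expression of a single marker gene (for instance *ESR1*, encoding estrogen
receptor alpha, in hepatocellular carcinoma), the strata are characterized by
a differential-expression signature, each sample receives an "oncoactivity"
score summarizing coordinate oncogene activation and tumor-suppressor
repression, external cohorts are classified against the signature by nearest
template prediction (NTP), and the strata are related to survival and
clinicopathological covariates.

Every stage is exposed as a function; `runPipeline()` composes them in the
order stratify → differential expression → oncoactivity → NTP → survival and
association statistics.

## Median-cutoff stratification

`medianSplit()` uses the sample median of the marker's log2 expression as
the cutoff: strictly above is HIGH, at or below is LOW. Sending ties to LOW
fixes the arithmetic for odd cohorts — with 371 distinct values the split is
185 HIGH / 186 LOW. The split is invariant under any strictly monotone
transform of the marker values, so normalization choices that preserve rank
do not move samples between strata.

`madFilter()` selects variably expressed genes by raw median absolute
deviation, median(|x − median(x)|), **without** the 1.4826 normal-consistency
constant. Published MAD thresholds rarely state their convention; raw MAD is
the simpler default here and the constant is exposed as an argument.
`clusterConcordance()` quantifies how well unsupervised structure reflects
the strata: average-linkage hierarchical clustering on a (1 − Pearson)
distance cut at k = 2, clusters matched to strata by the
agreement-maximizing assignment. Neither the clustering algorithm nor the
linkage is canonical for this analysis; 1 − Pearson with average linkage is
the most common transcriptome convention and both are deliberate,
documented stand-ins rather than an attempt to reproduce a specific
dendrogram.

## Permutation t-test signatures

`permutationTStats()` computes a Welch (unequal-variance) t per gene —
safer than the pooled form under stratum-size imbalance — and a log2 fold
change defined as the difference of log2 means (printed fold-change
thresholds of 0.5 and 1.0, and per-gene values like 3.83, are only coherent
on the log scale). The permutation null relabels samples with group sizes
fixed. Two null modes are offered:

* **gene-wise** (`pooledNull = FALSE`): each gene is compared with its own
  `nPerm` null statistics; p-values are plus-one corrected,
  p ≥ 1/(nPerm + 1).
* **pooled** (`pooledNull = TRUE`, default): null statistics are pooled
  across genes, giving resolution 1/(nPerm × nGenes + 1). Thresholds such
  as p < 10⁻⁶ are unreachable gene-wise at desk scale; pooling achieves
  that resolution with nPerm ≈ 1000 under the exchangeability assumption
  that null t statistics are comparable across genes (reasonable on a
  variance-stabilized log scale).

`exhaustive = TRUE` enumerates all relabelings (small cohorts) and returns
the exact permutation p, which the tests compare against an independent
brute-force enumeration. `buildSignature()` thresholds on p and fold change
to produce the two directional gene sets; membership is monotone in both
thresholds, and flipping the stratum labels swaps the two sets exactly.

## Running-sum enrichment and oncoactivity

`enrichmentScore()` is the classic weighted Kolmogorov–Smirnov running sum:
walking the ranked list, hits add |metric|^weightExp (normalized by the
total hit weight) and misses subtract 1/(N − nHits); the enrichment score
(ES) is the running sum's signed maximum absolute deviation. When the
maximum and minimum deviations tie in magnitude the positive extreme is
returned (a 10⁻⁹ tolerance guards against floating-point accumulation
order). If every hit has metric 0 (possible with weightExp > 0), hits fall
back to equal weights instead of producing 0/0.

For **two-group GSEA** (`gseaTwoGroup()`), genes are ranked by the
signal-to-noise ratio with the classic variance floor (each group SD is
floored at max(0.2·|mean|, 0.2)); the null is phenotype relabeling, NES is
the ES divided by the mean |null ES| of matching sign, and the nominal p is
the plus-one-corrected same-sign tail. The default weight exponent is 1.

For **per-sample scoring** (`sampleEnrichment()`), genes are ranked within
each sample and the metric is the gene's rank from the bottom, so the score
depends only on the within-sample ordering: adding a constant to a sample,
re-ordering the gene rows, or any within-sample monotone transform (at
weightExp = 0) leaves it unchanged. The default weight exponent is 0.25,
the usual single-sample convention. Whether the published oncoactivity ES
was a per-sample statistic or a two-group ES evaluated per sample is not
specified in its source; the per-sample reading is implemented because "for
each sample" has no meaning for a phenotype-labeled two-group ES, and
because it makes the score usable on unlabeled external cohorts.

`oncoactivityScores()` reports, per sample, ES over an oncogene set minus
ES over a tumor-suppressor set. Two identities pin the implementation down:
the score is identically zero when the two sets coincide, and swapping the
sets negates every score exactly. `compareGroupScores()` compares scores
between strata by a two-sided Wilcoxon rank-sum test (exact enumeration up
to 10 + 10 samples).

## Nearest template prediction

`buildTemplates()` encodes the signature as a ±1 template over the
signature genes found in the target cohort (error below 50% overlap by
default — pooled multi-platform cohorts lose genes, and a silent heavy loss
would bias calls). `ntpClassify()` z-scores each template gene across
samples, assigns each sample to the nearer of the template and its
negation by cosine distance (1 − cosine similarity), and derives
significance from resampled templates: random ±1 vectors with the same
+/− composition as the real template, which controls for the imbalance
between the two signature arms. The null distance of a sample to a random
template is the distance to the nearer of the template and its negation,
mirroring the observed nearest-template distance; this makes the procedure
exactly symmetric under negation of the expression matrix (calls swap,
distances and p-values unchanged). Per-sample p-values are plus-one
corrected, the FDR is Benjamini–Hochberg across samples, and samples at
FDR ≥ threshold (default 0.05) are reported as ND (not determined). The
original NTP publications leave the exact null construction to their
references; the contract above is one defensible reading, implemented and
tested as stated.

## Survival and association statistics

Kaplan–Meier curves, the log-rank test and Cox proportional-hazards
regression are computed through the survival package (`survfit`,
`survdiff`, `coxph`); OncoStrat's wrappers fix the conventions: Efron tie
correction by default (more accurate with tied follow-up months; Breslow
retained for cross-checks), Wald 95% CIs and p-values (what a hazard ratio
with a symmetric CI on the log scale implies), convergence at relative
log-likelihood change < 10⁻⁹ or 50 iterations, and zero follow-up times
bumped to half the smallest positive time with a warning (registry cohorts
contain day-of-surgery events). The classical identity that the Cox score
test at β = 0 equals the log-rank chi-square (tie-free data, one binary
covariate) is verified to 10⁻⁶ in the tests.

`fisherExact()` reports the sample odds ratio ad/bc and offers two
two-sided conventions: `"minlik"` (sum of hypergeometric probabilities no
larger than the observed table's — the convention of `fisher.test` and most
software) and `"doubled"` (twice the smaller one-sided tail, capped at 1).
Published p-values come from either convention depending on the software
used; on the motivating cohort's microvascular-invasion table
(12, 20 | 182, 125) the doubled convention reproduces the published
two-sided p of 0.029 (0.0298) while the minimum-likelihood convention gives
0.0235, so both are exposed and the worked example in the tests anchors on
the doubled form. Chi-square (optional Yates correction for 2×2) and
Student/Welch t-tests complete the Table-1-style utilities;
`contingencyRates()` turns count tables into the row percentages such
tables print.

# The synthetic-cohort generator

`simulateCohort()` produces the structure the analysis assumes, with known
ground truth: two latent subtypes (HIGH and LOW, the LOW stratum taking the
extra sample for odd n); per-gene baselines μ_g ~ Uniform(2, 12) on the
log2 scale, spanning realistic microarray/RNA-seq intensities without
modeling counts; Gaussian noise with SD `sigma`; a `delta` log2 shift for
each differentially expressed gene in its subtype; a `markerDelta` shift of
the stratifying marker; additive per-dataset batch offsets; and exponential
survival with rate `baselineHazard` (HIGH) versus `baselineHazard × hr`
(LOW), administratively censored at `censorTime` — the simplest censoring
mechanism that still exercises the right-censoring paths. Two clinical
covariates with subtype-dependent distributions (age, a binary invasion
indicator) feed the association utilities. One global seed drives a fixed
sub-stream per component (expression, survival, gene sets), so changing
survival parameters cannot perturb the expression draw.

Defaults are desk-scale study conditions: 200 samples, 2000 genes, 10% DEGs
at delta = 1 log2 unit, sigma = 0.5, markerDelta = 2, hazard ratio 2 with
baseline hazard 0.02/month and censoring at 120 months, and
oncogene/tumor-suppressor sets of 100/150 genes, half drawn from the true
DEGs of the matching direction (`simulateGeneSets()`), scaled down from
genome-wide lists of several hundred to ~1000 genes.

What the generator deliberately does **not** emulate: count-level noise
(negative binomial dispersion), gene–gene correlation beyond the subtype
effect, probe-level artifacts, non-proportional hazards, and informative
censoring. Tests passing on this generator therefore validate the
*algorithms* — calibration under the null, recovery of planted structure,
exact agreement with oracles — not the biological fidelity of any
particular dataset.

# Numerical choices and degenerate inputs

* Permutation and resampling p-values are plus-one corrected, so they are
  never 0 and type-I error control is valid.
* The pooled permutation null is searched with a sorted-vector binary
  search; a 10⁻¹⁰ relative tolerance counts exact ties (which arise only at
  t = 0, e.g. zero-variance genes, where p = 1 is the required answer).
* Genes with zero variance in both groups get t = 0 with a warning rather
  than NaN; zero-variance template genes are dropped from NTP with a
  warning; a gene set that is empty on, or equal to, the ranked universe is
  an error.
* Ranking ties are broken by gene symbol order everywhere, so results are
  deterministic across platforms.
* Duplicate gene symbols at load are resolved by keeping the row with the
  highest mean (deterministic, and biased toward the better-measured
  probe); symbols are uppercased, and cross-dataset merging intersects
  uppercased symbols — the lowest common denominator for pooled series that
  share only symbol annotation. ComBat-style empirical-Bayes batch
  correction is out of scope; `mergeDatasets(adjust = "center")` removes
  per-dataset location shifts by median centering, which is idempotent and
  exactly removes constant offsets.

# Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen so
each property is decisive yet the whole suite runs in well under a minute
per file: enrichment-score oracles on 200 random instances (N ≤ 50); exact
3-vs-3 permutation enumeration; type-I error on a 1000-gene null cohort
(40 samples, 200 permutations, pooled null); NTP recovery on a 100 + 100
cohort at delta = 1.5, sigma = 0.5 with 1000 resampled templates; Cox
hazard-ratio recovery at n = 1000 and CI coverage over 200 replicates of
n = 300; and byte-identity of two pipeline runs on a 60-sample simulated
config.

# Known limitations

* The oncoactivity ES convention (per-sample, rank-weighted, weightExp
  0.25) and the NTP null are documented contracts, not certified
  re-derivations of any specific publication's internals.
* The pooled permutation null assumes cross-gene exchangeability of null t
  statistics; strongly heteroskedastic genes can violate it. The gene-wise
  mode is the conservative fallback.
* No moderated-variance (empirical Bayes) differential expression, no
  multi-class (>2 template) NTP, no time-varying covariates or competing
  risks, and no probe-to-gene mapping from platform annotation.
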