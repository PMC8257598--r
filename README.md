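# OncoStrat

Marker-based stratification of tumor transcriptome cohorts, with
oncoactivity scoring, nearest-template prediction and survival statistics.

## The problem

In tumor molecular pathology a recurring analysis pattern asks: does the
expression of a single marker gene (say *ESR1*, encoding estrogen receptor
alpha, in hepatocellular carcinoma) define clinically meaningful subtypes?
Answering it takes a chain of steps — split the cohort at the marker's
median, derive a differential-expression signature between the strata, score
each tumor's oncogenic drive, classify independent cohorts against the
signature, and test the strata against survival and clinicopathological
variables. OncoStrat packages that chain as tested, reusable functions for
computational oncologists, with a ground-truth synthetic-cohort generator so
every stage can be validated end to end at desk scale.

## The methods at its core

- **Median split** — cutoff = median marker log2 expression; HIGH strictly
  above, ties to LOW (371 distinct values → 185/186).
- **Permutation t-test signatures** — per gene, Welch t and log2 fold change
  Δ = mean(HIGH) − mean(LOW); permutation null with fixed group sizes,
  optionally pooled across genes so thresholds like p < 10⁻⁶ are reachable;
  signature membership: p < p_max and |Δ| > fc_min, by direction.
- **Running-sum enrichment (ES)** — weighted Kolmogorov–Smirnov statistic
  over a ranked gene list; two-group GSEA with phenotype-permutation NES and
  nominal p, and per-sample (rank-metric) scores.
- **Oncoactivity** — per sample, ES over an oncogene set minus ES over a
  tumor-suppressor set:
  `Oncoactivity = ES_oncogene − ES_TSG`.
- **Nearest template prediction (NTP)** — cosine distance of each
  (cross-sample z-scored) sample to a ±1 signature template; significance by
  resampled templates of the same composition, Benjamini–Hochberg FDR across
  samples, calls at FDR < 0.05, otherwise "ND".
- **Survival & association statistics** — Kaplan–Meier, log-rank, Cox
  proportional hazards (Efron ties, Wald CIs) via the survival package;
  Fisher's exact (both two-sided conventions), chi-square, t-tests and
  contingency rates for Table-1-style summaries.

See `vignettes/marker-stratification-methods.Rmd` for conventions,
assumptions and numerical details.

## Worked example

```r
library(OncoStrat)

cfg <- simConfig(nSamples = 100L, nGenes = 500L, fracDeg = 0.1, delta = 1.2,
                 sigma = 0.5, nOnco = 30L, nTsg = 40L, seed = 42L)
co    <- simulateCohort(cfg)                      # expression + clinical + truth
strat <- medianSplit(co$expr, "ESR1")
strat
#> StratificationResult on marker ESR1
#>   cutoff (log2): 5.436
#>   HIGH: 50  LOW: 50

stats <- permutationTStats(co$expr, strat, nPerm = 200, seed = 43L)
sig   <- buildSignature(stats, pMax = 1e-3, fcMin = 0.5)
sig
#> SignaturePair
#>   up in HIGH: 26 genes; up in LOW: 25 genes
#>   thresholds: p < 0.001, |log2 FC| > 0.5

sets <- simulateGeneSets(co$truth, cfg)
onc  <- oncoactivityScores(co$expr, sets$onco, sets$tsg)
compareGroupScores(oncoactivity(onc), strat)$p    # LOW stratum scores higher
#> 1.2e-16

tmpl  <- buildTemplates(sig, co$expr)
ntpClassify(co$expr, tmpl, nNull = 1000, seed = 44L)
#> NTPCalls for 100 samples (FDR < 0.05)
#>   A: 50  B: 50  ND: 0

lab <- strataLabels(strat)[co$clinical$sample_id]
logrankTest(co$clinical$time, co$clinical$event, lab)$p
#> 5.03e-07
coxFit(co$clinical$time, co$clinical$event,
       data.frame(low = as.integer(lab == "LOW")))
#>      coef    hr lo95  hi95 p
#> low 1.108 3.029 1.93 4.754 0
```

The split is exactly 50/50 at the median; the recovered signature (51 genes)
captures the planted differential genes; oncoactivity is sharply higher in
the LOW stratum (Wilcoxon p ≈ 10⁻¹⁶); NTP re-identifies every sample's
subtype with no ND calls; and the LOW stratum's hazard ratio estimate (3.0,
95% CI 1.9–4.8, true value 2 at this small n) shows the expected survival
disadvantage (log-rank p ≈ 5×10⁻⁷).

A full run from one config — including written TSV/GMT/JSON outputs and a
reproducibility manifest — is `runPipeline()`; a thin command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

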