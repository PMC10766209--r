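# survscan

Expression-based survival stratification with honest inference, for
transcriptomics analysts who dichotomize patient cohorts at an "optimal"
expression cutoff and need p-values that survive the selection.

## The problem and the methods

Splitting a cohort into *high* and *low* expressors at the threshold that
maximizes the separation of their survival curves (minimum-p
dichotomization) badly inflates type-I error: the best of 81 candidate
log-rank tests looks significant far too often. `survscan` implements the
full procedure and its correction:

- **Cutpoint scan.** Every quantile level q = 0.10, 0.11, …, 0.90 of the
  expression values is tried as a dividing threshold (strictly-greater
  split); at each admissible split the two-group log-rank chi-square

  χ² = (Σᵢ Oᵢ − Eᵢ)² / Σᵢ Vᵢ

  is computed over distinct event times (hypergeometric expectation Eᵢ and
  variance Vᵢ, multi-death tie handling), and the maximizing threshold is
  selected.
- **Permutation test that re-optimizes the cutoff.** Under the null, the
  (time, event) pairs are shuffled against the fixed expression vector and
  the *entire scan* — including re-selection of the best cutoff — is
  repeated N = 10 000 times; p is the fraction of permutation maxima
  exceeding the observed maximum. This is the correct null for a
  maximally selected statistic.
- **Univariate Cox regression** on log2 expression (Newton–Raphson on the
  partial likelihood, Efron tie correction), so exp(β) is the hazard
  ratio per 2-fold expression increase, with Wald 95% CI.
- **Universal threshold.** For two variables on the same patients (e.g.
  two splice isoforms on a common log2(FPKM+1) scale), the single
  absolute level maximizing the mean of the two log-rank statistics over
  the union of both quantile grids.
- **Signed DEG-set overlap.** Differentially expressed gene sets
  (FDR < 0.05, |fold change| ≥ 1.5) carry a direction sign; a Monte-Carlo
  test draws random same-size sets from the gene universe with fair-coin
  signs and scores how often the concordant (or discordant, or total)
  overlap exceeds the observed one. A hypergeometric upper-tail test,
  Benjamini–Hochberg adjustment and Spearman fold-change concordance
  round out the set comparisons.
- **Expression preparation.** TMM normalization factors (doubly trimmed,
  inverse-variance-weighted mean of M-values), log2(FPKM+1)
  transformation, low-expression filtering, and isoform-ratio summaries.
- **Synthetic data generators** for every stage — survival cohorts with a
  planted step or log-linear hazard effect, DEG-set pairs with an exact
  planted overlap composition, negative-binomial count matrices with
  planted depth/composition bias — each returning its ground truth, so
  the whole pipeline is testable offline.

## Worked example

```r
library(survscan)

# a 500-patient cohort whose hazard triples above the median expression
sim  <- simulate_cohort(n = 500, hr_high = 3, cut_quantile = 0.5, seed = 1)
scan <- scan_cutpoints(sim$cohort)
scan
#> cutpoint_scan: 81 levels (0 skipped)
#>   best: level 0.50, threshold 5.945, log-rank chi-square 116.177 (naive p 4.35e-27)
#>   naive p is biased by cutoff selection; use permutation_test()

permutation_test(sim$cohort, n_perm = 10000, seed = 2)
#> permutation_result: observed max log-rank 116.177
#>   p = 0 (strict rule; strict 0, add-one 9.999e-05; N = 10000, seed 2)

cox_univariate(sim$cohort)
#> cox_result: HR 1.320 per 2-fold expression increase [95% CI 1.233-1.414]
#>   beta 0.2777 (se 0.0350), Wald p 1.94e-15, 425 events / 500 patients (efron ties)
```

The scan recovers the planted median cutpoint exactly (level 0.50,
threshold 5.945 vs. planted 5.945); the permutation p stays below 1/10 000
even after paying for the cutoff selection. The Cox HR of 1.32 per 2-fold
change is the marginal log-linear summary of a step-shaped effect — the
two models answer different questions.

```r
deg <- simulate_deg_pair(G = 20000, n_a = 1500, n_b = 1500,
                         n_concordant = 120, n_discordant = 30, seed = 3)
mc_overlap_test(deg$set_a, deg$set_b, n_iter = 10000, seed = 4)
#> overlap_result: shared 150 (concordant 120, discordant 30) of |a|=1500, |b|=1500, G=20000
#>   concordant-mode p = 0 (strict rule, N = 10000)
```

An end-to-end run (normalization → scan → permutation → Cox → overlap)
is driven by a YAML config through `run_pipeline()`, or from a shell via
`inst/scripts/survscan-pipeline.R --config analysis.yaml`; it writes a
JSON report plus TSV artifacts and is bit-reproducible for a fixed seed.

## Vignette

`vignettes/optimal-cutpoint-survival.Rmd` documents the statistical
models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical/design choices.
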