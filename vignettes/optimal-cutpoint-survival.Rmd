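---
title: "Optimal-cutpoint survival stratification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal-cutpoint survival stratification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscan)
```

## Why a permutation test that re-optimizes the cutoff

Dichotomizing a continuous expression variable at the threshold that
maximizes the two-group log-rank statistic is a *maximally selected*
test: the best of 81 correlated chi-square statistics is not chi-square
distributed, and reading its naive p-value off $\chi^2_1$ is
anticonservative by an order of magnitude. The package's inferential
core is therefore a permutation scheme in which the *whole selection* is
repeated under the null: survival pairs $(t_i, \delta_i)$ are shuffled
against the fixed expression vector, the quantile-grid scan re-selects
its own optimal cutoff in every permutation, and the observed maximal
statistic is referred to the distribution of permutation maxima. The
acceptance suite quantifies the difference on simulated null cohorts:
the corrected test rejects at close to its nominal 0.05 level while the
naive best-of-grid p rejects far more often.

Assumptions worth keeping in mind:

- *Exchangeability.* Shuffling $(t, \delta)$ against expression assumes
  patients are exchangeable under the null — no covariate structure
  (stage, site, batch) ties survival to expression through a confounder.
  The test corrects selection bias, not confounding.
- *Right-censoring that is uninformative* given the group, as usual for
  Kaplan–Meier and the log-rank test.
- *One variable at a time.* The scan is univariate; the universal
  threshold couples two variables only through a shared candidate level.

## The pieces and their parameters

### Cutpoint scan (`scan_cutpoints`)

| parameter | default | meaning |
|---|---|---|
| `q_lo`, `q_hi`, `q_step` | 0.10, 0.90, 0.01 | quantile grid of candidate thresholds (81 levels) |
| `min_group` | 2 | smallest admissible group after a split |

Thresholds are type-7 quantiles (linear interpolation between order
statistics, the default of the common analysis environments); the
quantile type is a deliberate, documented choice since several
conventions exist. The split rule is strictly greater: ties at the
threshold fall into the low group. Levels whose split leaves a group
below `min_group`, or no events, are recorded as skipped; if every level
is skipped (e.g. constant expression) the scan errors rather than
returning a degenerate optimum. Equal maximal statistics resolve to the
smallest quantile level, deterministically.

### Permutation test (`permutation_test`)

`n_perm` defaults to 10 000. Two tail conventions are always computed:
the strict fraction $\#\{S^* > S_{obs}\}/N$ (which can be exactly 0) and
the add-one estimator $(1 + \#\{S^* \ge S_{obs}\})/(N+1)$ (which cannot).
The strict rule is the default; both appear in every report, and the
choice matters exactly when the observed statistic exceeds all
permutation maxima. Permutations in which no cutoff is admissible score
0 — no admissible split is the weakest possible evidence — and stay in
the denominator; their count is logged. The permutation loop runs in
C++ with R's RNG, so a fixed seed reproduces results bit-identically.

### Cox regression (`cox_univariate`)

Newton–Raphson from $\beta = 0$ on the partial likelihood with the Efron
tie correction (Breslow available), convergence at
$|\Delta\beta| < 10^{-9}$ or 50 iterations. Because the covariate is
log2 expression, $e^\beta$ is the hazard ratio per 2-fold expression
increase; the 95% CI is Wald, $\exp(\beta \pm 1.959964\,\mathrm{se})$.
Degenerate inputs error explicitly: a constant covariate, fewer than two
events, and monotone likelihoods (detected either by $|\beta| > 50$
during iteration or by a collapsed information matrix — a Wald se more
than two orders of magnitude above the covariate's scale — at
convergence).

### Universal threshold (`universal_threshold`)

Both cohorts must carry identical patients and survival data. The
candidate grid is the union of both variables' 81 quantile thresholds,
deduplicated and sorted — about twice as dense as either variable's own
grid. At each candidate, both cohorts split at the *same absolute
level*; the mean of the two log-rank statistics is maximized. The
reported "avg p" is the mean of the two per-variable permutation
p-values, each obtained by the re-optimizing permutation test restricted
to the same fixed grid. A joint (single-permutation-stream) p would be
an equally defensible construction; the marginal-mean definition is what
the output labels, and the choice is recorded in the report metadata.

### TMM normalization (`tmm_factors`)

Per sample against a reference: per-gene
$M = \log_2\frac{y_k/N_k}{y_r/N_r}$ and
$A = \tfrac12(\log_2 y_k/N_k + \log_2 y_r/N_r)$ over genes with nonzero
counts in both samples (no pseudocounts); the extreme `trim_m` = 30% of
M and `trim_a` = 5% of A are discarded on each side; the factor is
$2^{\sum w_g M_g / \sum w_g}$ with binomial inverse-variance weights;
factors are centred to geometric mean 1. The reference (`"auto"`) is the
sample whose upper-quartile count fraction is closest to the mean of
those fractions.

One deliberate design choice: by default the weight variances are
evaluated at a standardized common depth
($w_g^{-1} = (1-p_k)/p_k + (1-p_r)/p_r$ on the count proportions), so
the factors depend on relative composition only and are *exactly*
invariant to scaling any sample's counts — the property a normalization
factor is meant to have, and one the tests assert at $10^{-9}$.
Evaluating the variances at the observed library sizes instead
(`weight_variance = "observed"`) reproduces the edgeR implementation
bit-for-bit; the two weightings coincide whenever library sizes are
equal and differ only through the relative gene weights otherwise. The
test suite pins both: the observed mode against edgeR at $10^{-10}$, the
default against an independent transcription of the trimmed
weighted-mean formulas.

### Low-expression filter, FPKM, ratios

`filter_low_expression` keeps a gene if its count reaches
`min_count` = 10 (rescaled to each library via a CPM cutoff at the
median library size) in at least $n_{\min}$ samples — the smallest group
size when groups are given, half the samples otherwise — and its total
count reaches `min_total` = 15. `fpkm_log2` computes
$\log_2(\mathrm{FPKM}+1)$ with effective library sizes
$N_k f_k$. `isoform_ratio` summarizes two isoforms on the linear FPKM
scale (recovered as $2^v - 1$) as a ratio of cohort means by default;
whether a published isoform ratio was a ratio of means, of medians, or a
mean of per-sample ratios is rarely stated, so all three summaries are
available and the one used is echoed in the result.

### Signed overlap (`mc_overlap_test`)

DEG sets are built with the conventional thresholds FDR < 0.05 and
|FC| ≥ 1.5, each gene signed by its direction of change. Each
Monte-Carlo iteration draws two uniform subsets of the universe with the
observed cardinalities and assigns every drawn gene an independent
fair-coin sign. Three statistics are accumulated per iteration —
concordant, discordant, and total shared — because published overlap
claims come in both directional flavours; the mode the p-value refers to
is explicit in the result, and in `"shared"` mode the null is exactly
hypergeometric (the tests verify agreement with the analytic upper
tail). The gene universe $G$ is the caller's responsibility (all
protein-coding genes in scope is the usual choice); when the pipeline
builds sets from two DE tables without an explicit universe it uses the
union of genes present in either table and records that rule in the
report.

## What the synthetic generators emulate — and what they do not

`simulate_cohort` draws log2 expression from a normal distribution
(matching the log2(FPKM+1) working scale), plants either a step effect
(hazard × `hr_high` above a threshold — the estimand of the cutpoint
scan) or a log-linear effect (the estimand of Cox regression), and
applies exponential event and censoring times; the default censoring
rate is a quarter of the baseline hazard, i.e. roughly 20% censored
under the null. `simulate_deg_pair` plants an exact overlap composition;
`simulate_counts` plants known depth factors, negative-binomial
dispersion and an asymmetric fold-change fraction.

These generators make every stage verifiable against known truth, but
they are deliberately idealized: proportional or piecewise-constant
hazards, no covariate-dependent censoring, no correlation structure
among genes, no batch effects, no isoform-level quantification
uncertainty, and normally distributed expression with no zero-inflation.
Passing the recovery and calibration suites therefore demonstrates that
the *algorithms* are correct and calibrated under their own model — not
that real cohorts satisfy that model.

## Numerical choices and validation problem sizes

- Log-rank tie handling uses the multi-death hypergeometric variance; a
  split with zero variance and balanced observed/expected events scores 0.
- All permutation/Monte-Carlo draws run under R's RNG (seed arguments),
  so every result object is reproducible bit-for-bit.
- The validation suite checks: the log-rank statistic against a
  brute-force oracle on 1000 random micro-cohorts ($n \le 6$, tolerance
  $10^{-12}$); Kaplan–Meier against the empirical survival function
  without censoring; Cox recovery of a true HR 2.0 at $n = 2000$ over 50
  seeds and null calibration over 100 seeds; type-I error of the
  corrected vs. naive cutpoint p over 500 null cohorts of $n = 300$ with
  1000 permutations each; cutpoint recovery (planted median, HR 3,
  $n = 500$, 100 seeds) and universal-threshold recovery (planted level
  6.5, $n = 1000$ — the scale of the combined colorectal TCGA cohorts —
  100 seeds, within one step of the union grid); Monte-Carlo overlap
  p-values against exhaustive enumeration for universes of size 7–8 and
  against the hypergeometric tail; TMM depth invariance and centring at
  $10^{-9}$ plus a 20-gene hand-checked example; BH and Spearman against
  definitional recomputation at $10^{-12}$; and bit-identical end-to-end
  pipeline reports across repeated runs.

## Known limitations

- The scan's p-value is honest for the *scan's own* selection; it cannot
  repair selection happening upstream (gene shopping across thousands of
  candidates needs its own multiplicity control, e.g. `bh_adjust` across
  genes).
- The universal threshold assumes the two variables live on a common,
  comparable scale; it is meaningless across differently normalized
  matrices.
- Cox results are univariate by design — no adjustment, stratification
  or competing risks.
- The Monte-Carlo overlap null treats gene draws as exchangeable;
  co-expression structure in real DEG sets makes the null overlap wider
  than this model assumes, so its p-values are best read comparatively.
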