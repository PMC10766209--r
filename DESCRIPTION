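Package: survscan
Title: Optimal-Cutpoint Survival Stratification with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expression-based survival stratification of patient
    cohorts. Implements the maximally selected log-rank cutpoint scan over a
    quantile grid, a permutation test that re-optimizes the cutoff under the
    null to correct the selection bias of minimum-p dichotomization,
    univariate Cox proportional-hazards regression on log2 expression
    (hazard ratios per 2-fold change), and a joint two-variable universal
    threshold search. Also provides a signed Monte-Carlo test for
    directional overlap of differentially expressed gene sets, hypergeometric
    overlap testing, TMM normalization with log2(FPKM+1) transformation and
    low-expression filtering, and seeded synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
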