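#' Simulate a survival cohort with a planted expression effect
#'
#' Generates a right-censored cohort whose hazard depends on a normal
#' log2-expression covariate, with known ground truth. Two effect shapes
#' are available: a step effect (hazard multiplied by `hr_high` above a
#' planted threshold -- the shape the cutpoint scan estimates) and a
#' log-linear effect (hazard multiplied by `hr_high` per +1 log2 unit --
#' the shape Cox regression estimates). `hr_high = 1` gives a global-null
#' cohort in either mode.
#'
#' Event times are exponential with the patient-specific hazard;
#' censoring is exponential with rate `censor_rate` (and/or administrative
#' at `admin_time`). The default `censor_rate` of 1/4 of the baseline
#' event rate yields roughly 20% censoring in the null model.
#'
#' @param n Number of patients (>= 10).
#' @param baseline_rate Baseline exponential hazard per time unit.
#' @param cut_quantile Planted cutoff as a quantile of the realized
#'   expression values (step mode; ignored if `cut_level` is given).
#' @param cut_level Planted cutoff as an absolute log2 level (step mode).
#' @param hr_high Hazard multiplier above the cutoff (step mode) or per
#'   +1 log2 unit (log-linear mode).
#' @param effect `"step"` (default) or `"loglinear"`.
#' @param expr_mean,expr_sd Normal parameters of the log2 expression.
#' @param censor_rate Exponential censoring hazard; 0 disables random
#'   censoring.
#' @param admin_time Administrative censoring time (default `Inf`).
#' @param seed Integer seed.
#'
#' @return List with `cohort` (a [survival_cohort()]) and `truth` (planted
#'   threshold / quantile, `hr_high`, effect shape, realized event
#'   fraction).
#' @export
simulate_cohort <- function(n = 300, baseline_rate = 0.1, cut_quantile = 0.5,
                            cut_level = NULL, hr_high = 1,
                            effect = c("step", "loglinear"),
                            expr_mean = 6, expr_sd = 1.5,
                            censor_rate = baseline_rate / 4, admin_time = Inf,
                            seed = NULL) {
  effect <- match.arg(effect)
  if (n < 10) stop("n must be >= 10")
  if (baseline_rate <= 0 || hr_high <= 0 || expr_sd <= 0)
    stop("rates, hazard ratios and expr_sd must be positive")
  if (is.null(cut_level) && (cut_quantile <= 0 || cut_quantile >= 1))
    stop("cut_quantile must lie in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  expr <- stats::rnorm(n, expr_mean, expr_sd)
  if (effect == "step") {
    threshold <- if (is.null(cut_level)) {
      unname(stats::quantile(expr, cut_quantile, type = 7))
    } else {
      cut_level
    }
    hazard <- baseline_rate * ifelse(expr > threshold, hr_high, 1)
  } else {
    threshold <- NA_real_
    hazard <- baseline_rate * hr_high^(expr - expr_mean)
  }
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else Inf
  censor_time <- pmin(censor_time, admin_time)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  if (mean(event) < 0.05)
    warning("fewer than 5% of patients experience an event")
  # guard against exact zeros from underflow
  time <- pmax(time, .Machine$double.eps)
  list(
    cohort = survival_cohort(time, event, expr),
    truth = list(threshold = threshold,
                 cut_quantile = if (is.null(cut_level)) cut_quantile else NA_real_,
                 hr_high = hr_high, effect = effect,
                 event_fraction = mean(event))
  )
}

#' Simulate a pair of signed DEG sets with planted overlap
#'
#' Draws two signed gene sets from a universe of `G` genes with an exact,
#' known overlap composition: `n_concordant` shared genes with equal
#' signs, `n_discordant` shared genes with opposite signs, and the
#' remainders exclusive to each set with independent random signs.
#'
#' @param G Universe size.
#' @param n_a,n_b Set cardinalities.
#' @param n_concordant,n_discordant Planted shared-gene counts.
#' @param seed Integer seed.
#'
#' @return List with `set_a`, `set_b` ([signed_gene_set()]s) and `truth`
#'   (the planted counts).
#' @export
simulate_deg_pair <- function(G = 20000, n_a = 1000, n_b = 1000,
                              n_concordant = 50, n_discordant = 50,
                              seed = NULL) {
  n_shared <- n_concordant + n_discordant
  if (n_shared > min(n_a, n_b)) stop("planted overlap exceeds a set size")
  if (n_a > G || n_b > G) stop("set size exceeds universe")
  if (n_a + n_b - n_shared > G) stop("sets cannot fit in the universe")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- paste0("g", seq_len(G))
  pool <- sample(ids)  # random gene order
  shared_conc <- pool[seq_len(n_concordant)]
  shared_disc <- pool[n_concordant + seq_len(n_discordant)]
  rest <- pool[-(seq_len(n_shared))]
  only_a <- rest[seq_len(n_a - n_shared)]
  only_b <- rest[n_a - n_shared + seq_len(n_b - n_shared)]

  sign_conc <- sample(c(-1L, 1L), n_concordant, replace = TRUE)
  sign_disc <- sample(c(-1L, 1L), n_discordant, replace = TRUE)
  members_a <- stats::setNames(
    c(sign_conc, sign_disc,
      sample(c(-1L, 1L), length(only_a), replace = TRUE)),
    c(shared_conc, shared_disc, only_a))
  members_b <- stats::setNames(
    c(sign_conc, -sign_disc,
      sample(c(-1L, 1L), length(only_b), replace = TRUE)),
    c(shared_conc, shared_disc, only_b))
  list(set_a = signed_gene_set(members_a, G),
       set_b = signed_gene_set(members_b, G),
       truth = list(n_concordant = n_concordant, n_discordant = n_discordant,
                    n_shared = n_shared))
}

#' Simulate a negative-binomial count matrix
#'
#' Generates a genes-by-samples raw count matrix with log-normal gene
#' abundances, per-sample sequencing-depth factors, negative-binomial
#' noise, and an optional fraction of genes fold-changed in designated
#' samples (creating the asymmetric composition differences TMM exists to
#' correct). Gene lengths are uniform over `length_range`.
#'
#' @param n_genes,n_samples Matrix dimensions (>= 2 each).
#' @param mean_log_mu,sd_log_mu Parameters of the log-normal gene mean
#'   distribution (natural log scale).
#' @param dispersion Negative-binomial dispersion (`variance = mu +
#'   dispersion * mu^2`); 0 gives Poisson counts.
#' @param depth_factors Per-sample depth multipliers (recycled to
#'   `n_samples`).
#' @param de_fraction Fraction of genes fold-changed in `de_samples`.
#' @param de_fold Linear fold change applied to those genes.
#' @param de_samples Indices of affected samples (default: last sample).
#' @param length_range Gene length range in bp.
#' @param seed Integer seed.
#'
#' @return List with `cm` (a [count_matrix()]) and `truth` (depth factors,
#'   DE gene indices, fold).
#' @export
simulate_counts <- function(n_genes = 2000, n_samples = 2, mean_log_mu = 4,
                            sd_log_mu = 1.5, dispersion = 0.1,
                            depth_factors = 1, de_fraction = 0,
                            de_fold = 4, de_samples = n_samples,
                            length_range = c(500, 5000), seed = NULL) {
  if (n_genes < 2 || n_samples < 2) stop("need at least 2 genes and 2 samples")
  if (dispersion < 0) stop("dispersion must be >= 0")
  depth_factors <- rep_len(depth_factors, n_samples)
  if (any(depth_factors <= 0)) stop("depth_factors must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu0 <- exp(stats::rnorm(n_genes, mean_log_mu, sd_log_mu))
  de_idx <- integer(0)
  if (de_fraction > 0)
    de_idx <- sample.int(n_genes, round(de_fraction * n_genes))
  counts <- matrix(0L, n_genes, n_samples)
  for (s in seq_len(n_samples)) {
    mu <- mu0 * depth_factors[s]
    if (s %in% de_samples && length(de_idx)) mu[de_idx] <- mu[de_idx] * de_fold
    counts[, s] <- if (dispersion == 0) {
      stats::rpois(n_genes, mu)
    } else {
      stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
  }
  lengths_bp <- round(stats::runif(n_genes, length_range[1], length_range[2]))
  cm <- count_matrix(counts, lengths_bp,
                     gene_ids = paste0("g", seq_len(n_genes)),
                     sample_ids = paste0("s", seq_len(n_samples)))
  list(cm = cm, truth = list(depth_factors = depth_factors,
                             de_genes = sort(de_idx), de_fold = de_fold))
}
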