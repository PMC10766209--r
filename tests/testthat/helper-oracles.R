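# Independent oracle implementations used to validate the package's
# statistics. These are deliberately written as direct transcriptions of
# the defining formulas, sharing no code with the package internals.

# Brute-force two-group log-rank: accumulate observed, expected and
# hypergeometric variance at each distinct event time.
oracle_logrank <- function(time, event, group) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# Pairwise TMM factor for one sample against a reference: direct
# transcription of the trimmed, weighted-mean-of-M-values definition.
oracle_tmm_pair <- function(y_sample, y_ref, trim_m = 0.30, trim_a = 0.05) {
  n_s <- sum(y_sample)
  n_r <- sum(y_ref)
  both <- y_sample > 0 & y_ref > 0
  ys <- y_sample[both]; yr <- y_ref[both]
  m_vals <- log2((ys / n_s) / (yr / n_r))
  a_vals <- (log2(ys / n_s) + log2(yr / n_r)) / 2
  if (max(abs(m_vals)) < 1e-6) return(1)
  g <- length(m_vals)
  keep_m <- rank(m_vals) >= floor(g * trim_m) + 1 &
    rank(m_vals) <= g - floor(g * trim_m)
  keep_a <- rank(a_vals) >= floor(g * trim_a) + 1 &
    rank(a_vals) <= g - floor(g * trim_a)
  keep <- keep_m & keep_a
  # binomial variance of the log-ratio evaluated at a common depth
  p_s <- ys / n_s
  p_r <- yr / n_r
  weights <- 1 / ((1 - p_s) / p_s + (1 - p_r) / p_r)
  2^(sum(weights[keep] * m_vals[keep]) / sum(weights[keep]))
}

# Step-up Benjamini-Hochberg, transcribed from the procedure definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail by log-space summation of the mass function.
oracle_hypergeom_upper <- function(n_a, n_b, G, k) {
  if (k <= 0) return(1)
  js <- k:min(n_a, n_b)
  terms <- lchoose(n_a, js) + lchoose(G - n_a, n_b - js) - lchoose(G, n_b)
  sum(exp(terms))
}

# Exhaustive null law of the signed-overlap statistics for a small
# universe: enumerate every pair of subsets and, for each shared gene,
# every joint sign state of the pair (4 equally likely states per gene).
# Returns P(statistic > observed) for all three statistics.
oracle_overlap_exhaustive <- function(G, n_a, n_b, obs_concordant,
                                      obs_discordant, obs_shared) {
  subsets_a <- utils::combn(G, n_a, simplify = FALSE)
  subsets_b <- utils::combn(G, n_b, simplify = FALSE)
  max_s <- min(n_a, n_b)
  # joint distribution over (shared, concordant): concordant genes are the
  # shared genes whose two independent fair-coin signs agree (2 of the 4
  # joint states), enumerated explicitly below
  prob_conc_given_shared <- function(s) {
    if (s == 0) return(c(`0` = 1))
    states <- expand.grid(rep(list(1:4), s))  # ++, +-, -+, -- per gene
    agree <- matrix(unlist(states) %in% c(1, 4), nrow = nrow(states))
    tab <- table(rowSums(agree)) / nrow(states)
    tab
  }
  p_shared <- numeric(max_s + 1)
  for (A in subsets_a) {
    for (B in subsets_b) {
      s <- length(intersect(A, B))
      p_shared[s + 1] <- p_shared[s + 1] + 1
    }
  }
  p_shared <- p_shared / sum(p_shared)
  p_conc <- numeric(max_s + 1)
  p_disc <- numeric(max_s + 1)
  for (s in 0:max_s) {
    if (p_shared[s + 1] == 0) next
    cond <- prob_conc_given_shared(s)
    for (nm in names(cond)) {
      k <- as.integer(nm)
      p_conc[k + 1] <- p_conc[k + 1] + p_shared[s + 1] * cond[[nm]]
      p_disc[s - k + 1] <- p_disc[s - k + 1] + p_shared[s + 1] * cond[[nm]]
    }
  }
  tail_above <- function(pmf, obs) {
    idx <- which(seq_along(pmf) - 1 > obs)
    if (!length(idx)) 0 else sum(pmf[idx])
  }
  c(concordant = tail_above(p_conc, obs_concordant),
    discordant = tail_above(p_disc, obs_discordant),
    shared = tail_above(p_shared, obs_shared))
}

# Spearman rho by explicit rank-then-Pearson computation, p-value from
# the t approximation.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Random small survival cohort for oracle comparisons. Times are drawn
# from a small integer set so ties occur often.
random_tiny_cohort <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  repeat {
    time <- sample(1:4, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    group <- rbinom(n, 1, 0.5)
    if (sum(event) >= 1 && any(group == 0) && any(group == 1)) break
  }
  list(time = time, event = event, group = group,
       cohort = survival_cohort(time, event, expr = rnorm(n)))
}

# Two cohorts on shared patients whose hazard steps up at the same
# absolute expression level for both variables.
simulate_shared_level_pair <- function(n = 500, level = 6.5, hr = 3,
                                       baseline = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expr_a <- rnorm(n, 6, 1.5)
  expr_b <- rnorm(n, 6, 1.5)
  hazard <- baseline * hr^((expr_a > level) + (expr_b > level))
  event_time <- rexp(n, hazard)
  censor <- rexp(n, baseline / 4)
  time <- pmax(pmin(event_time, censor), .Machine$double.eps)
  event <- as.integer(event_time <= censor)
  ids <- paste0("pt_", seq_len(n))
  list(a = survival_cohort(time, event, expr_a, patient_ids = ids),
       b = survival_cohort(time, event, expr_b, patient_ids = ids))
}
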