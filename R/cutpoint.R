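#' Optimal-cutpoint scan over a quantile grid
#'
#' Scans expression quantile levels (default 0.10 to 0.90 in steps of
#' 0.01, i.e. 81 candidates) as dividing thresholds. At each level the
#' cohort is split into a high group (expression strictly greater than the
#' threshold) and a low group, and the two-group log-rank statistic is
#' computed. The level with the highest statistic is the optimal cutpoint
#' (minimum-p dichotomization); its naive chi-square p-value is biased by
#' the selection and must be corrected with [permutation_test()].
#'
#' Levels whose split leaves either group with fewer than `min_group`
#' patients (or with an otherwise degenerate log-rank) are skipped. Ties
#' among maximal statistics resolve to the smallest quantile level.
#'
#' @param cohort A [survival_cohort()].
#' @param q_lo,q_hi,q_step Quantile grid (defaults 0.10, 0.90, 0.01).
#' @param min_group Minimum group size for an admissible split (default 2).
#'
#' @return Object of class `cutpoint_scan`: `table` (data.frame with
#'   `level`, `threshold`, `statistic`, `skipped`), `best_level`,
#'   `best_threshold`, `best_statistic`, `naive_p` (uncorrected
#'   chi-square(1) p of the best statistic), and the grid parameters.
#' @export
scan_cutpoints <- function(cohort, q_lo = 0.10, q_hi = 0.90, q_step = 0.01,
                           min_group = 2) {
  stopifnot(inherits(cohort, "survival_cohort"))
  n <- length(cohort$time)
  if (sum(cohort$event) < 1) stop("cohort has no events")
  if (n < 2 * min_group) stop("cohort smaller than 2 * min_group")
  levels <- seq(q_lo, q_hi, by = q_step)
  # linear interpolation between order statistics (quantile type 7)
  thresholds <- unname(stats::quantile(cohort$expr, probs = levels, type = 7))
  stats_ <- logrank_scan_cpp(cohort$time, cohort$event, cohort$expr,
                             thresholds, as.integer(min_group))
  skipped <- is.na(stats_)
  if (all(skipped)) stop("no admissible cutpoint")
  best_idx <- which.max(ifelse(skipped, -Inf, stats_))  # earliest level on ties
  best_statistic <- stats_[best_idx]
  structure(
    list(
      table = data.frame(level = levels, threshold = thresholds,
                         statistic = stats_, skipped = skipped),
      best_level = levels[best_idx],
      best_threshold = thresholds[best_idx],
      best_statistic = best_statistic,
      naive_p = stats::pchisq(best_statistic, df = 1, lower.tail = FALSE),
      q_lo = q_lo, q_hi = q_hi, q_step = q_step, min_group = min_group
    ),
    class = "cutpoint_scan"
  )
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf(
    "cutpoint_scan: %d levels (%d skipped)\n  best: level %.2f, threshold %.4g, log-rank chi-square %.3f (naive p %.3g)\n",
    nrow(x$table), sum(x$table$skipped), x$best_level, x$best_threshold,
    x$best_statistic, x$naive_p))
  cat("  naive p is biased by cutoff selection; use permutation_test()\n")
  invisible(x)
}

#' Permutation test for the optimal cutpoint
#'
#' Corrects the selection bias of the cutpoint scan: under the null that
#' no expression threshold separates survival, the (time, event) pairs are
#' jointly shuffled against the fixed expression vector and the full scan
#' -- including re-optimization of the cutoff -- is repeated `n_perm`
#' times. The p-value is the fraction of permutation maxima exceeding the
#' observed maximal statistic.
#'
#' @param cohort A [survival_cohort()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @param exceed_rule `"strict"` counts permutation statistics strictly
#'   greater than the observed one (fraction over `n_perm`; can be exactly
#'   0); `"add_one"` uses the conservative `(1 + #{null >= obs}) /
#'   (n_perm + 1)` estimator. Both are always reported.
#' @param q_lo,q_hi,q_step,min_group Scan parameters, as [scan_cutpoints()].
#'
#' @return Object of class `permutation_result`: `observed` (best
#'   statistic of the unpermuted scan), `null_stats`, `p_value` (under
#'   `exceed_rule`), `p_strict`, `p_add_one`, `n_permutations`,
#'   `n_failed_scans` (permutations with no admissible cutoff, scored 0),
#'   `exceed_rule`, `seed`, and the underlying `scan`.
#' @export
permutation_test <- function(cohort, n_perm = 10000, seed = NULL,
                             exceed_rule = c("strict", "add_one"),
                             q_lo = 0.10, q_hi = 0.90, q_step = 0.01,
                             min_group = 2) {
  stopifnot(inherits(cohort, "survival_cohort"))
  exceed_rule <- match.arg(exceed_rule)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
        seed != round(seed))
      stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
  if (n_perm < 100) warning("fewer than 100 permutations: p-value is coarse")
  scan <- scan_cutpoints(cohort, q_lo = q_lo, q_hi = q_hi, q_step = q_step,
                         min_group = min_group)
  thresholds <- scan$table$threshold
  res <- perm_scan_cpp(cohort$time, cohort$event, cohort$expr,
                       thresholds, as.integer(n_perm), as.integer(min_group))
  null_stats <- res$max_stats
  if (res$n_failed > 0)
    message(res$n_failed, " permutation scan(s) had no admissible cutpoint; scored 0")
  p_strict <- mean(null_stats > scan$best_statistic)
  p_add_one <- (1 + sum(null_stats >= scan$best_statistic)) / (n_perm + 1)
  structure(
    list(observed = scan$best_statistic, null_stats = null_stats,
         n_permutations = as.integer(n_perm),
         p_value = if (exceed_rule == "strict") p_strict else p_add_one,
         p_strict = p_strict, p_add_one = p_add_one,
         n_failed_scans = res$n_failed,
         exceed_rule = exceed_rule, seed = seed, scan = scan),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed max log-rank %.3f\n", x$observed))
  cat(sprintf("  p = %.4g (%s rule; strict %.4g, add-one %.4g; N = %d, seed %s)\n",
              x$p_value, x$exceed_rule, x$p_strict, x$p_add_one,
              x$n_permutations, ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}
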