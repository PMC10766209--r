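#' Construct a survival cohort
#'
#' A right-censored survival cohort with one continuous covariate, the
#' log2-transformed expression of a single gene or isoform. All
#' cutpoint-scan, permutation and Cox operations consume this object.
#'
#' @param time Positive follow-up times (one consistent unit, e.g. months).
#' @param event Event indicators: 1 = event observed, 0 = right-censored.
#' @param expr Log2-scale expression values, one per patient.
#' @param patient_ids Optional unique patient identifiers.
#'
#' @return Object of class `survival_cohort`.
#' @export
survival_cohort <- function(time, event, expr, patient_ids = NULL) {
  n <- length(time)
  if (n < 2) stop("cohort must contain at least 2 patients")
  if (length(event) != n || length(expr) != n)
    stop("time, event and expr must have equal length")
  time <- as.numeric(time)
  event <- as.integer(event)
  expr <- as.numeric(expr)
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (event)")
  if (any(!is.finite(expr))) stop("expr must be finite")
  if (is.null(patient_ids)) patient_ids <- paste0("pt_", seq_len(n))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != n || anyDuplicated(patient_ids))
    stop("patient_ids must be unique and match cohort size")
  structure(
    list(patient_ids = patient_ids, time = time, event = event, expr = expr),
    class = "survival_cohort"
  )
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d patients, %d events (%.0f%% censored)\n",
              length(x$time), sum(x$event), 100 * mean(x$event == 0)))
  cat(sprintf("  expr (log2): median %.2f, range [%.2f, %.2f]\n",
              stats::median(x$expr), min(x$expr), max(x$expr)))
  invisible(x)
}

#' @export
length.survival_cohort <- function(x) length(x$time)

#' Dichotomize a cohort at an expression threshold
#'
#' Patients with expression strictly greater than the threshold form the
#' "high" group; ties at the threshold fall into the "low" group.
#'
#' @param cohort A [survival_cohort()].
#' @param threshold Finite expression level on the cohort's log2 scale.
#'
#' @return List with `labels` (factor low/high per patient), `n_low`,
#'   `n_high`, and the `threshold` used.
#' @export
stratify <- function(cohort, threshold) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  high <- cohort$expr > threshold
  labels <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  list(labels = labels, n_low = sum(!high), n_high = sum(high),
       threshold = threshold)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param cohort A [survival_cohort()].
#' @param subset Optional logical or integer index selecting patients.
#'
#' @return Object of class `km_curve`: `event_times` (strictly increasing),
#'   `survival` (product-limit estimate at each event time), `at_risk`
#'   (risk-set size just before each event time) and `n`. A subset with no
#'   events yields the flat curve (no event times).
#' @export
km_estimate <- function(cohort, subset = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"))
  time <- cohort$time
  event <- cohort$event
  if (!is.null(subset)) {
    time <- time[subset]
    event <- event[subset]
  }
  if (length(time) == 0) stop("subset is empty")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- unique(time[event == 1])
  if (length(ev_times) == 0) {
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n = length(time)),
                     class = "km_curve"))
  }
  n_at_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
  d <- vapply(ev_times, function(t) sum(time == t & event == 1), integer(1))
  surv <- cumprod(1 - d / n_at_risk)
  structure(list(event_times = ev_times, survival = surv,
                 at_risk = n_at_risk, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event times\n", x$n, length(x$event_times)))
  if (length(x$event_times))
    print(data.frame(time = x$event_times, at_risk = x$at_risk,
                     survival = round(x$survival, 4)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic: at each distinct event time the
#' observed number of events in one group is compared with its
#' hypergeometric expectation given the risk sets, with the multi-death
#' hypergeometric variance handling ties; the chi-square statistic is
#' `(sum(O - E))^2 / sum(V)` on 1 degree of freedom.
#'
#' @param cohort A [survival_cohort()].
#' @param group Two-level grouping (logical, factor, or 0/1) per patient.
#'
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_statistic <- function(cohort, group) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.integer(as.logical(group) | group > 0)
  if (length(group) != length(cohort$time))
    stop("group length must match cohort size")
  if (all(group == 1L) || all(group == 0L)) stop("both groups must be non-empty")
  if (sum(cohort$event) == 0) stop("no events")
  stat <- logrank_cpp(cohort$time, cohort$event, group)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
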