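#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values (TMM) scaling factors (Robinson &
#' Oshlack 2010) for a raw count matrix. For each sample against a
#' reference sample, per-gene log-ratios M (library-size-scaled) and
#' average log abundances A are formed over genes expressed in both; the
#' most extreme `trim_m` of the M-values and `trim_a` of the A-values are
#' discarded on each side, and the factor is 2 raised to the
#' inverse-variance-weighted mean of the retained M-values. Factors are
#' centred so their geometric mean is 1.
#'
#' The binomial inverse-variance weights are, by default, evaluated at a
#' standardized common sequencing depth (`weight_variance =
#' "standardized"`), which makes each factor depend on the samples'
#' count proportions only -- multiplying one sample's counts by any
#' constant leaves every factor unchanged. With `weight_variance =
#' "observed"` the variances are evaluated at the observed library
#' sizes, reproducing the edgeR reference implementation exactly; the
#' two coincide whenever library sizes are equal, and differ only
#' through the relative gene weights otherwise.
#'
#' @param cm A [count_matrix()].
#' @param trim_m Fraction of M-values trimmed on each side (default 0.30).
#' @param trim_a Fraction of A-values trimmed on each side (default 0.05).
#' @param reference Sample id to normalize against, or `"auto"` to pick the
#'   sample whose upper-quartile count fraction is closest to the mean of
#'   those fractions.
#' @param weight_variance `"standardized"` (default) or `"observed"`; see
#'   Details.
#'
#' @return An object of class `norm_factors`: a list with `sample_ids`,
#'   `factors` (geometric mean 1), `reference_sample`, `trim_m`, `trim_a`.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, reference = "auto",
                        weight_variance = c("standardized", "observed")) {
  stopifnot(inherits(cm, "count_matrix"))
  weight_variance <- match.arg(weight_variance)
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stop("trim fractions must lie in [0, 0.5)")
  counts <- cm$counts
  n_samp <- ncol(counts)
  if (n_samp < 2) stop("need >=2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have positive library size")

  if (identical(reference, "auto")) {
    f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_idx <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_idx <- match(reference, cm$sample_ids)
    if (is.na(ref_idx)) stop("reference sample '", reference, "' not found")
  }

  yr <- counts[, ref_idx]
  nr <- lib[ref_idx]
  factors <- vapply(seq_len(n_samp), function(k) {
    if (k == ref_idx) return(1)
    .tmm_pair_factor(counts[, k], lib[k], yr, nr, trim_m, trim_a,
                     weight_variance, sample_id = cm$sample_ids[k])
  }, numeric(1))

  # centre to geometric mean 1
  factors <- factors / exp(mean(log(factors)))
  structure(
    list(sample_ids = cm$sample_ids, factors = stats::setNames(factors, cm$sample_ids),
         reference_sample = cm$sample_ids[ref_idx],
         trim_m = trim_m, trim_a = trim_a),
    class = "norm_factors"
  )
}

# One pairwise TMM factor: sample (yk, nk) against reference (yr, nr).
# Genes with a zero count in either member are excluded pairwise; no
# pseudocounts are added.
.tmm_pair_factor <- function(yk, nk, yr, nr, trim_m, trim_a,
                             weight_variance = "standardized",
                             sample_id = "?") {
  keep <- yk > 0 & yr > 0
  if (!any(keep))
    stop("sample '", sample_id, "' shares no co-expressed genes with the reference")
  yk <- yk[keep]; yr <- yr[keep]
  m <- log2((yk / nk) / (yr / nr))
  a <- (log2(yk / nk) + log2(yr / nr)) / 2
  # degenerate case: samples already proportional
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  kept <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(kept)) return(1)
  # binomial delta-method variance of M per gene; weights are its inverse.
  # "standardized" evaluates the variance at a common depth so the weights
  # (and hence the factor) depend only on count proportions
  w <- if (weight_variance == "standardized") {
    pk <- yk / nk
    pr <- yr / nr
    1 / ((1 - pk) / pk + (1 - pr) / pr)
  } else {
    1 / ((nk - yk) / nk / yk + (nr - yr) / nr / yr)
  }
  2^(sum(w[kept] * m[kept]) / sum(w[kept]))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("TMM normalization factors (reference: %s, trim M %.2f / A %.2f)\n",
              x$reference_sample, x$trim_m, x$trim_a))
  print(round(x$factors, 4))
  invisible(x)
}

#' log2(FPKM + 1) expression matrix
#'
#' Converts raw counts to TMM-normalized FPKM and applies the
#' log2(FPKM + 1) transformation. FPKM for gene g in sample s is
#' `count / (length_kb * effective_library_size_millions)`, where the
#' effective library size is the raw library size times the sample's TMM
#' factor.
#'
#' @param cm A [count_matrix()].
#' @param nf A `norm_factors` object from [tmm_factors()] covering all
#'   samples of `cm`.
#' @param log2_transform If `FALSE`, return raw FPKM instead.
#'
#' @return An object of class `expression_matrix`: list with `values`
#'   (genes x samples), `gene_ids`, `sample_ids` and `scale_tag`
#'   (`"log2_fpkm_plus1"` or `"raw_fpkm"`).
#' @export
fpkm_log2 <- function(cm, nf, log2_transform = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(nf, "norm_factors"))
  if (!all(cm$sample_ids %in% nf$sample_ids))
    stop("normalization factors do not cover all samples")
  f <- nf$factors[cm$sample_ids]
  lib <- colSums(cm$counts)
  eff_millions <- lib * f / 1e6
  if (any(eff_millions <= 0)) stop("zero effective library size")
  len_kb <- cm$gene_lengths_bp / 1000
  fpkm <- sweep(cm$counts, 2, eff_millions, "/") / len_kb
  values <- if (log2_transform) log2(fpkm + 1) else fpkm
  structure(
    list(values = values, gene_ids = cm$gene_ids, sample_ids = cm$sample_ids,
         scale_tag = if (log2_transform) "log2_fpkm_plus1" else "raw_fpkm"),
    class = "expression_matrix"
  )
}

#' Low-expression gene filter
#'
#' Flags genes with enough reads to be distinguishable from background
#' noise, in the style of the filtering convention used with TMM-normalized
#' count data: a gene is kept iff it reaches a library-size-rescaled
#' minimum count in at least `n_min` samples and a minimum total count
#' across all samples. `n_min` is the smallest group size when
#' `group_labels` are present, otherwise half the sample count (rounded
#' up).
#'
#' @param cm A [count_matrix()].
#' @param min_count Minimum per-sample count at the median library size
#'   (default 10); rescaled per sample by library size.
#' @param min_total Minimum summed count across samples (default 15).
#'
#' @return Logical vector (one per gene): `TRUE` = keep.
#' @export
filter_low_expression <- function(cm, min_count = 10, min_total = 15) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  n_min <- if (!is.null(cm$group_labels)) {
    min(table(cm$group_labels))
  } else {
    ceiling(ncol(cm$counts) * 0.5)
  }
  # express the count threshold as a CPM cutoff at the median library size,
  # so deeper libraries need proportionally more reads
  cpm_cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- sweep(cm$counts, 2, lib / 1e6, "/")
  keep <- rowSums(cpm >= cpm_cutoff) >= n_min & rowSums(cm$counts) >= min_total
  if (!any(keep)) warning("no genes pass the low-expression filter")
  stats::setNames(keep, cm$gene_ids)
}

#' Isoform expression ratio
#'
#' Ratio of two isoforms' expression on the linear FPKM scale. Linear
#' values are recovered from a log2(FPKM+1) matrix as `2^value - 1`. The
#' cohort summary is (by default) the ratio of cohort means; per-sample
#' ratios are reported where the denominator is positive.
#'
#' @param em An `expression_matrix` from [fpkm_log2()].
#' @param iso_num,iso_den Gene/isoform ids of numerator and denominator.
#' @param summary One of `"mean_ratio"` (ratio of cohort means, default),
#'   `"median_ratio"` (ratio of cohort medians), `"mean_of_ratios"` (mean
#'   of per-sample ratios).
#'
#' @return List with `ratio` (cohort summary), `per_sample` (named vector,
#'   NA where the denominator is 0), `summary` (the rule used).
#' @export
isoform_ratio <- function(em, iso_num, iso_den,
                          summary = c("mean_ratio", "median_ratio", "mean_of_ratios")) {
  stopifnot(inherits(em, "expression_matrix"))
  summary <- match.arg(summary)
  i_num <- match(iso_num, em$gene_ids)
  i_den <- match(iso_den, em$gene_ids)
  if (is.na(i_num)) stop("gene id '", iso_num, "' not found")
  if (is.na(i_den)) stop("gene id '", iso_den, "' not found")
  to_linear <- function(v) {
    if (identical(em$scale_tag, "log2_fpkm_plus1")) 2^v - 1 else v
  }
  num <- to_linear(em$values[i_num, ])
  den <- to_linear(em$values[i_den, ])
  if (mean(den) <= 0) stop("ratio undefined: denominator mean is 0")
  per_sample <- ifelse(den > 0, num / den, NA_real_)
  names(per_sample) <- em$sample_ids
  ratio <- switch(summary,
    mean_ratio = mean(num) / mean(den),
    median_ratio = stats::median(num) / stats::median(den),
    mean_of_ratios = mean(per_sample, na.rm = TRUE)
  )
  list(ratio = ratio, per_sample = per_sample, summary = summary)
}
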