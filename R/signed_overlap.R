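#' Build a signed gene set from a differential-expression table
#'
#' Selects differentially expressed genes by the standard thresholds
#' (FDR below `fdr_max` and absolute fold change at least `fc_min`, i.e.
#' `|log2 fold change| >= log2(fc_min)`) and records each gene's direction
#' of change as a sign (+1 up, -1 down).
#'
#' @param det Data frame with columns `gene_id`, `log2_fc`, and `fdr`
#'   (adjusted p-value; recompute from raw p-values with [bh_adjust()] if
#'   needed).
#' @param fc_min Minimum absolute linear fold change (default 1.5).
#' @param fdr_max FDR threshold (default 0.05; strict `<`).
#' @param universe_size Number of genes in the universe the set is drawn
#'   from (e.g. all protein-coding genes in scope); defaults to the number
#'   of rows of `det`.
#'
#' @return Object of class `signed_gene_set`: `universe_size` and
#'   `members`, a named vector of signs (+1/-1) keyed by gene id. Genes
#'   passing the FDR filter with a log2 fold change of exactly 0 carry no
#'   direction and are excluded (with a message).
#' @export
make_signed_set <- function(det, fc_min = 1.5, fdr_max = 0.05,
                            universe_size = nrow(det)) {
  stopifnot(is.data.frame(det),
            all(c("gene_id", "log2_fc", "fdr") %in% names(det)))
  if (fc_min <= 1) stop("fc_min must be > 1")
  if (anyDuplicated(det$gene_id)) stop("gene ids must be unique")
  if (universe_size < nrow(det))
    stop("universe_size must be at least the number of genes in the table")
  pass_fdr <- det$fdr < fdr_max
  pass_fc <- abs(det$log2_fc) >= log2(fc_min)
  zero_dir <- pass_fdr & det$log2_fc == 0
  if (any(zero_dir))
    message(sum(zero_dir), " gene(s) passed filters with log2 FC exactly 0; ",
            "excluded (no direction)")
  sel <- pass_fdr & pass_fc & det$log2_fc != 0
  members <- stats::setNames(ifelse(det$log2_fc[sel] > 0, 1L, -1L),
                             det$gene_id[sel])
  signed_gene_set(members, universe_size)
}

#' Construct a signed gene set directly
#'
#' @param members Named integer vector of signs in {-1, +1}, keyed by
#'   gene id.
#' @param universe_size Total genes in the sampling universe.
#' @return Object of class `signed_gene_set`.
#' @export
signed_gene_set <- function(members, universe_size) {
  members <- stats::setNames(as.integer(members), names(members))
  if (length(members) && (is.null(names(members)) || anyDuplicated(names(members))))
    stop("members must be uniquely named by gene id")
  if (!all(members %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (universe_size < length(members))
    stop("universe_size smaller than the set")
  structure(list(universe_size = as.integer(universe_size), members = members),
            class = "signed_gene_set")
}

#' @export
print.signed_gene_set <- function(x, ...) {
  cat(sprintf("signed_gene_set: %d genes (%d up, %d down) in universe of %d\n",
              length(x$members), sum(x$members > 0), sum(x$members < 0),
              x$universe_size))
  invisible(x)
}

#' @export
length.signed_gene_set <- function(x) length(x$members)

#' Directional overlap counts of two signed gene sets
#'
#' @param a,b [signed_gene_set()]s over the same universe.
#' @return List with `n_shared` (genes in both sets), `n_concordant`
#'   (shared with equal sign) and `n_discordant` (shared with opposite
#'   sign).
#' @export
concordant_overlap <- function(a, b) {
  stopifnot(inherits(a, "signed_gene_set"), inherits(b, "signed_gene_set"))
  if (a$universe_size != b$universe_size)
    stop("sets must share the same universe size")
  shared <- intersect(names(a$members), names(b$members))
  n_conc <- sum(a$members[shared] == b$members[shared])
  list(n_shared = length(shared), n_concordant = n_conc,
       n_discordant = length(shared) - n_conc)
}

#' Monte-Carlo test for directional gene-set overlap
#'
#' Assesses whether the overlap of two signed gene sets exceeds chance.
#' Each iteration draws two uniform random subsets of the universe with
#' the observed cardinalities (without replacement within each set),
#' assigns every drawn gene an independent fair-coin sign, and computes
#' the overlap statistic. The p-value is the fraction of iterations whose
#' statistic strictly exceeds the observed one (or the add-one variant).
#' All three statistics (concordant, discordant, total shared) are
#' accumulated per iteration and reported.
#'
#' In `"shared"` mode the null is exactly hypergeometric, so the result
#' converges to [hypergeom_overlap_test()].
#'
#' @param a,b [signed_gene_set()]s over the same universe.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param statistic_mode Which statistic the p-value refers to:
#'   `"concordant"` (default; same gene, same direction), `"discordant"`
#'   (same gene, opposite direction) or `"shared"` (ignore signs).
#' @param seed Integer seed.
#' @param exceed_rule `"strict"` or `"add_one"`, as [permutation_test()].
#'
#' @return Object of class `overlap_result`: observed counts, the mode,
#'   `observed_statistic`, `p_value`, p-values under both rules and for
#'   all three modes (`p_table`), the per-iteration null statistics
#'   (`nulls`), `n_iterations`, `seed`.
#' @export
mc_overlap_test <- function(a, b, n_iter = 10000,
                            statistic_mode = c("concordant", "discordant", "shared"),
                            seed = NULL, exceed_rule = c("strict", "add_one")) {
  stopifnot(inherits(a, "signed_gene_set"), inherits(b, "signed_gene_set"))
  statistic_mode <- match.arg(statistic_mode)
  exceed_rule <- match.arg(exceed_rule)
  if (a$universe_size != b$universe_size)
    stop("sets must share the same universe size")
  G <- a$universe_size
  n_a <- length(a$members)
  n_b <- length(b$members)
  if (n_a > G || n_b > G) stop("set larger than universe")
  obs <- concordant_overlap(a, b)
  observed <- switch(statistic_mode,
                     concordant = obs$n_concordant,
                     discordant = obs$n_discordant,
                     shared = obs$n_shared)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
      stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
  null_conc <- integer(n_iter)
  null_disc <- integer(n_iter)
  null_shared <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    ga <- sample.int(G, n_a)
    gb <- sample.int(G, n_b)
    sa <- sample(c(-1L, 1L), n_a, replace = TRUE)
    sb <- sample(c(-1L, 1L), n_b, replace = TRUE)
    idx <- match(gb, ga)
    hit <- !is.na(idx)
    s <- sum(hit)
    null_shared[i] <- s
    null_conc[i] <- sum(sa[idx[hit]] == sb[hit])
    null_disc[i] <- s - null_conc[i]
  }
  nulls <- list(concordant = null_conc, discordant = null_disc,
                shared = null_shared)
  obs_by_mode <- c(concordant = obs$n_concordant, discordant = obs$n_discordant,
                   shared = obs$n_shared)
  p_table <- do.call(rbind, lapply(names(nulls), function(m) {
    data.frame(mode = m, observed = obs_by_mode[[m]],
               p_strict = mean(nulls[[m]] > obs_by_mode[[m]]),
               p_add_one = (1 + sum(nulls[[m]] >= obs_by_mode[[m]])) / (n_iter + 1))
  }))
  row <- p_table[p_table$mode == statistic_mode, ]
  structure(
    list(n_shared = obs$n_shared, n_concordant = obs$n_concordant,
         n_discordant = obs$n_discordant,
         statistic_mode = statistic_mode, observed_statistic = observed,
         p_value = if (exceed_rule == "strict") row$p_strict else row$p_add_one,
         p_table = p_table, nulls = nulls, exceed_rule = exceed_rule,
         n_iterations = as.integer(n_iter), seed = seed,
         universe_size = G, n_a = n_a, n_b = n_b),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: shared %d (concordant %d, discordant %d) of |a|=%d, |b|=%d, G=%d\n",
    x$n_shared, x$n_concordant, x$n_discordant, x$n_a, x$n_b, x$universe_size))
  cat(sprintf("  %s-mode p = %.4g (%s rule, N = %d)\n", x$statistic_mode,
              x$p_value, x$exceed_rule, x$n_iterations))
  invisible(x)
}

#' Hypergeometric upper-tail overlap test
#'
#' Probability of observing at least `k_observed` shared genes when two
#' unsigned sets of sizes `n_a` and `n_b` are drawn uniformly from a
#' universe of `G` genes.
#'
#' @param n_a,n_b Set sizes.
#' @param G Universe size.
#' @param k_observed Observed intersection cardinality.
#' @return Upper-tail p-value `P(K >= k_observed)`.
#' @export
hypergeom_overlap_test <- function(n_a, n_b, G, k_observed) {
  if (n_a > G || n_b > G) stop("set size exceeds universe")
  if (k_observed < 0 || k_observed > min(n_a, n_b))
    stop("infeasible overlap count")
  if (k_observed == 0) return(1)
  stats::phyper(k_observed - 1, m = n_a, n = G - n_a, k = n_b,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment; a thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values))) stop("p-values must not contain NA/NaN")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman concordance of two fold-change vectors
#'
#' Spearman rank correlation (average ranks for ties) with the t-
#' approximation p-value, plus the significance call used for fold-change
#' concordance screens: absolute correlation above 0.3 with FDR below
#' 0.05.
#'
#' @param fc_a,fc_b Paired numeric vectors (n >= 4).
#' @param fdr Optional externally adjusted p-value to use for the
#'   significance call; defaults to the raw p (adjust across multiple
#'   tests with [bh_adjust()]).
#' @return List with `rho`, `p_value`, `n`, and `significant`
#'   (`|rho| > 0.3` and FDR < 0.05).
#' @export
spearman_fc_concordance <- function(fc_a, fc_b, fdr = NULL) {
  if (length(fc_a) != length(fc_b)) stop("vectors must be paired")
  n <- length(fc_a)
  if (n < 4) stop("need at least 4 pairs")
  if (stats::sd(fc_a) == 0 || stats::sd(fc_b) == 0)
    stop("rank-degenerate input: constant vector")
  ra <- rank(fc_a); rb <- rank(fc_b)
  rho <- stats::cor(ra, rb)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (is.null(fdr)) fdr <- p
  list(rho = rho, p_value = p, n = n,
       significant = abs(rho) > 0.3 && fdr < 0.05)
}
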