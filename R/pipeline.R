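#' Run the full expression-survival analysis pipeline
#'
#' Orchestrates the stages end to end: optional TMM/log2(FPKM+1)
#' normalization of raw counts, the optimal-cutpoint scan with
#' permutation inference and univariate Cox regression for one gene,
#' optionally the two-variable universal-threshold search, and optionally
#' the signed Monte-Carlo overlap test of two DE tables. Writes a JSON
#' report plus TSV artifacts to the output directory. Re-running with an
#' identical configuration and seeds reproduces the outputs bit-
#' identically (except the `wall_time_s` / `timestamp` fields).
#'
#' @param config A named list or a path to a YAML file with entries:
#' \describe{
#'   \item{counts, lengths, groups}{optional paths for the normalization
#'     stage; when present the survival expression is taken from the
#'     normalized matrix.}
#'   \item{survival}{path to the survival table (required for the
#'     survival stage).}
#'   \item{expression}{path to an expression table (long or wide) when no
#'     counts are given.}
#'   \item{gene, gene_b}{gene/isoform id(s); `gene_b` triggers the
#'     universal-threshold stage.}
#'   \item{de_a, de_b, universe_size, flip_b}{DE table paths and universe
#'     for the overlap stage; `flip_b` negates table B's fold changes to
#'     orient both tables to the same contrast direction.}
#'   \item{q_lo, q_hi, q_step, min_group, n_permutations, n_iterations,
#'     exceed_rule, statistic_mode, fc_min, fdr_max, seed}{analysis
#'     parameters, all optional with the package defaults.}
#'   \item{out_dir}{output directory (required).}
#' }
#'
#' @return The report (list of class `run_report`), invisibly also
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- .fill_defaults(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  for (f in c("counts", "lengths", "groups", "survival", "expression",
              "de_a", "de_b")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file for '", f, "' does not exist: ", cfg[[f]])
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  report <- list(package_version = as.character(utils::packageVersion("survscan")),
                 config = cfg, stages = list())

  expr_source <- NULL
  if (!is.null(cfg$counts)) {
    cm <- read_counts(cfg$counts, cfg$lengths, cfg$groups)
    keep <- filter_low_expression(cm, min_count = cfg$min_count,
                                  min_total = cfg$min_total)
    cm_f <- count_matrix(cm$counts[keep, , drop = FALSE],
                         cm$gene_lengths_bp[keep],
                         gene_ids = cm$gene_ids[keep],
                         group_labels = cm$group_labels)
    nf <- tmm_factors(cm_f, trim_m = cfg$trim_m, trim_a = cfg$trim_a)
    em <- fpkm_log2(cm_f, nf)
    write_expression_matrix(em, nf, file.path(cfg$out_dir, "expression.tsv"))
    write_norm_factors(nf, file.path(cfg$out_dir, "tmm_factors.tsv"))
    expr_source <- em
    report$stages$normalization <- list(
      n_genes_in = length(cm$gene_ids), n_genes_kept = sum(keep),
      reference_sample = nf$reference_sample,
      factors = as.list(round(nf$factors, 6)),
      trim_m = nf$trim_m, trim_a = nf$trim_a, scale_tag = em$scale_tag)
    .stage_log("normalization", kept = sum(keep),
               reference = nf$reference_sample)
  }

  if (!is.null(cfg$survival)) {
    if (is.null(cfg$gene)) stop("survival stage requires a 'gene' id")
    surv <- read_survival(cfg$survival)
    cohort <- .pipeline_cohort(cfg, surv, expr_source, cfg$gene)
    perm <- permutation_test(cohort, n_perm = cfg$n_permutations,
                             seed = cfg$seed, exceed_rule = cfg$exceed_rule,
                             q_lo = cfg$q_lo, q_hi = cfg$q_hi,
                             q_step = cfg$q_step, min_group = cfg$min_group)
    scan <- perm$scan
    cox <- cox_univariate(cohort)
    strat <- stratify(cohort, scan$best_threshold)
    km_low <- km_estimate(cohort, strat$labels == "low")
    km_high <- km_estimate(cohort, strat$labels == "high")
    utils::write.table(scan$table, file.path(cfg$out_dir, "cutpoint_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$survival <- list(
      gene = cfg$gene, n_patients = length(cohort), n_events = sum(cohort$event),
      best_level = scan$best_level, best_threshold = scan$best_threshold,
      best_statistic = scan$best_statistic, naive_p = scan$naive_p,
      permutation = list(p_strict = perm$p_strict, p_add_one = perm$p_add_one,
                         exceed_rule = perm$exceed_rule,
                         n_permutations = perm$n_permutations,
                         n_failed_scans = perm$n_failed_scans,
                         seed = cfg$seed),
      cox = list(beta = cox$beta, se = cox$se, hr = cox$hr,
                 ci95 = as.list(cox$ci95), wald_p = cox$wald_p,
                 ties_method = cox$ties_method),
      groups = list(n_low = strat$n_low, n_high = strat$n_high),
      km_low = .km_as_list(km_low), km_high = .km_as_list(km_high))
    .stage_log("survival", gene = cfg$gene, best_level = scan$best_level,
               p_strict = perm$p_strict, hr = round(cox$hr, 3))

    if (!is.null(cfg$gene_b)) {
      cohort_b <- .pipeline_cohort(cfg, surv, expr_source, cfg$gene_b)
      ut <- universal_threshold(cohort, cohort_b, min_group = cfg$min_group,
                                n_perm = cfg$n_permutations, seed = cfg$seed,
                                exceed_rule = cfg$exceed_rule)
      report$stages$universal_threshold <- list(
        gene_a = cfg$gene, gene_b = cfg$gene_b, threshold = ut$threshold,
        avg_statistic = ut$avg_statistic,
        per_variable_p = as.list(ut$per_variable_p), avg_p = ut$avg_p,
        p_definition = "mean of per-variable re-optimizing permutation p-values on the shared fixed grid")
      .stage_log("universal_threshold", threshold = ut$threshold,
                 avg_p = ut$avg_p)
    }
  }

  if (!is.null(cfg$de_a) && !is.null(cfg$de_b)) {
    det_a <- read_de_table(cfg$de_a)
    det_b <- read_de_table(cfg$de_b)
    if (isTRUE(cfg$flip_b)) det_b$log2_fc <- -det_b$log2_fc
    universe <- cfg$universe_size
    if (is.null(universe))
      universe <- length(union(det_a$gene_id, det_b$gene_id))
    set_a <- make_signed_set(det_a, fc_min = cfg$fc_min, fdr_max = cfg$fdr_max,
                             universe_size = universe)
    set_b <- make_signed_set(det_b, fc_min = cfg$fc_min, fdr_max = cfg$fdr_max,
                             universe_size = universe)
    ov <- mc_overlap_test(set_a, set_b, n_iter = cfg$n_iterations,
                          statistic_mode = cfg$statistic_mode,
                          seed = cfg$seed, exceed_rule = cfg$exceed_rule)
    hyper_p <- hypergeom_overlap_test(length(set_a), length(set_b), universe,
                                      ov$n_shared)
    report$stages$overlap <- list(
      n_a = length(set_a), n_b = length(set_b), universe_size = universe,
      universe_rule = if (is.null(cfg$universe_size)) "union_of_tables" else "config",
      flip_b = isTRUE(cfg$flip_b),
      n_shared = ov$n_shared, n_concordant = ov$n_concordant,
      n_discordant = ov$n_discordant, statistic_mode = ov$statistic_mode,
      p_value = ov$p_value, p_table = ov$p_table,
      hypergeom_p = hyper_p, n_iterations = ov$n_iterations, seed = cfg$seed)
    .stage_log("overlap", shared = ov$n_shared, p = ov$p_value)
  }

  report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  invisible(report)
}

.fill_defaults <- function(config) {
  defaults <- list(q_lo = 0.10, q_hi = 0.90, q_step = 0.01, min_group = 2,
                   n_permutations = 10000, n_iterations = 10000,
                   exceed_rule = "strict", statistic_mode = "concordant",
                   fc_min = 1.5, fdr_max = 0.05, min_count = 10,
                   min_total = 15, trim_m = 0.30, trim_a = 0.05,
                   seed = 1L, flip_b = FALSE)
  utils::modifyList(defaults, config)
}

.pipeline_cohort <- function(cfg, surv, expr_source, gene) {
  expr <- if (!is.null(expr_source)) {
    row <- match(gene, expr_source$gene_ids)
    if (is.na(row)) stop("gene id '", gene, "' not found in normalized matrix")
    stats::setNames(expr_source$values[row, ], expr_source$sample_ids)
  } else {
    if (is.null(cfg$expression))
      stop("config must provide 'expression' or 'counts'")
    read_expression(cfg$expression, gene = gene)
  }
  cohort_from_tables(surv, expr)
}

.km_as_list <- function(km) {
  list(time = km$event_times, survival = km$survival, at_risk = km$at_risk,
       n = km$n)
}

.stage_log <- function(stage, ...) {
  kv <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(lapply(kv, format)), sep = "=",
                        collapse = " ")))
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (survscan", x$package_version, ")\n")
  for (s in names(x$stages)) cat("  stage:", s, "\n")
  cat("  wall time:", x$wall_time_s, "s\n")
  invisible(x)
}
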