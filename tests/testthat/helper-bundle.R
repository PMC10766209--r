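# Synthetic on-disk input bundles for pipeline-level tests.

# Writes survival + wide expression tables for a cohort with a step effect
# planted at the median of "iso3", plus a pair of DE tables whose signed
# sets overlap with a planted 25 concordant / 5 discordant composition.
write_bundle <- function(dir, n = 250, hr_high = 3, seed = 77) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(n = n, hr_high = hr_high, cut_quantile = 0.5,
                         seed = seed)
  co <- sim$cohort
  surv_file <- file.path(dir, "survival.tsv")
  write.table(data.frame(patient_id = co$patient_ids, time = co$time,
                         event = co$event),
              surv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  expr_file <- file.path(dir, "expression.tsv")
  # wide layout: two isoforms, the second a pure-noise variable
  set.seed(seed + 1)
  expr2 <- rnorm(n, 6, 1.5)
  mat <- rbind(iso3 = co$expr, iso4 = expr2)
  write.table(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
              expr_file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("gene_id", co$patient_ids))
  deg <- simulate_deg_pair(G = 800, n_a = 80, n_b = 80, n_concordant = 25,
                           n_discordant = 5, seed = seed + 2)
  de_files <- lapply(c(a = "set_a", b = "set_b"), function(s) {
    set <- deg[[s]]
    f <- file.path(dir, paste0("de_", s, ".tsv"))
    all_ids <- paste0("g", 1:800)
    in_set <- all_ids %in% names(set$members)
    lfc <- ifelse(in_set, set$members[all_ids] * 2, rnorm(800, 0, 0.1))
    padj <- ifelse(in_set, 0.001, runif(800, 0.2, 1))
    write.table(data.frame(gene = all_ids, log2fc = lfc, pvalue = padj / 2,
                           padj = padj),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  list(survival = surv_file, expression = expr_file,
       de_a = de_files$a, de_b = de_files$b, truth = sim$truth)
}

base_config <- function(bundle, out_dir, ...) {
  modifyList(list(survival = bundle$survival, expression = bundle$expression,
                  gene = "iso3", de_a = bundle$de_a, de_b = bundle$de_b,
                  universe_size = 800, n_permutations = 300,
                  n_iterations = 300, seed = 5, out_dir = out_dir),
             list(...))
}
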