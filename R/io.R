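# Delimited-text readers/writers for the pipeline's external formats.
# Separator is inferred from the file extension (.csv = comma, else tab).

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a raw count matrix with gene lengths
#'
#' @param counts_file TSV/CSV, first column gene id, remaining columns one
#'   per sample.
#' @param lengths_file TSV/CSV with columns gene id and length in bp.
#' @param groups_file Optional TSV/CSV with columns sample id and group.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_file, lengths_file, groups_file = NULL) {
  tab <- .read_delim_auto(counts_file)
  gene_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  mode(counts) <- "numeric"
  len <- .read_delim_auto(lengths_file)
  idx <- match(gene_ids, as.character(len[[1]]))
  if (any(is.na(idx)))
    stop("lengths missing for gene(s): ",
         paste(utils::head(gene_ids[is.na(idx)], 5), collapse = ", "))
  group_labels <- NULL
  if (!is.null(groups_file)) {
    grp <- .read_delim_auto(groups_file)
    gidx <- match(colnames(counts), as.character(grp[[1]]))
    if (any(is.na(gidx)))
      stop("group labels missing for sample(s): ",
           paste(colnames(counts)[is.na(gidx)], collapse = ", "))
    group_labels <- as.character(grp[[2]])[gidx]
  }
  count_matrix(counts, as.numeric(len[[2]])[idx], gene_ids = gene_ids,
               group_labels = group_labels)
}

#' Read a survival table
#'
#' @param file TSV/CSV with columns patient id, time, event (0/1), in that
#'   order or named `patient_id`/`time`/`event`.
#' @return Data frame with columns `patient_id`, `time`, `event`.
#' @export
read_survival <- function(file) {
  tab <- .read_delim_auto(file)
  cols <- c("patient_id", "time", "event")
  if (!all(cols %in% names(tab))) {
    if (ncol(tab) < 3) stop("survival table needs 3 columns: ", file)
    tab <- tab[, 1:3]
    names(tab) <- cols
  }
  tab$patient_id <- as.character(tab$patient_id)
  tab[, cols]
}

#' Read a per-sample expression table
#'
#' Accepts either a long table (columns sample id and value, one gene) or
#' a wide matrix (first column gene id, one column per sample) from which
#' the row of `gene` is extracted.
#'
#' @param file TSV/CSV path.
#' @param gene Gene/isoform id (wide layout only).
#' @return Named numeric vector of expression keyed by sample id.
#' @export
read_expression <- function(file, gene = NULL) {
  tab <- .read_delim_auto(file)
  # two columns = long layout (sample id, value), whatever `gene` says
  if (ncol(tab) == 2) {
    return(stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]])))
  }
  if (is.null(gene)) stop("wide expression table requires a gene id")
  ids <- as.character(tab[[1]])
  row <- match(gene, ids)
  if (is.na(row)) stop("gene id '", gene, "' not found in ", file)
  vals <- as.numeric(tab[row, -1])
  stats::setNames(vals, colnames(tab)[-1])
}

#' Read a differential-expression result table
#'
#' @param file TSV/CSV path.
#' @param cols Named character vector mapping the standard names
#'   (`gene_id`, `log2_fc`, `p_value`, `fdr`) to the file's column names.
#' @return Data frame with the standard columns.
#' @export
read_de_table <- function(file, cols = c(gene_id = "gene", log2_fc = "log2fc",
                                         p_value = "pvalue", fdr = "padj")) {
  tab <- .read_delim_auto(file)
  missing_cols <- setdiff(unname(cols), names(tab))
  if (length(missing_cols))
    stop("column(s) not found in ", file, ": ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(gene_id = as.character(tab[[cols[["gene_id"]]]]),
                    log2_fc = as.numeric(tab[[cols[["log2_fc"]]]]),
                    p_value = as.numeric(tab[[cols[["p_value"]]]]),
                    fdr = as.numeric(tab[[cols[["fdr"]]]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in ", file)
  out
}

#' Write a normalized expression matrix
#'
#' Writes a TSV with a leading comment line recording the scale and the
#' normalization settings, then gene id plus one column per sample.
#'
#' @param em An `expression_matrix` from [fpkm_log2()].
#' @param nf The `norm_factors` used.
#' @param file Output path.
#' @export
write_expression_matrix <- function(em, nf, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s trim_m=%g trim_a=%g reference=%s",
                     em$scale_tag, nf$trim_m, nf$trim_a, nf$reference_sample),
             con)
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write TMM factors as a two-column TSV
#' @param nf A `norm_factors` object.
#' @param file Output path.
#' @export
write_norm_factors <- function(nf, file) {
  utils::write.table(
    data.frame(sample_id = nf$sample_ids, factor = unname(nf$factors)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Build a survival cohort from survival and expression tables
#'
#' Joins a survival table to per-sample expression by patient id; any id
#' present on one side only is an error (all orphans are listed).
#'
#' @param surv Data frame from [read_survival()].
#' @param expr Named numeric vector keyed by patient/sample id.
#' @return A [survival_cohort()].
#' @export
cohort_from_tables <- function(surv, expr) {
  orphans_s <- setdiff(surv$patient_id, names(expr))
  orphans_e <- setdiff(names(expr), surv$patient_id)
  if (length(orphans_s) || length(orphans_e))
    stop("patient ids do not match between survival and expression tables; ",
         "orphaned: ",
         paste(c(orphans_s, orphans_e), collapse = ", "))
  survival_cohort(surv$time, surv$event, expr[surv$patient_id],
                  patient_ids = surv$patient_id)
}
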