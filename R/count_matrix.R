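#' Construct a count matrix object
#'
#' Bundles a genes-by-samples matrix of raw read counts with gene lengths
#' and optional per-sample group labels. This is the input container for
#' [tmm_factors()], [fpkm_log2()] and [filter_low_expression()].
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns. Dimnames are used as gene/sample ids when `gene_ids` or
#'   `sample_ids` are not given.
#' @param gene_lengths_bp Positive integer vector of transcript lengths in
#'   base pairs, one per gene.
#' @param gene_ids,sample_ids Optional character vectors of unique ids.
#' @param group_labels Optional per-sample categorical labels (used by
#'   [filter_low_expression()] to determine the smallest group size).
#'
#' @return An object of class `count_matrix` with fields `counts`,
#'   `gene_ids`, `sample_ids`, `gene_lengths_bp`, `group_labels`.
#' @export
count_matrix <- function(counts, gene_lengths_bp, gene_ids = rownames(counts),
                         sample_ids = colnames(counts), group_labels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match number of count rows")
  if (length(sample_ids) != ncol(counts))
    stop("sample_ids length does not match number of count columns")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  gene_lengths_bp <- as.numeric(gene_lengths_bp)
  if (length(gene_lengths_bp) != nrow(counts))
    stop("gene_lengths_bp length does not match number of genes")
  if (any(!is.finite(gene_lengths_bp)) || any(gene_lengths_bp <= 0))
    stop("gene_lengths_bp must be positive")
  if (!is.null(group_labels)) {
    if (length(group_labels) != ncol(counts))
      stop("group_labels length does not match number of samples")
    group_labels <- as.character(group_labels)
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids,
         gene_lengths_bp = gene_lengths_bp, group_labels = group_labels),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  library sizes: %s\n",
              paste(format(colSums(x$counts), big.mark = ","), collapse = ", ")))
  if (!is.null(x$group_labels))
    cat(sprintf("  groups: %s\n", paste(unique(x$group_labels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
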