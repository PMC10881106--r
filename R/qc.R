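# Sample QC by mapping statistics, TPM normalization, and aggregation of
# samples to analysis groups (region, developmental window, cell type).

#' Filter samples by mapping statistics
#'
#' Retains samples with strictly more than `min_unique_reads` uniquely
#' mapped reads AND a uniquely-mapped fraction strictly greater than
#' `min_unique_fraction` (both inequalities strict: a sample sitting exactly
#' on a threshold is removed).  The defaults are the usual bulk RNA-seq
#' gates of 10 million uniquely mapped reads and an 80% unique fraction.
#' The removed rows, with the criterion (or criteria) each one failed, are
#' attached as the `"qc_rejections"` attribute.  Filtering is idempotent.
#'
#' @param meta a [sample_metadata()] table; mapping-stat fields must be
#'   complete (missing values are an error, never a silent pass)
#' @param min_unique_reads minimum uniquely mapped reads (strict), default 1e7
#' @param min_unique_fraction minimum unique fraction (strict), default 0.8
#' @return the retained rows, with attribute `"qc_rejections"`: a data.frame
#'   `sample_id`, `fail_reads`, `fail_fraction`
#' @export
#' @examples
#' meta <- data.frame(sample_id = c("a", "b"), region = "R",
#'                    region_class = "cortical",
#'                    uniquely_mapped_reads = c(2e7, 1e7),
#'                    total_reads = c(2.2e7, 1.2e7))
#' qc_filter_samples(sample_metadata(meta))  # "b" removed: 1e7 is not > 1e7
qc_filter_samples <- function(meta, min_unique_reads = 1e7,
                              min_unique_fraction = 0.8) {
  meta <- sample_metadata(as.data.frame(meta))
  if (anyNA(meta$uniquely_mapped_reads) || anyNA(meta$total_reads)) {
    bad <- meta$sample_id[is.na(meta$uniquely_mapped_reads) |
                          is.na(meta$total_reads)]
    stop_evoindex("evoindex_validation",
                  "missing mapping statistics for sample(s): %s",
                  paste(head(bad, 10), collapse = ", "))
  }
  fail_reads <- !(meta$uniquely_mapped_reads > min_unique_reads)
  fail_fraction <- !(meta$uniquely_mapped_reads / meta$total_reads >
                     min_unique_fraction)
  drop <- fail_reads | fail_fraction
  rejections <- data.frame(sample_id = meta$sample_id[drop],
                           fail_reads = fail_reads[drop],
                           fail_fraction = fail_fraction[drop],
                           stringsAsFactors = FALSE, row.names = NULL)
  out <- meta[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_rejections") <- rejections
  out
}

#' Convert raw counts to TPM
#'
#' Per sample: `rate_i = count_i / length_i`;
#' `TPM_i = 1e6 * rate_i / sum_j rate_j`.  Columns with no counts at all are
#' left all-zero and flagged in the result's `"zero_columns"` attribute.
#'
#' @param counts an [expression_matrix()] with `units = "counts"`
#' @param gene_lengths named numeric vector of positive gene lengths in
#'   bases, covering every gene in `counts`
#' @return an [expression_matrix()] with `units = "TPM"`
#' @export
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' counts_to_tpm(expression_matrix(m, "counts"),
#'               c(g1 = 1000, g2 = 2000))  # 666666.7, 333333.3
counts_to_tpm <- function(counts, gene_lengths) {
  if (!inherits(counts, "expression_matrix")) {
    counts <- expression_matrix(counts, units = "counts")
  }
  if (expr_units(counts) != "counts") {
    invalid_parameter("counts_to_tpm expects units = 'counts', got '%s'",
                      expr_units(counts))
  }
  genes <- rownames(counts)
  missing_len <- setdiff(genes, names(gene_lengths))
  if (length(missing_len)) {
    stop_evoindex("evoindex_validation",
                  "no gene length for: %s",
                  paste(head(missing_len, 10), collapse = ", "))
  }
  len <- gene_lengths[genes]
  if (any(!is.finite(len) | len <= 0)) {
    stop_evoindex("evoindex_validation",
                  "gene lengths must be positive and finite")
  }
  rate <- unclass(counts) / len
  denom <- colSums(rate)
  tpm <- rate
  nz <- denom > 0
  tpm[, nz] <- sweep(rate[, nz, drop = FALSE], 2, denom[nz], "/") * 1e6
  tpm[, !nz] <- 0
  expression_matrix(tpm, units = "TPM")
}

#' Aggregate expression over sample groups
#'
#' Reduces a genes x samples matrix to genes x groups by taking, per gene,
#' the arithmetic mean (default) or median of the member samples.  Grouping
#' keys: `region`, `window`, `region_window`, `cell_type`,
#' `region_cell_type`; composite keys are joined with `"|"`.  Group columns
#' are ordered lexicographically, so output is invariant to sample order.
#'
#' @param expr an [expression_matrix()]
#' @param meta a [sample_metadata()] table covering every sample in `expr`
#' @param group_by grouping key (see above)
#' @param fun `"mean"` (default) or `"median"`
#' @return an [expression_matrix()] of genes x groups; counts input becomes
#'   `"normalized"`, other units are preserved
#' @export
aggregate_expression <- function(expr, meta,
                                 group_by = c("region", "window",
                                              "region_window", "cell_type",
                                              "region_cell_type"),
                                 fun = c("mean", "median")) {
  group_by <- match.arg(group_by)
  fun <- match.arg(fun)
  meta <- sample_metadata(as.data.frame(meta))
  missing_samples <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing_samples)) {
    stop_evoindex("evoindex_validation",
                  "samples absent from metadata: %s",
                  paste(head(missing_samples, 10), collapse = ", "))
  }
  m <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  key <- switch(group_by,
    region = m$region,
    window = m$window,
    region_window = paste(m$region, m$window, sep = GROUP_SEP),
    cell_type = m$cell_type,
    region_cell_type = paste(m$region, m$cell_type, sep = GROUP_SEP))
  if (anyNA(key) || any(!nzchar(key))) {
    stop_evoindex("evoindex_validation",
                  "grouping key '%s' undefined for some samples", group_by)
  }
  groups <- sort(unique(key))
  vals <- unclass(expr)
  out <- matrix(0, nrow(vals), length(groups),
                dimnames = list(rownames(vals), groups))
  if (fun == "mean") {
    agg <- rowsum(t(vals), key)                 # groups x genes, sums
    counts <- as.vector(table(key)[rownames(agg)])
    out[, rownames(agg)] <- t(agg / counts)
  } else {
    for (g in groups) {
      out[, g] <- apply(vals[, key == g, drop = FALSE], 1, median)
    }
  }
  units_out <- if (expr_units(expr) == "counts") "normalized" else expr_units(expr)
  expression_matrix(out, units = units_out)
}
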