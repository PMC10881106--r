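# Expression-weighted evolutionary indices.
#
# ERI (evolutionary rate index) of a group of samples and an ancestral
# lineage:   ERI = sum_i (dN/dS)_i * E_i / sum_i E_i
# TAI (transcriptome age index) of a group:
#            TAI = sum_i A_i * E_i / sum_i E_i
# where E_i is the (untransformed) expression of gene i in the group, and
# pairs with a missing value or zero weight are removed pairwise.  No
# expression cutoff is applied: every expressed gene contributes with its
# weight.

#' Expression-weighted mean of a per-gene quantity
#'
#' The primitive behind both indices: `sum(value_i * weight_i) /
#' sum(weight_i)` over the entries retained after pairwise removal of
#' missing values and zero or missing weights.  Scale-invariant in the
#' weights and always within the range of the retained values.
#'
#' @param values per-gene numeric values (dN/dS or ages; NAs allowed)
#' @param weights per-gene non-negative weights (expression)
#' @return list with `value` (the weighted mean) and `n_used` (entries
#'   retained)
#' @export
#' @examples
#' weighted_index(c(0.1, 0.5), c(1, 3))$value  # 0.4
weighted_index <- function(values, weights) {
  if (length(values) != length(weights)) {
    invalid_parameter("values and weights must have equal length (%d vs %d)",
                      length(values), length(weights))
  }
  if (any(weights < 0, na.rm = TRUE)) {
    invalid_parameter("weights must be non-negative")
  }
  keep <- !is.na(values) & !is.na(weights) & weights > 0
  sw <- sum(weights[keep])
  if (!any(keep) || sw <= 0 || !is.finite(sw)) {
    stop_evoindex("evoindex_undefined_index",
                  "undefined index: no retained gene carries positive weight")
  }
  list(value = sum(values[keep] * weights[keep]) / sw,
       n_used = sum(keep))
}

# shared engine for the two index tables
compute_index_table <- function(gene_evo, grouped_expr, kind) {
  genes <- intersect(gene_evo$gene_id, rownames(grouped_expr))
  if (!length(genes)) {
    stop_evoindex("evoindex_validation",
                  "no genes shared between the gene table and the expression matrix")
  }
  ge <- as.data.frame(gene_evo)[match(genes, gene_evo$gene_id), , drop = FALSE]
  ex <- unclass(grouped_expr)[genes, , drop = FALSE]
  groups <- colnames(ex)
  value_cols <- if (kind == "ERI") evo_lineages(gene_evo) else "age"
  rows <- vector("list", length(groups) * length(value_cols))
  k <- 0L
  for (vc in value_cols) {
    v <- ge[[vc]]
    for (g in groups) {
      k <- k + 1L
      wi <- tryCatch(weighted_index(v, ex[, g]), evoindex_undefined_index =
        function(e) {
          stop_evoindex("evoindex_undefined_index",
                        "undefined %s for group '%s'%s: %s", kind, g,
                        if (kind == "ERI") sprintf(", lineage '%s'", vc) else "",
                        conditionMessage(e))
        })
      rows[[k]] <- data.frame(group = g,
                              lineage = if (kind == "ERI") vc else NA_character_,
                              index_kind = kind, value = wi$value,
                              n_genes_used = wi$n_used,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  index_table(df$group, df$lineage, df$index_kind, df$value, df$n_genes_used)
}

#' Evolutionary rate index per group and lineage
#'
#' One ERI per (group x lineage): the expression-weighted mean of the
#' lineage's per-gene dN/dS.  Genes with missing dN/dS in a lineage are
#' excluded pairwise for that lineage only; no expression cutoff is applied.
#'
#' @param gene_evo a [gene_evo_table()]
#' @param grouped_expr an [expression_matrix()] of genes x groups, e.g. from
#'   [aggregate_expression()]
#' @return an [index_table()] with `index_kind = "ERI"`
#' @export
compute_eri_table <- function(gene_evo, grouped_expr) {
  compute_index_table(gene_evo, grouped_expr, "ERI")
}

#' Transcriptome age index per group
#'
#' The expression-weighted mean of per-gene evolutionary ages.  With age
#' measured as time before present, a low TAI indicates a transcriptome
#' enriched for evolutionarily young genes.
#'
#' @inheritParams compute_eri_table
#' @return an [index_table()] with `index_kind = "TAI"` (lineage empty)
#' @export
compute_tai_table <- function(gene_evo, grouped_expr) {
  compute_index_table(gene_evo, grouped_expr, "TAI")
}

#' Per-sample indices averaged within groups
#'
#' The alternative to aggregate-then-index: compute one index per sample,
#' then average samples within each group, optionally with a seeded
#' percentile bootstrap CI over the group's samples.  With unequal
#' per-sample weight totals this differs (slightly) from the index of the
#' group-mean expression; [compare_index_modes()] measures the discrepancy.
#'
#' @param gene_evo a [gene_evo_table()]
#' @param expr genes x samples [expression_matrix()]
#' @param meta [sample_metadata()] covering the samples
#' @param group_by grouping key, as in [aggregate_expression()]
#' @param kind `"ERI"` or `"TAI"`
#' @param n_boot bootstrap resamples for percentile CIs (0 = none)
#' @param conf CI level (default 0.95)
#' @param seed seed for the bootstrap
#' @return data.frame: group, lineage, index_kind, value (group mean of
#'   per-sample indices), n_samples, and `ci_lo`/`ci_hi` when `n_boot > 0`
#' @export
per_sample_index <- function(gene_evo, expr, meta, group_by = "region",
                             kind = c("ERI", "TAI"), n_boot = 0,
                             conf = 0.95, seed = 1L) {
  kind <- match.arg(kind)
  per_sample <- compute_index_table(gene_evo, expr, kind)
  meta <- sample_metadata(as.data.frame(meta))
  m <- meta[match(per_sample$group, meta$sample_id), , drop = FALSE]
  key <- switch(group_by,
    region = m$region,
    window = m$window,
    region_window = paste(m$region, m$window, sep = GROUP_SEP),
    cell_type = m$cell_type,
    region_cell_type = paste(m$region, m$cell_type, sep = GROUP_SEP))
  set.seed(seed)
  lin <- ifelse(is.na(per_sample$lineage), "", per_sample$lineage)
  split_keys <- split(seq_len(nrow(per_sample)),
                      paste(key, lin, sep = "\r"), drop = TRUE)
  rows <- lapply(names(split_keys), function(nm) {
    idx <- split_keys[[nm]]
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    lineage_lab <- if (length(parts) < 2L || !nzchar(parts[2])) NA_character_ else parts[2]
    vals <- per_sample$value[idx]
    out <- data.frame(group = parts[1], lineage = lineage_lab, index_kind = kind,
                      value = mean(vals), n_samples = length(vals),
                      stringsAsFactors = FALSE)
    if (n_boot > 0) {
      boots <- vapply(seq_len(n_boot), function(b) {
        mean(vals[sample.int(length(vals), replace = TRUE)])
      }, numeric(1))
      qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
      out$ci_lo <- qs[1]
      out$ci_hi <- qs[2]
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discrepancy between the two index computation modes
#'
#' Computes each group index both ways -- index of the group-mean expression
#' (aggregate-then-index, the default reporting path) and mean of per-sample
#' indices -- and reports them side by side with their difference.  The two
#' agree exactly only when every sample of a group has the same total
#' weight.
#'
#' @inheritParams per_sample_index
#' @return data.frame: group, lineage, aggregate_value, per_sample_value,
#'   difference
#' @export
compare_index_modes <- function(gene_evo, expr, meta, group_by = "region",
                                kind = c("ERI", "TAI")) {
  kind <- match.arg(kind)
  agg <- compute_index_table(gene_evo,
                             aggregate_expression(expr, meta, group_by), kind)
  per <- per_sample_index(gene_evo, expr, meta, group_by, kind)
  key_a <- paste(agg$group, agg$lineage)
  key_p <- paste(per$group, per$lineage)
  idx <- match(key_a, key_p)
  data.frame(group = agg$group, lineage = agg$lineage,
             aggregate_value = agg$value,
             per_sample_value = per$value[idx],
             difference = agg$value - per$value[idx],
             stringsAsFactors = FALSE)
}
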