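# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (explicit loops, textbook formulas) and
# never call the package functions they are used to check.

naive_weighted_index <- function(values, weights) {
  num <- 0
  den <- 0
  n <- 0L
  for (i in seq_along(values)) {
    if (!is.na(values[i]) && !is.na(weights[i]) && weights[i] > 0) {
      num <- num + values[i] * weights[i]
      den <- den + weights[i]
      n <- n + 1L
    }
  }
  list(value = num / den, n_used = n)
}

# brute-force index table: explicit double loop over groups and value columns
naive_index_table <- function(gene_evo, expr, kind = "ERI") {
  genes <- intersect(gene_evo$gene_id, rownames(expr))
  ge <- as.data.frame(gene_evo)
  ge <- ge[match(genes, ge$gene_id), , drop = FALSE]
  cols <- if (kind == "ERI") evo_lineages(gene_evo) else "age"
  out <- list()
  for (vc in cols) {
    for (g in colnames(expr)) {
      wi <- naive_weighted_index(ge[[vc]], unclass(expr)[genes, g])
      out[[length(out) + 1L]] <- data.frame(
        group = g, lineage = if (kind == "ERI") vc else NA_character_,
        value = wi$value, n_genes_used = wi$n_used,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# textbook two-sample t statistics (hand-derived formulas, two-sided p)
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

student_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# fixtures ------------------------------------------------------------------

toy_expr <- function(values, genes = NULL, samples = NULL,
                     units = "normalized") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, units = units)
}

toy_gene_evo <- function(dnds, age = NULL, lineages = colnames(dnds)) {
  n <- nrow(dnds)
  if (is.null(age)) age <- seq_len(n)
  df <- data.frame(gene_id = sprintf("g%d", seq_len(n)), dnds, age = age,
                   check.names = FALSE, stringsAsFactors = FALSE)
  gene_evo_table(df, lineages = lineages)
}

toy_meta <- function(sample_id, region, region_class, window = NA,
                     unique_reads = 2e7, total_reads = 2.2e7) {
  sample_metadata(data.frame(
    sample_id = sample_id, region = region, region_class = region_class,
    window = window, uniquely_mapped_reads = unique_reads,
    total_reads = total_reads, stringsAsFactors = FALSE))
}

generic_regions <- function(n_noncortical, n_cortical) {
  data.frame(
    region = sprintf("R%02d", seq_len(n_noncortical + n_cortical)),
    region_class = rep(c("non_cortical", "cortical"),
                       c(n_noncortical, n_cortical)),
    stringsAsFactors = FALSE)
}

# small, fast simulation config for Monte Carlo work (overridable defaults)
calib_config <- function(...) {
  args <- list(n_genes = 300, regions = generic_regions(6, 6),
               n_samples_per_region = 2, seed = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# full simulate -> aggregate -> ERI -> compare chain, per-lineage p-values
one_study_pvalues_for_test <- function(cfg) {
  ge <- simulate_gene_evo(cfg)
  st <- simulate_expression_study(ge, cfg)
  eri <- compute_eri_table(ge, aggregate_expression(st$expr, st$meta, "region"))
  compare_region_classes(eri, cfg$regions)$p_value
}
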