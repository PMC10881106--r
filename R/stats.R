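# Inferential layer: cortical vs non-cortical comparison of per-region
# indices, dN/dS--expression correlation diagnostics, developmental peak
# detection, and Monte Carlo calibration of the whole comparison.

#' Compare region classes by two-sample t-test, per lineage
#'
#' For each lineage, tests the per-region ERI values of non-cortical regions
#' against those of cortical regions.  Welch's unequal-variance test is the
#' default (the Student pooled test is available); two-sided by default, the
#' directional alternative "non-cortical greater" is available.  Regions of
#' class `"other"` are excluded.  Raw p-values are reported per lineage; a
#' Benjamini-Hochberg column (`p_bh`) is emitted alongside for convenience.
#'
#' If both classes have zero variance the closed form is used: t = 0, p = 1
#' when the means agree, |t| = Inf, p = 0 otherwise (under the two-sided
#' alternative).
#'
#' @param eri_table an [index_table()] of ERI values with `group` = region
#' @param class_map named character vector region -> region_class, or a
#'   data.frame with columns `region`, `region_class`
#' @param method `"welch"` (default) or `"student"`
#' @param sidedness `"two_sided"` (default) or `"greater"` (non-cortical
#'   mean greater than cortical)
#' @return data.frame, one row per lineage: `lineage`, `mean_noncortical`,
#'   `mean_cortical`, `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `method`, `sidedness`, `p_bh`
#' @export
compare_region_classes <- function(eri_table,
                                   class_map,
                                   method = c("welch", "student"),
                                   sidedness = c("two_sided", "greater")) {
  method <- match.arg(method)
  sidedness <- match.arg(sidedness)
  if (is.data.frame(class_map)) {
    class_map <- setNames(class_map$region_class, class_map$region)
  }
  tab <- as.data.frame(eri_table)
  tab <- tab[tab$index_kind == "ERI", , drop = FALSE]
  cls <- class_map[tab$group]
  unknown <- unique(tab$group[is.na(cls)])
  if (length(unknown)) {
    stop_evoindex("evoindex_validation",
                  "region(s) missing from class map: %s",
                  paste(head(unknown, 10), collapse = ", "))
  }
  tab$cls <- unname(cls)
  tab <- tab[tab$cls != "other", , drop = FALSE]
  lineages <- unique(tab$lineage)
  rows <- lapply(lineages, function(ln) {
    sub <- tab[tab$lineage == ln, , drop = FALSE]
    x <- sub$value[sub$cls == "non_cortical"]
    y <- sub$value[sub$cls == "cortical"]
    if (length(x) < 2L || length(y) < 2L) {
      stop_evoindex("evoindex_validation",
                    "lineage %s: each class needs >= 2 regions (non_cortical %d, cortical %d)",
                    ln, length(x), length(y))
    }
    alt <- if (sidedness == "two_sided") "two.sided" else "greater"
    if (var(x) == 0 && var(y) == 0) {
      diff <- mean(x) - mean(y)
      t_stat <- if (diff == 0) 0 else sign(diff) * Inf
      df <- length(x) + length(y) - 2
      p <- if (diff == 0) 1 else if (alt == "two.sided") 0 else if (diff > 0) 0 else 1
    } else {
      tt <- t.test(x, y, var.equal = (method == "student"), alternative = alt)
      t_stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
    data.frame(lineage = ln, mean_noncortical = mean(x),
               mean_cortical = mean(y), t_statistic = t_stat,
               degrees_of_freedom = df, p_value = p,
               method = method, sidedness = sidedness,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Pearson correlation between dN/dS and expression, per group and lineage
#'
#' Diagnostic for the independence of the two ingredients of the
#' expression-weighted rate index: for every (group, lineage) pair, the
#' Pearson correlation between per-gene dN/dS and (optionally log1p
#' transformed) expression, with pairwise exclusion of missing values.
#' Pairs with fewer than 3 complete genes or a zero-variance vector are
#' flagged (`undefined = TRUE`, `pearson_r = NA`), never an error.
#'
#' @param gene_evo a [gene_evo_table()]
#' @param grouped_expr genes x groups [expression_matrix()]
#' @param transform `"identity"` (default) or `"log1p"`
#' @return data.frame: `group`, `lineage`, `pearson_r`, `n_genes`,
#'   `undefined`
#' @export
dnds_expression_correlation <- function(gene_evo, grouped_expr,
                                        transform = c("identity", "log1p")) {
  transform <- match.arg(transform)
  genes <- intersect(gene_evo$gene_id, rownames(grouped_expr))
  if (!length(genes)) {
    stop_evoindex("evoindex_validation",
                  "no genes shared between the gene table and the expression matrix")
  }
  ge <- as.data.frame(gene_evo)[match(genes, gene_evo$gene_id), , drop = FALSE]
  ex <- unclass(grouped_expr)[genes, , drop = FALSE]
  if (transform == "log1p") ex <- log1p(ex)
  lineages <- evo_lineages(gene_evo)
  rows <- vector("list", ncol(ex) * length(lineages))
  k <- 0L
  for (g in colnames(ex)) {
    e <- ex[, g]
    for (ln in lineages) {
      d <- ge[[ln]]
      keep <- !is.na(d) & !is.na(e)
      n <- sum(keep)
      k <- k + 1L
      undef <- n < 3L || sd(d[keep]) == 0 || sd(e[keep]) == 0
      r <- if (undef) NA_real_ else cor(d[keep], e[keep])
      rows[[k]] <- data.frame(group = g, lineage = ln, pearson_r = r,
                              n_genes = n, undefined = undef,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peak (or trough) developmental window per region and lineage
#'
#' For an index table computed on region x window groups, finds per
#' (region, lineage) the window where the trajectory peaks: the argmax over
#' windows for ERI, the argmin for TAI (the "youngest transcriptome"
#' reading).  Exact ties break toward the earliest window in the configured
#' order.  The result is invariant to adding a constant to all index
#' values.
#'
#' @param idx_table an [index_table()] whose `group` values are
#'   `"<region>|<window>"` (as produced by
#'   `aggregate_expression(..., group_by = "region_window")`)
#' @param windows ordered window labels; unknown labels in the table are an
#'   error
#' @return data.frame: `region`, `lineage`, `index_kind`, `peak_window`,
#'   `direction` (`"max"` for ERI, `"min"` for TAI), `peak_value`
#' @export
peak_stage <- function(idx_table, windows = developmental_windows()$window) {
  tab <- as.data.frame(idx_table)
  parts <- strsplit(tab$group, GROUP_SEP, fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop_evoindex("evoindex_validation",
                  "group labels must be '<region>%s<window>'", GROUP_SEP)
  }
  tab$region <- vapply(parts, `[`, "", 1L)
  tab$window <- vapply(parts, `[`, "", 2L)
  unknown <- setdiff(unique(tab$window), windows)
  if (length(unknown)) {
    stop_evoindex("evoindex_validation",
                  "unknown window label(s) %s; configured order: %s",
                  paste(unknown, collapse = ", "),
                  paste(windows, collapse = ", "))
  }
  lin <- ifelse(is.na(tab$lineage), "", tab$lineage)
  keys <- split(seq_len(nrow(tab)),
                paste(tab$region, lin, tab$index_kind, sep = "\r"),
                drop = TRUE)
  rows <- lapply(keys, function(idx) {
    sub <- tab[idx, , drop = FALSE]
    if (length(unique(sub$window)) < 2L) {
      stop_evoindex("evoindex_validation",
                    "region %s: need >= 2 windows for a trajectory",
                    sub$region[1])
    }
    ord <- order(match(sub$window, windows))
    sub <- sub[ord, , drop = FALSE]
    direction <- if (sub$index_kind[1] == "TAI") "min" else "max"
    ext <- if (direction == "max") max(sub$value) else min(sub$value)
    pick <- which(sub$value == ext)[1]   # earliest-window tie break
    data.frame(region = sub$region[1], lineage = sub$lineage[1],
               index_kind = sub$index_kind[1],
               peak_window = sub$window[pick], direction = direction,
               peak_value = ext, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one simulated study -> per-lineage p-values of the class comparison
one_study_pvalues <- function(cfg, method = "welch", sidedness = "two_sided") {
  ge <- simulate_gene_evo(cfg)
  study <- simulate_expression_study(ge, cfg)
  agg <- aggregate_expression(study$expr, study$meta, "region")
  eri <- compute_eri_table(ge, agg)
  cmp <- compare_region_classes(eri, cfg$regions, method = method,
                                sidedness = sidedness)
  setNames(cmp$p_value, cmp$lineage)
}

#' Monte Carlo calibration of the class comparison
#'
#' Repeats simulate -> aggregate -> ERI -> t-test over `n_reps` replicate
#' synthetic studies and reports, per lineage, the fraction of replicates
#' rejecting at level `alpha`, with exact binomial confidence intervals,
#' plus the rate at which any lineage rejects.  With
#' `coupling_delta = 0` this measures the empirical type-I error of the
#' whole pipeline (which should sit near `alpha`); with a positive coupling
#' it measures power against the planted effect.  Fully seeded: replicate
#' `r` uses `config$seed + r`.
#'
#' @param config a [sim_config()]; `coupling_delta = 0` for a null
#'   calibration
#' @param n_reps number of replicate studies (>= 100)
#' @param alpha nominal test level (default 0.05)
#' @param method,sidedness passed to [compare_region_classes()]
#' @param conf level of the binomial CIs (default 0.95)
#' @return list: `per_lineage` (data.frame lineage, n_reject, rate, ci_lo,
#'   ci_hi), `any_lineage` (same for min-over-lineages p < alpha), `alpha`,
#'   `n_reps`
#' @export
run_null_calibration <- function(config, n_reps = 2000, alpha = 0.05,
                                 method = "welch", sidedness = "two_sided",
                                 conf = 0.95) {
  cfg <- validate_sim_config(unclass(config))
  if (n_reps < 100) invalid_parameter("n_reps must be >= 100")
  if (alpha <= 0 || alpha > 1) invalid_parameter("alpha must be in (0, 1]")
  pmat <- matrix(NA_real_, n_reps, length(cfg$lineages),
                 dimnames = list(NULL, cfg$lineages))
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    pmat[r, ] <- one_study_pvalues(cfg_r, method, sidedness)[cfg$lineages]
  }
  ci <- function(k) {
    b <- binom.test(k, n_reps, conf.level = conf)
    c(rate = k / n_reps, lo = b$conf.int[1], hi = b$conf.int[2])
  }
  per <- t(vapply(cfg$lineages,
                  function(ln) ci(sum(pmat[, ln] < alpha)), numeric(3)))
  per_lineage <- data.frame(lineage = cfg$lineages, n_reject = per[, 1] * n_reps,
                            rate = per[, 1], ci_lo = per[, 2], ci_hi = per[, 3],
                            stringsAsFactors = FALSE, row.names = NULL)
  k_any <- sum(apply(pmat, 1, min) < alpha)
  any_ci <- ci(k_any)
  list(per_lineage = per_lineage,
       any_lineage = data.frame(n_reject = k_any, rate = any_ci[1],
                                ci_lo = any_ci[2], ci_hi = any_ci[3],
                                row.names = NULL),
       alpha = alpha, n_reps = n_reps)
}
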