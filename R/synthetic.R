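# Synthetic study generator.  Emulates the statistical structure of a
# region-structured brain transcriptome study: per-lineage dN/dS tables,
# gene ages drawn from the species-tree node ages, log-normal expression
# with a planted class-dependent coupling between a gene's evolutionary rate
# and its expression, developmental-window structure with a planted peak,
# mapping-statistic covariates with exact planted QC failures, and Dollo
# presence/absence evolution for the gene-age module.  Every downstream
# stage can therefore be checked against a known truth.

#' Build a simulation configuration
#'
#' All knobs of the synthetic study in one validated list.  A single `seed`
#' governs the whole study; the individual generators derive their streams
#' from it by fixed offsets, so a study object is reproducible as a whole.
#'
#' Key parameters: `coupling_delta` is the extra log-expression shift per
#' standard-score unit of a gene's dN/dS applied in non-cortical samples
#' (0 = null, no planted class effect); `window_coupling` scales a tent
#' profile over developmental windows peaking at `peak_window`, so the
#' expression-weighted dN/dS of every region rises toward that window;
#' `rate_factor_shape` controls a per-gene gamma rate factor (mean 1) shared
#' across lineages, which induces the cross-lineage correlation of dN/dS
#' seen in real ortholog tables (`Inf` switches it off);
#' `reference_lineage = "mean"` couples expression to the per-gene mean
#' dN/dS across lineages (any single lineage label may be used instead).
#'
#' @param n_genes number of genes (default 2000)
#' @param lineages ordered lineage labels, default [primate_lineages()]
#' @param regions data.frame(region, region_class), default
#'   `region_preset("macaque45")`
#' @param n_samples_per_region samples simulated per region (default 13)
#' @param coupling_delta planted class coupling (default 0.5)
#' @param reference_lineage `"mean"` or a lineage label
#' @param windows ordered developmental window labels
#' @param peak_window planted peak window (must be in `windows`)
#' @param window_coupling strength of the developmental tent profile
#' @param dnds_shape,dnds_scale gamma parameters of per-lineage dN/dS
#'   (defaults 2 and 0.125, mean dN/dS 0.25)
#' @param rate_factor_shape shape (= rate) of the per-gene rate factor
#' @param missing_frac fraction of (gene, lineage) dN/dS cells set missing
#' @param age_rate_cor Gaussian-copula correlation between a gene's rate
#'   factor and its age rank (default 0: ages independent of dN/dS)
#' @param expr_sigma log-normal expression noise sd (natural log scale)
#' @param gene_log_mean,gene_log_sd distribution of per-gene baseline
#'   log-expression
#' @param loss_rate per-branch gene loss probability for presence/absence
#'   simulation
#' @param n_qc_fail number of samples planted below the QC thresholds
#' @param qc_min_unique_reads,qc_min_unique_frac QC thresholds the
#'   non-planted samples are guaranteed to exceed
#' @param cell_types optional cell-type labels assigned round-robin
#' @param tree dated species tree, default [default_species_tree()]
#' @param focal focal species leaf name
#' @param seed integer master seed
#' @return a validated list of class `sim_config`
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' ge <- simulate_gene_evo(cfg)
sim_config <- function(n_genes = 2000,
                       lineages = primate_lineages(),
                       regions = region_preset("macaque45"),
                       n_samples_per_region = 13,
                       coupling_delta = 0.5,
                       reference_lineage = "mean",
                       windows = developmental_windows()$window,
                       peak_window = "w6",
                       window_coupling = 0.5,
                       dnds_shape = 2,
                       dnds_scale = 0.125,
                       rate_factor_shape = 2,
                       missing_frac = 0.02,
                       age_rate_cor = 0,
                       expr_sigma = 0.5,
                       gene_log_mean = 2,
                       gene_log_sd = 1.0,
                       loss_rate = 0.1,
                       n_qc_fail = 0,
                       qc_min_unique_reads = 1e7,
                       qc_min_unique_frac = 0.8,
                       cell_types = NULL,
                       tree = default_species_tree(),
                       focal = default_focal_species(),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), lineages = lineages,
              regions = regions,
              n_samples_per_region = as.integer(n_samples_per_region),
              coupling_delta = coupling_delta,
              reference_lineage = reference_lineage,
              windows = windows, peak_window = peak_window,
              window_coupling = window_coupling,
              dnds_shape = dnds_shape, dnds_scale = dnds_scale,
              rate_factor_shape = rate_factor_shape,
              missing_frac = missing_frac, age_rate_cor = age_rate_cor,
              expr_sigma = expr_sigma, gene_log_mean = gene_log_mean,
              gene_log_sd = gene_log_sd, loss_rate = loss_rate,
              n_qc_fail = as.integer(n_qc_fail),
              qc_min_unique_reads = qc_min_unique_reads,
              qc_min_unique_frac = qc_min_unique_frac,
              cell_types = cell_types, tree = tree, focal = focal,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) invalid_parameter("n_genes must be >= 1")
  if (anyDuplicated(cfg$lineages)) invalid_parameter("lineage labels must be unique")
  if (!is.data.frame(cfg$regions) ||
      !all(c("region", "region_class") %in% names(cfg$regions))) {
    invalid_parameter("regions must be a data.frame(region, region_class)")
  }
  if (nrow(cfg$regions) < 1L) invalid_parameter("region list must be non-empty")
  if (anyDuplicated(cfg$regions$region)) invalid_parameter("region labels must be unique")
  bad <- setdiff(unique(cfg$regions$region_class), c("cortical", "non_cortical"))
  if (length(bad)) {
    invalid_parameter("region_class must be cortical or non_cortical (got: %s)",
                      paste(bad, collapse = ", "))
  }
  if (cfg$n_samples_per_region < 1L) invalid_parameter("n_samples_per_region must be >= 1")
  if (!is.finite(cfg$coupling_delta)) invalid_parameter("coupling_delta must be finite")
  if (cfg$dnds_shape <= 0 || cfg$dnds_scale <= 0) {
    invalid_parameter("gamma parameters dnds_shape and dnds_scale must be positive")
  }
  if (cfg$rate_factor_shape <= 0) invalid_parameter("rate_factor_shape must be positive")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    invalid_parameter("missing_frac must be in [0, 1)")
  }
  if (cfg$loss_rate < 0 || cfg$loss_rate > 1) invalid_parameter("loss_rate must be in [0, 1]")
  if (cfg$expr_sigma <= 0) invalid_parameter("expr_sigma must be positive")
  if (anyDuplicated(cfg$windows)) invalid_parameter("window labels must be unique")
  if (!cfg$peak_window %in% cfg$windows) {
    invalid_parameter("peak_window '%s' is not among the configured windows", cfg$peak_window)
  }
  if (abs(cfg$age_rate_cor) > 1) invalid_parameter("age_rate_cor must be in [-1, 1]")
  if (cfg$n_qc_fail < 0 ||
      cfg$n_qc_fail > nrow(cfg$regions) * cfg$n_samples_per_region) {
    invalid_parameter("n_qc_fail must be between 0 and the total sample count")
  }
  if (!cfg$reference_lineage %in% c("mean", cfg$lineages)) {
    invalid_parameter("reference_lineage must be 'mean' or one of the lineages")
  }
  if (!cfg$focal %in% cfg$tree$tip.label) {
    invalid_parameter("focal species '%s' is not a leaf of the tree", cfg$focal)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a per-gene evolutionary table
#'
#' dN/dS values are gamma-distributed per lineage with mean
#' `dnds_shape * dnds_scale`, multiplied by a per-gene rate factor (gamma,
#' mean 1) that correlates values across lineages; a `missing_frac` fraction
#' of cells is set missing.  Gene ages are drawn uniformly from the node
#' ages on the focal-to-root path of the configured species tree (including
#' age 0, the focal-only stratum), optionally rank-correlated with the rate
#' factor.
#'
#' @param config a [sim_config()]
#' @return a [gene_evo_table()]
#' @export
simulate_gene_evo <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  L <- length(cfg$lineages)
  rate <- if (is.finite(cfg$rate_factor_shape)) {
    rgamma(n, shape = cfg$rate_factor_shape, rate = cfg$rate_factor_shape)
  } else rep(1, n)
  pool <- sort(unname(focal_path_ages(cfg$tree, cfg$focal)))
  if (cfg$age_rate_cor == 0) {
    age <- pool[sample.int(length(pool), n, replace = TRUE)]
  } else {
    rho <- cfg$age_rate_cor
    z_rate <- qnorm(pgamma(rate, shape = cfg$rate_factor_shape,
                           rate = cfg$rate_factor_shape))
    # high rate factor <-> young gene when rho > 0 (fast genes look recent)
    u <- pnorm(-rho * z_rate + sqrt(1 - rho^2) * rnorm(n))
    age <- pool[pmin(length(pool), floor(u * length(pool)) + 1L)]
  }
  dnds <- matrix(rgamma(n * L, shape = cfg$dnds_shape, scale = cfg$dnds_scale),
                 nrow = n, ncol = L) * rate
  if (cfg$missing_frac > 0) {
    dnds[matrix(runif(n * L) < cfg$missing_frac, n, L)] <- NA_real_
  }
  colnames(dnds) <- cfg$lineages
  df <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                   dnds, age = age,
                   check.names = FALSE, stringsAsFactors = FALSE)
  gene_evo_table(df, lineages = cfg$lineages)
}

# standard score of the coupling reference (per-gene scalar; missing -> 0)
reference_zscore <- function(gene_evo, reference = "mean") {
  lineages <- evo_lineages(gene_evo)
  v <- if (identical(reference, "mean")) {
    rowMeans(as.matrix(gene_evo[, lineages]), na.rm = TRUE)
  } else {
    gene_evo[[reference]]
  }
  s <- sd(v, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v, na.rm = TRUE)) / s
  z[!is.finite(z)] <- 0
  z
}

# tent profile over windows: 1 at the peak, linear decay with window distance
window_profile <- function(windows, peak_window) {
  i <- seq_along(windows)
  ip <- match(peak_window, windows)
  1 - abs(i - ip) / max(1L, length(windows) - 1L)
}

#' Simulate a region-structured expression study
#'
#' Expression is log-normal per gene and sample.  In non-cortical samples
#' the expected log-expression of gene *i* is shifted by
#' `coupling_delta * z_i`, where `z_i` is the standard score of the gene's
#' reference dN/dS, which plants a positive excess of the expression-weighted
#' dN/dS (ERI) in non-cortical regions.  Samples are assigned developmental
#' windows round-robin within each region, with an additional shift
#' `window_coupling * profile(window) * z_i` peaking at the configured peak
#' window.  Mapping statistics are simulated (total reads negative binomial,
#' unique fraction beta) and guaranteed to pass the configured QC thresholds
#' except for `n_qc_fail` planted failures, recorded in the returned truth.
#'
#' @param gene_evo a [gene_evo_table()], typically from [simulate_gene_evo()]
#' @param config the same [sim_config()]
#' @return list with elements `expr` (an [expression_matrix()], units
#'   `"normalized"`), `meta` (a [sample_metadata()] table) and `truth` (list:
#'   `true_class_effect`, per-lineage `class_effect_by_lineage`,
#'   `true_gene_ages`, `true_peak_window`, `qc_fail` data frame)
#' @export
simulate_expression_study <- function(gene_evo, config) {
  cfg <- validate_sim_config(unclass(config))
  if (nrow(gene_evo) != cfg$n_genes) {
    invalid_parameter("gene_evo has %d rows but config$n_genes = %d",
                      nrow(gene_evo), cfg$n_genes)
  }
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  regions <- cfg$regions
  ns <- cfg$n_samples_per_region
  S <- nrow(regions) * ns
  z <- reference_zscore(gene_evo, cfg$reference_lineage)
  mu <- rnorm(n, cfg$gene_log_mean, cfg$gene_log_sd)

  region <- rep(regions$region, each = ns)
  region_class <- rep(regions$region_class, each = ns)
  widx <- rep((seq_len(ns) - 1L) %% length(cfg$windows) + 1L, nrow(regions))
  window <- cfg$windows[widx]
  sample_id <- sprintf("%s_s%02d", region, rep(seq_len(ns), nrow(regions)))
  cell_type <- if (is.null(cfg$cell_types)) NA_character_ else {
    cfg$cell_types[(seq_len(S) - 1L) %% length(cfg$cell_types) + 1L]
  }

  prof <- window_profile(cfg$windows, cfg$peak_window)
  a <- cfg$coupling_delta * (region_class == "non_cortical") +
    cfg$window_coupling * prof[widx]
  logx <- outer(mu, rep(1, S)) + outer(z, a) +
    matrix(rnorm(n * S, 0, cfg$expr_sigma), n, S)
  values <- exp(logx)
  dimnames(values) <- list(gene_evo$gene_id, sample_id)
  expr <- expression_matrix(values, units = "normalized")

  # mapping statistics: rejection-sample passing draws with a small safety
  # margin so rounding can never push a non-planted sample over a threshold
  total <- rnbinom(S, mu = 3.5e7, size = 15) + 1
  frac <- rbeta(S, 60, 6)
  bad <- which(total * frac <= cfg$qc_min_unique_reads * 1.05 |
               frac <= cfg$qc_min_unique_frac + 0.005)
  while (length(bad)) {
    total[bad] <- rnbinom(length(bad), mu = 3.5e7, size = 15) + 1
    frac[bad] <- rbeta(length(bad), 60, 6)
    bad <- which(total * frac <= cfg$qc_min_unique_reads * 1.05 |
                 frac <= cfg$qc_min_unique_frac + 0.005)
  }
  unique_reads <- round(total * frac)

  qc_fail <- data.frame(sample_id = character(0), fail_reads = logical(0),
                        fail_fraction = logical(0), stringsAsFactors = FALSE)
  if (cfg$n_qc_fail > 0) {
    planted <- sort(sample.int(S, cfg$n_qc_fail))
    fail_reads <- seq_along(planted) %% 2L == 1L   # alternate failure modes
    for (k in seq_along(planted)) {
      j <- planted[k]
      if (fail_reads[k]) {
        # at or below the read threshold; fraction stays clearly passing
        u <- round(runif(1, 0.5, 1) * cfg$qc_min_unique_reads)
        total[j] <- round(u / 0.9)
        unique_reads[j] <- u
      } else {
        # fraction at or below threshold; absolute reads stay clearly passing
        f <- runif(1, 0.55, cfg$qc_min_unique_frac)
        total[j] <- round(runif(1, 3e7, 4e7))
        unique_reads[j] <- floor(total[j] * f)
      }
    }
    qc_fail <- data.frame(sample_id = sample_id[planted],
                          fail_reads = fail_reads,
                          fail_fraction = !fail_reads,
                          stringsAsFactors = FALSE)
  }

  meta <- sample_metadata(data.frame(
    sample_id = sample_id, region = region, region_class = region_class,
    window = window, cell_type = cell_type,
    uniquely_mapped_reads = unique_reads, total_reads = total,
    stringsAsFactors = FALSE))

  truth <- list(
    true_class_effect = NA_real_,
    class_effect_by_lineage = planted_class_effect(gene_evo, mu, z, prof, cfg),
    true_gene_ages = setNames(gene_evo$age, gene_evo$gene_id),
    true_peak_window = cfg$peak_window,
    qc_fail = qc_fail)
  truth$true_class_effect <- mean(truth$class_effect_by_lineage, na.rm = TRUE)
  list(expr = expr, meta = meta, truth = truth)
}

# expected ERI difference (non-cortical minus cortical) per lineage under the
# planted log-linear coupling, using expected sample weights
planted_class_effect <- function(gene_evo, mu, z, prof, cfg) {
  w_base <- exp(mu + cfg$expr_sigma^2 / 2) *
    rowMeans(exp(outer(z, cfg$window_coupling * prof)))
  w_nc <- w_base * exp(cfg$coupling_delta * z)
  vapply(evo_lineages(gene_evo), function(ln) {
    d <- gene_evo[[ln]]
    keep <- !is.na(d)
    sum(d[keep] * w_nc[keep]) / sum(w_nc[keep]) -
      sum(d[keep] * w_base[keep]) / sum(w_base[keep])
  }, numeric(1))
}

#' Simulate ortholog presence/absence by Dollo evolution
#'
#' Each gene originates at a node drawn uniformly from the focal-to-root
#' path (including the focal leaf itself), is present throughout the origin
#' clade, and is then lost independently along each descendant branch with
#' probability `loss_rate`; a loss removes the whole subtree below the
#' branch.  Branches on the focal path never lose the gene, so every gene is
#' observable in the focal species.
#'
#' @param tree dated species tree (`phylo`)
#' @param config a [sim_config()]; uses `n_genes`, `loss_rate`, `focal`,
#'   `seed`
#' @return list with `pa` (logical genes x species matrix) and `truth`
#'   (list: `true_gene_ages` named vector, `origin_node` labels)
#' @export
simulate_presence_absence <- function(tree, config) {
  cfg <- validate_sim_config(unclass(config))
  if (!cfg$focal %in% tree$tip.label) {
    stop_evoindex("evoindex_validation",
                  "focal species '%s' is not a leaf of the tree", cfg$focal)
  }
  set.seed(cfg$seed + 3L)
  n <- cfg$n_genes
  ntip <- length(tree$tip.label)
  ages <- node_ages_from_tree(tree)
  path <- focal_path_nodes(tree, cfg$focal)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede descendants
  edge <- tr$edge
  nE <- nrow(edge)
  immune <- edge[, 2] %in% path
  origins <- path[sample.int(length(path), n, replace = TRUE)]
  pa <- matrix(FALSE, n, ntip, dimnames = list(sprintf("g%05d", seq_len(n)),
                                               tree$tip.label))
  nnode_total <- ntip + tree$Nnode
  for (g in seq_len(n)) {
    alive <- logical(nnode_total)
    alive[origins[g]] <- TRUE
    lost <- !immune & runif(nE) < cfg$loss_rate
    for (e in seq_len(nE)) {
      if (alive[edge[e, 1]] && !lost[e]) alive[edge[e, 2]] <- TRUE
    }
    pa[g, ] <- alive[seq_len(ntip)]
  }
  truth <- list(true_gene_ages = setNames(unname(ages[origins]), rownames(pa)),
                origin_node = setNames(names(ages)[origins], rownames(pa)))
  list(pa = pa, truth = truth)
}

#' Write a complete synthetic fixture set to disk
#'
#' Simulates the gene table, expression study and presence/absence matrix
#' under one configuration and writes them as plain-text files:
#' `gene_evo.tsv`, `expression.tsv`, `metadata.tsv`, `tree.nwk`,
#' `presence_absence.tsv` and a `sim_manifest.json` recording the
#' configuration and the planted truth.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the file paths and the two truth lists
#' @export
write_fixture_set <- function(config, dir) {
  cfg <- validate_sim_config(unclass(config))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ge <- simulate_gene_evo(cfg)
  study <- simulate_expression_study(ge, cfg)
  dollo <- simulate_presence_absence(cfg$tree, cfg)
  paths <- list(
    gene_evo = file.path(dir, "gene_evo.tsv"),
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    presence_absence = file.path(dir, "presence_absence.tsv"),
    manifest = file.path(dir, "sim_manifest.json"))
  write_gene_evo_table(ge, paths$gene_evo)
  write_expression_matrix(study$expr, paths$expression)
  write_sample_metadata(study$meta, paths$metadata)
  ape::write.tree(cfg$tree, file = paths$tree)
  write_presence_absence(dollo$pa, paths$presence_absence)
  manifest <- list(
    config = sim_config_serializable(cfg),
    truth = list(
      true_class_effect = study$truth$true_class_effect,
      class_effect_by_lineage = as.list(study$truth$class_effect_by_lineage),
      true_peak_window = study$truth$true_peak_window,
      n_qc_fail = nrow(study$truth$qc_fail),
      qc_fail = study$truth$qc_fail))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, study_truth = study$truth,
                 dollo_truth = dollo$truth))
}

sim_config_serializable <- function(cfg) {
  out <- unclass(cfg)
  out$tree <- ape::write.tree(cfg$tree)
  out$regions <- as.list(setNames(cfg$regions$region_class, cfg$regions$region))
  out
}
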