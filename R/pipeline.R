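# Orchestration: reproducible staged runs over a config, with an auditable
# manifest (config hash, seed, input/output checksums, row counts).  Stage
# wall-times and row counts are logged to the console; the manifest itself
# contains no timestamps so reruns with identical config and inputs are
# byte-identical.

#' Build a pipeline run configuration
#'
#' File locations default to `<outdir>/<standard name>`, so `simulate`
#' followed by other commands works with no further wiring.  Precedence of
#' settings is: arguments to this function > config file values (when read
#' via [read_pipeline_config()]) > defaults.
#'
#' @param outdir output directory
#' @param gene_evo,expression,metadata,tree,presence_absence input paths
#'   (defaults under `outdir`)
#' @param gene_lengths optional path to a two-column TSV `gene_id`, `length`
#'   for TPM conversion of counts input
#' @param expression_units units of the expression input
#' @param lineages ordered lineage labels
#' @param windows ordered window labels
#' @param qc_min_unique_reads,qc_min_unique_frac QC thresholds
#' @param index_mode `"aggregate"` (index of group-mean expression, default)
#'   or `"per_sample"` (mean of per-sample indices)
#' @param ttest `"welch"` or `"student"`
#' @param sided `"two_sided"` or `"greater"`
#' @param transform `"identity"` or `"log1p"` for the correlation diagnostic
#' @param ages_from `"table"` (use the age column of the gene table) or
#'   `"inferred"` (use Dollo ages from tree + presence/absence)
#' @param sim a [sim_config()] used by the `simulate` and `calibrate`
#'   commands
#' @param calibration_reps replicates for the `calibrate` command
#' @param alpha test level for `calibrate`
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(outdir = "evoindex_out",
                            gene_evo = file.path(outdir, "gene_evo.tsv"),
                            expression = file.path(outdir, "expression.tsv"),
                            metadata = file.path(outdir, "metadata.tsv"),
                            tree = file.path(outdir, "tree.nwk"),
                            presence_absence = file.path(outdir, "presence_absence.tsv"),
                            gene_lengths = NULL,
                            expression_units = "normalized",
                            lineages = primate_lineages(),
                            windows = developmental_windows()$window,
                            qc_min_unique_reads = 1e7,
                            qc_min_unique_frac = 0.8,
                            index_mode = c("aggregate", "per_sample"),
                            ttest = c("welch", "student"),
                            sided = c("two_sided", "greater"),
                            transform = c("identity", "log1p"),
                            ages_from = c("table", "inferred"),
                            sim = NULL,
                            calibration_reps = 200,
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- list(outdir = outdir, gene_evo = gene_evo, expression = expression,
              metadata = metadata, tree = tree,
              presence_absence = presence_absence,
              gene_lengths = gene_lengths,
              expression_units = expression_units,
              lineages = lineages, windows = windows,
              qc_min_unique_reads = qc_min_unique_reads,
              qc_min_unique_frac = qc_min_unique_frac,
              index_mode = match.arg(index_mode),
              ttest = match.arg(ttest), sided = match.arg(sided),
              transform = match.arg(transform),
              ages_from = match.arg(ages_from),
              sim = sim, calibration_reps = calibration_reps, alpha = alpha,
              seed = as.integer(seed))
  if (anyDuplicated(cfg$lineages)) invalid_parameter("lineage labels must be unique")
  if (anyDuplicated(cfg$windows)) invalid_parameter("window labels must be unique")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a `sim:` block is
#' passed to [sim_config()].  Keys absent from the file keep their
#' defaults.
#'
#' @param path YAML file
#' @param ... overrides applied after the file (highest precedence)
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    invalid_parameter("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, t0, n_rows) {
  message(sprintf("[evoindex] %-10s %6.2fs  %d rows", stage,
                  as.numeric(Sys.time()) - t0, n_rows))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop_evoindex("evoindex_missing_input",
                  "missing required artifact '%s'; run the '%s' command first",
                  path, produced_by)
  }
  path
}

#' Run pipeline stages
#'
#' Commands: `simulate` (write a synthetic fixture set), `qc` (filter
#' metadata by mapping stats), `tpm` (counts to TPM when counts + gene
#' lengths are configured; otherwise pass the expression through unchanged),
#' `ages` (Dollo gene ages from tree + presence/absence), `eri` / `tai`
#' (index tables by region and by region x window), `compare` (class
#' t-tests), `correlate` (dN/dS-expression Pearson diagnostics),
#' `trajectory` (developmental peaks), `calibrate` (Monte Carlo calibration),
#' `all` (qc, tpm, ages, eri, tai, compare, correlate, trajectory).  Each
#' command writes its TSV/JSON outputs under `config$outdir` plus a
#' `run_manifest.json` with config hash, seed and input/output MD5
#' checksums.  Rerunning with identical config and inputs reproduces
#' byte-identical files.
#'
#' @param config a [pipeline_config()] or path to a YAML config file
#' @param command one of the commands above
#' @return invisibly, a named list of output paths
#' @export
run_pipeline <- function(config,
                         command = c("all", "simulate", "qc", "tpm", "ages",
                                     "eri", "tai", "compare", "correlate",
                                     "trajectory", "calibrate")) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  inputs <- character(0)

  out_path <- function(name) file.path(cfg$outdir, name)
  steps <- if (command == "all") {
    c("qc", "tpm", "ages", "eri", "tai", "compare", "correlate", "trajectory")
  } else command

  for (step in steps) {
    t0 <- as.numeric(Sys.time())
    switch(step,
      simulate = {
        if (is.null(cfg$sim)) {
          stop_evoindex("evoindex_missing_input",
                        "command 'simulate' needs a 'sim' block in the config")
        }
        fx <- write_fixture_set(cfg$sim, cfg$outdir)
        outputs <- c(outputs, fx$paths)
        stage_log("simulate", t0, cfg$sim$n_genes)
      },
      qc = {
        meta <- read_sample_metadata(require_artifact(cfg$metadata, "simulate"))
        inputs <- c(inputs, cfg$metadata)
        kept <- qc_filter_samples(meta, cfg$qc_min_unique_reads,
                                  cfg$qc_min_unique_frac)
        rej <- attr(kept, "qc_rejections")
        outputs$metadata_qc <- write_sample_metadata(kept, out_path("metadata_qc.tsv"))
        outputs$qc_rejections <- write_tsv(rej, out_path("qc_rejections.tsv"))
        stage_log("qc", t0, nrow(kept))
      },
      tpm = {
        expr <- read_expression_matrix(require_artifact(cfg$expression, "simulate"),
                                       units = cfg$expression_units)
        inputs <- c(inputs, cfg$expression)
        if (identical(cfg$expression_units, "counts")) {
          if (is.null(cfg$gene_lengths)) {
            stop_evoindex("evoindex_missing_input",
                          "counts input needs config field 'gene_lengths'")
          }
          lens <- read_tsv_raw(cfg$gene_lengths)
          inputs <- c(inputs, cfg$gene_lengths)
          expr <- counts_to_tpm(expr, setNames(lens$length, lens$gene_id))
        }
        outputs$expression_tpm <- write_expression_matrix(expr, out_path("expression_tpm.tsv"))
        stage_log("tpm", t0, nrow(expr))
      },
      ages = {
        tr <- ape::read.tree(require_artifact(cfg$tree, "simulate"))
        pa <- read_presence_absence(require_artifact(cfg$presence_absence, "simulate"))
        inputs <- c(inputs, cfg$tree, cfg$presence_absence)
        ages <- assign_gene_ages(pa, tr)
        outputs$gene_ages <- write_tsv(ages, out_path("gene_ages.tsv"))
        stage_log("ages", t0, nrow(ages))
      },
      eri = ,
      tai = {
        kind <- toupper(step)
        ge <- read_gene_evo_table(require_artifact(cfg$gene_evo, "simulate"),
                                  lineages = cfg$lineages)
        inputs <- c(inputs, cfg$gene_evo)
        if (kind == "TAI" && cfg$ages_from == "inferred") {
          ages <- read_tsv_raw(require_artifact(out_path("gene_ages.tsv"), "ages"))
          ge$age[match(ages$gene_id, ge$gene_id)] <- ages$age
        }
        expr_path <- if (file.exists(out_path("expression_tpm.tsv"))) {
          out_path("expression_tpm.tsv")
        } else require_artifact(cfg$expression, "simulate")
        units <- if (identical(cfg$expression_units, "counts")) "TPM" else cfg$expression_units
        expr <- read_expression_matrix(expr_path, units = units)
        meta_path <- if (file.exists(out_path("metadata_qc.tsv"))) {
          out_path("metadata_qc.tsv")
        } else require_artifact(cfg$metadata, "simulate")
        meta <- read_sample_metadata(meta_path)
        inputs <- c(inputs, expr_path, meta_path)
        expr <- expr[, intersect(colnames(expr), meta$sample_id), drop = FALSE]
        compute1 <- function(group_by) {
          if (cfg$index_mode == "aggregate") {
            agg <- aggregate_expression(expr, meta, group_by)
            if (kind == "ERI") compute_eri_table(ge, agg) else compute_tai_table(ge, agg)
          } else {
            ps <- per_sample_index(ge, expr, meta, group_by, kind)
            index_table(ps$group, ps$lineage, ps$index_kind, ps$value,
                        rep(1L, nrow(ps)))
          }
        }
        by_region <- compute1("region")
        nm <- tolower(kind)
        outputs[[paste0(nm, "_by_region")]] <-
          write_index_table(by_region, out_path(sprintf("%s_by_region.tsv", nm)))
        if (!anyNA(meta$window)) {
          by_rw <- compute1("region_window")
          outputs[[paste0(nm, "_by_region_window")]] <-
            write_index_table(by_rw, out_path(sprintf("%s_by_region_window.tsv", nm)))
        }
        stage_log(nm, t0, nrow(by_region))
      },
      compare = {
        eri_path <- require_artifact(out_path("eri_by_region.tsv"), "eri")
        meta <- read_sample_metadata(require_artifact(cfg$metadata, "simulate"))
        inputs <- c(inputs, eri_path, cfg$metadata)
        eri <- read_index_table(eri_path)
        class_map <- unique(meta[, c("region", "region_class")])
        cmp <- compare_region_classes(eri, class_map, method = cfg$ttest,
                                      sidedness = cfg$sided)
        outputs$comparisons <- write_tsv(cmp, out_path("comparisons.tsv"))
        stage_log("compare", t0, nrow(cmp))
      },
      correlate = {
        ge <- read_gene_evo_table(require_artifact(cfg$gene_evo, "simulate"),
                                  lineages = cfg$lineages)
        expr_path <- if (file.exists(out_path("expression_tpm.tsv"))) {
          out_path("expression_tpm.tsv")
        } else require_artifact(cfg$expression, "simulate")
        units <- if (identical(cfg$expression_units, "counts")) "TPM" else cfg$expression_units
        expr <- read_expression_matrix(expr_path, units = units)
        meta_path <- if (file.exists(out_path("metadata_qc.tsv"))) {
          out_path("metadata_qc.tsv")
        } else require_artifact(cfg$metadata, "simulate")
        meta <- read_sample_metadata(meta_path)
        inputs <- c(inputs, cfg$gene_evo, expr_path, meta_path)
        expr <- expr[, intersect(colnames(expr), meta$sample_id), drop = FALSE]
        agg <- aggregate_expression(expr, meta, "region")
        cors <- dnds_expression_correlation(ge, agg, transform = cfg$transform)
        outputs$correlations <- write_tsv(cors, out_path("correlations.tsv"))
        stage_log("correlate", t0, nrow(cors))
      },
      trajectory = {
        eri_path <- require_artifact(out_path("eri_by_region_window.tsv"), "eri")
        inputs <- c(inputs, eri_path)
        peaks <- peak_stage(read_index_table(eri_path), windows = cfg$windows)
        if (file.exists(out_path("tai_by_region_window.tsv"))) {
          tai_peaks <- peak_stage(read_index_table(out_path("tai_by_region_window.tsv")),
                                  windows = cfg$windows)
          peaks <- rbind(peaks, tai_peaks)
        }
        outputs$peaks <- write_tsv(peaks, out_path("peaks.tsv"))
        stage_log("trajectory", t0, nrow(peaks))
      },
      calibrate = {
        if (is.null(cfg$sim)) {
          stop_evoindex("evoindex_missing_input",
                        "command 'calibrate' needs a 'sim' block in the config")
        }
        cal <- run_null_calibration(cfg$sim, n_reps = cfg$calibration_reps,
                                    alpha = cfg$alpha, method = cfg$ttest,
                                    sidedness = cfg$sided)
        outputs$calibration <- out_path("calibration.json")
        jsonlite::write_json(cal, outputs$calibration, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, dataframe = "columns")
        stage_log("calibrate", t0, cfg$calibration_reps)
      })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("evoindex")),
    command = command,
    seed = cfg$seed,
    config_hash = unname(config_hash(cfg)),
    inputs = checksum_files(unique(inputs)),
    outputs = checksum_files(unlist(outputs, use.names = FALSE)))
  manifest_path <- out_path("run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs$manifest <- manifest_path
  invisible(outputs)
}

config_hash <- function(cfg) {
  c2 <- unclass(cfg)
  if (!is.null(c2$sim)) c2$sim <- sim_config_serializable(c2$sim)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(c2, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  tools::md5sum(tmp)
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(stats::setNames(list(), character(0)))
  as.list(tools::md5sum(paths))
}
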