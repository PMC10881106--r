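# Synthetic study generator: determinism, distributional contracts,
# planted-effect bookkeeping.

test_that("gene table simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 1000, seed = 7)
  a <- simulate_gene_evo(cfg)
  b <- simulate_gene_evo(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_genes = 1000, seed = 8)
  expect_false(identical(simulate_gene_evo(cfg2), a))
})

test_that("dN/dS values are non-negative with the configured missingness", {
  cfg <- sim_config(n_genes = 2000, missing_frac = 0.1, seed = 3)
  ge <- simulate_gene_evo(cfg)
  d <- as.matrix(as.data.frame(ge)[, evo_lineages(ge)])
  expect_true(all(d >= 0, na.rm = TRUE))
  expect_gt(mean(is.na(d)), 0.08)
  expect_lt(mean(is.na(d)), 0.12)
})

test_that("degenerate gamma scale collapses dN/dS to ~0", {
  cfg <- sim_config(n_genes = 200, dnds_scale = 1e-12, missing_frac = 0, seed = 2)
  ge <- simulate_gene_evo(cfg)
  d <- as.matrix(as.data.frame(ge)[, evo_lineages(ge)])
  expect_true(all(d < 1e-9))
})

test_that("per-lineage dN/dS sample means match the configured gamma law", {
  cfg <- sim_config(n_genes = 10000, missing_frac = 0, seed = 5)
  ge <- simulate_gene_evo(cfg)
  expected <- cfg$dnds_shape * cfg$dnds_scale
  for (ln in evo_lineages(ge)) {
    v <- ge[[ln]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - expected), 3 * se)
  }
})

test_that("gene ages are drawn from the focal-path node ages", {
  cfg <- sim_config(n_genes = 500, seed = 4)
  ge <- simulate_gene_evo(cfg)
  pool <- unname(focal_path_ages(cfg$tree, cfg$focal))
  expect_true(all(ge$age %in% pool))
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_config(dnds_shape = -1), class = "evoindex_invalid_parameter")
  expect_error(sim_config(dnds_scale = 0), class = "evoindex_invalid_parameter")
  expect_error(sim_config(loss_rate = 1.2), class = "evoindex_invalid_parameter")
  expect_error(sim_config(regions = data.frame(region = character(0),
                                               region_class = character(0))),
               class = "evoindex_invalid_parameter")
  expect_error(sim_config(peak_window = "w99"),
               class = "evoindex_invalid_parameter")
})

test_that("expression study has the promised shape and positivity", {
  cfg <- calib_config(seed = 9)
  ge <- simulate_gene_evo(cfg)
  st <- simulate_expression_study(ge, cfg)
  expect_s3_class(st$expr, "expression_matrix")
  expect_equal(dim(st$expr), c(cfg$n_genes,
                               nrow(cfg$regions) * cfg$n_samples_per_region))
  expect_true(all(unclass(st$expr) > 0))
  expect_equal(nrow(st$meta), ncol(st$expr))
  expect_identical(st$truth$true_peak_window, cfg$peak_window)
  # windows assigned round-robin within each region
  expect_true(all(table(st$meta$window) > 0))
})

test_that("null coupling leaves the class difference centered at zero", {
  diffs <- vapply(1:200, function(r) {
    cfg <- calib_config(coupling_delta = 0, seed = 1000 + r)
    ge <- simulate_gene_evo(cfg)
    st <- simulate_expression_study(ge, cfg)
    eri <- compute_eri_table(ge, aggregate_expression(st$expr, st$meta, "region"))
    cls <- setNames(cfg$regions$region_class, cfg$regions$region)
    mean(eri$value[cls[eri$group] == "non_cortical"]) -
      mean(eri$value[cls[eri$group] == "cortical"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("a planted coupling produces a positive class difference almost surely", {
  wins <- vapply(1:200, function(r) {
    cfg <- calib_config(coupling_delta = 0.5, n_samples_per_region = 4,
                        seed = 3000 + r)
    ge <- simulate_gene_evo(cfg)
    st <- simulate_expression_study(ge, cfg)
    eri <- compute_eri_table(ge, aggregate_expression(st$expr, st$meta, "region"))
    cls <- setNames(cfg$regions$region_class, cfg$regions$region)
    mean(eri$value[cls[eri$group] == "non_cortical"]) >
      mean(eri$value[cls[eri$group] == "cortical"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("planted QC failures are bookkept exactly", {
  cfg <- sim_config(n_genes = 50, regions = generic_regions(5, 5),
                    n_samples_per_region = 59, n_qc_fail = 24, seed = 6)
  ge <- simulate_gene_evo(cfg)
  st <- simulate_expression_study(ge, cfg)
  expect_equal(nrow(st$meta), 590)
  expect_equal(nrow(st$truth$qc_fail), 24)
  # planted rows really violate the thresholds; all others pass
  m <- st$meta
  fail <- !(m$uniquely_mapped_reads > cfg$qc_min_unique_reads &
            m$uniquely_mapped_reads / m$total_reads > cfg$qc_min_unique_frac)
  expect_setequal(m$sample_id[fail], st$truth$qc_fail$sample_id)
})

test_that("expected class effect recorded in truth is positive under coupling", {
  cfg <- calib_config(coupling_delta = 0.5, seed = 12)
  ge <- simulate_gene_evo(cfg)
  st <- simulate_expression_study(ge, cfg)
  expect_gt(st$truth$true_class_effect, 0)
  expect_true(all(st$truth$class_effect_by_lineage > 0))
  cfg0 <- calib_config(coupling_delta = 0, seed = 12)
  st0 <- simulate_expression_study(simulate_gene_evo(cfg0), cfg0)
  expect_equal(st0$truth$true_class_effect, 0)
})

test_that("presence/absence without loss is exactly the origin clade", {
  tree <- default_species_tree()
  cfg <- sim_config(n_genes = 300, loss_rate = 0, seed = 21)
  sim <- simulate_presence_absence(tree, cfg)
  expect_true(all(sim$pa[, "Homo_sapiens"]))
  ages <- node_ages_from_tree(tree)
  # every carrier set is a full clade: presence equals leaves within origin age
  aa <- assign_gene_ages(sim$pa, tree)
  expect_identical(setNames(aa$age, aa$gene_id), sim$truth$true_gene_ages)
})

test_that("fixture set round-trips through disk", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 40, regions = generic_regions(2, 2),
                    n_samples_per_region = 3, seed = 17)
  fx <- write_fixture_set(cfg, dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  ge <- read_gene_evo_table(fx$paths$gene_evo)
  expect_equal(nrow(ge), 40)
  ex <- read_expression_matrix(fx$paths$expression)
  expect_equal(dim(ex), c(40, 12))
  pa <- read_presence_absence(fx$paths$presence_absence)
  expect_true(all(pa[, "Homo_sapiens"]))
})
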