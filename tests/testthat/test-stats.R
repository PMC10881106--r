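# Group comparison, correlation diagnostics, peak detection, calibration.

make_eri_table <- function(values_nc, values_c, lineage = "L1") {
  regions <- c(sprintf("N%d", seq_along(values_nc)),
               sprintf("C%d", seq_along(values_c)))
  index_table(regions, lineage, "ERI", c(values_nc, values_c),
              rep(10L, length(regions)))
}

class_map_for <- function(values_nc, values_c) {
  setNames(rep(c("non_cortical", "cortical"),
               c(length(values_nc), length(values_c))),
           c(sprintf("N%d", seq_along(values_nc)),
             sprintf("C%d", seq_along(values_c))))
}

test_that("t statistics match the textbook Welch and Student formulas", {
  set.seed(202)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    tab <- make_eri_table(x, y)
    cmap <- class_map_for(x, y)
    w <- compare_region_classes(tab, cmap, method = "welch")
    ow <- welch_oracle(x, y)
    expect_equal(w$t_statistic, ow$t, tolerance = 1e-10)
    expect_equal(w$degrees_of_freedom, ow$df, tolerance = 1e-10)
    expect_equal(w$p_value, ow$p, tolerance = 1e-10)
    s <- compare_region_classes(tab, cmap, method = "student")
    os <- student_oracle(x, y)
    expect_equal(s$t_statistic, os$t, tolerance = 1e-10)
    expect_equal(s$p_value, os$p, tolerance = 1e-10)
  }
})

test_that("degenerate equal-value classes give t = 0, p = 1", {
  tab <- make_eri_table(c(0.3, 0.3), c(0.3, 0.3))
  cmap <- class_map_for(c(1, 2), c(1, 2))
  res <- compare_region_classes(tab, cmap)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("classes with fewer than two regions are an error", {
  tab <- make_eri_table(0.4, c(0.2, 0.3))
  cmap <- class_map_for(1, c(1, 2))
  expect_error(compare_region_classes(tab, cmap),
               class = "evoindex_validation")
})

test_that("directional and 'other'-class handling work", {
  x <- c(0.5, 0.6, 0.7)
  y <- c(0.2, 0.3, 0.25)
  tab <- make_eri_table(x, y)
  cmap <- class_map_for(x, y)
  two <- compare_region_classes(tab, cmap, sidedness = "two_sided")
  gt <- compare_region_classes(tab, cmap, sidedness = "greater")
  expect_equal(gt$p_value, two$p_value / 2, tolerance = 1e-12)
  # a region marked "other" is excluded without error
  tab2 <- rbind(as.data.frame(tab),
                data.frame(group = "X", lineage = "L1", index_kind = "ERI",
                           value = 99, n_genes_used = 10L))
  cmap2 <- c(cmap, X = "other")
  res2 <- compare_region_classes(index_table(tab2$group, tab2$lineage,
                                             tab2$index_kind, tab2$value,
                                             tab2$n_genes_used), cmap2)
  expect_equal(res2$mean_noncortical, mean(x))
})

test_that("planted class effect is detected with high power", {
  rejections <- vapply(1:200, function(r) {
    cfg <- sim_config(n_genes = 300, regions = generic_regions(20, 25),
                      n_samples_per_region = 2, coupling_delta = 0.5,
                      seed = 40000 + r)
    min(one_study_pvalues_for_test(cfg)) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.90)
})

test_that("correlation diagnostics match closed forms and flag degeneracy", {
  # expression exactly proportional to dN/dS: r = 1
  d <- c(0.1, 0.2, 0.4, 0.8)
  ge <- toy_gene_evo(matrix(d, 4, 1, dimnames = list(NULL, "L1")))
  ex <- toy_expr(matrix(3 * d, 4, 1, dimnames = list(sprintf("g%d", 1:4), "A")))
  res <- dnds_expression_correlation(ge, ex, transform = "identity")
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  # constant expression: flagged undefined, not an error
  exc <- toy_expr(matrix(2, 4, 1, dimnames = list(sprintf("g%d", 1:4), "A")))
  resc <- dnds_expression_correlation(ge, exc)
  expect_true(resc$undefined)
  expect_true(is.na(resc$pearson_r))
  # pairwise missing exclusion
  ge2 <- toy_gene_evo(matrix(c(0.1, NA, 0.4, 0.8), 4, 1,
                             dimnames = list(NULL, "L1")))
  res2 <- dnds_expression_correlation(ge2, ex)
  expect_equal(res2$n_genes, 3L)
  expect_equal(res2$pearson_r, cor(c(0.1, 0.4, 0.8), 3 * c(0.1, 0.4, 0.8)),
               tolerance = 1e-12)
})

test_that("independent dN/dS and expression give near-zero correlations", {
  hits <- vapply(1:200, function(r) {
    set.seed(50000 + r)
    n <- 5000
    d <- rgamma(n, 2, 8)
    e <- rlnorm(n, 2, 1)
    abs(cor(d, e)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("peak detection follows the trajectory shape and tie rules", {
  windows <- paste0("w", 1:4)
  grp <- as.vector(outer("R1", windows, paste, sep = "|"))
  # strictly increasing: last window wins
  it <- index_table(grp, "L1", "ERI", c(1, 2, 3, 4), 10L)
  expect_equal(peak_stage(it, windows)$peak_window, "w4")
  # exact tie between w2 and w3 resolves to the earlier window
  it2 <- index_table(grp, "L1", "ERI", c(1, 5, 5, 2), 10L)
  expect_equal(peak_stage(it2, windows)$peak_window, "w2")
  # TAI uses the trough
  it3 <- index_table(grp, NA, "TAI", c(9, 3, 7, 8), 10L)
  res3 <- peak_stage(it3, windows)
  expect_equal(res3$peak_window, "w2")
  expect_equal(res3$direction, "min")
  # adding a constant changes nothing
  it4 <- index_table(grp, "L1", "ERI", c(1, 5, 4, 2) + 100, 10L)
  expect_equal(peak_stage(it4, windows)$peak_window, "w2")
  # unknown window labels are an error
  expect_error(peak_stage(it, paste0("v", 1:4)), class = "evoindex_validation")
})

test_that("planted developmental peak is recovered end to end", {
  regs <- data.frame(region = c("AMY", "HIP", "STR"),
                     region_class = "non_cortical")
  cfg <- sim_config(n_genes = 2000, regions = regs, n_samples_per_region = 96,
                    seed = 61)
  ge <- simulate_gene_evo(cfg)
  st <- simulate_expression_study(ge, cfg)
  eri <- compute_eri_table(ge, aggregate_expression(st$expr, st$meta,
                                                    "region_window"))
  pk <- peak_stage(eri, cfg$windows)
  expect_gte(mean(pk$peak_window == st$truth$true_peak_window), 0.9)
})

test_that("null calibration is deterministic and saturates at alpha = 1", {
  cfg <- calib_config(coupling_delta = 0, seed = 71)
  a <- run_null_calibration(cfg, n_reps = 100, alpha = 0.05)
  b <- run_null_calibration(cfg, n_reps = 100, alpha = 0.05)
  expect_identical(a, b)
  expect_true(all(a$per_lineage$rate >= 0 & a$per_lineage$rate <= 1))
  sat <- run_null_calibration(cfg, n_reps = 100, alpha = 1)
  expect_true(all(sat$per_lineage$rate == 1))
  expect_error(run_null_calibration(cfg, n_reps = 50),
               class = "evoindex_invalid_parameter")
})

test_that("permuting region classes destroys a planted effect", {
  # with labels shuffled, the planted coupling no longer aligns with the
  # class map, so rejections should fall back toward the nominal level
  set.seed(81)
  reject <- vapply(1:200, function(r) {
    cfg <- calib_config(coupling_delta = 0.5, seed = 80000 + r)
    ge <- simulate_gene_evo(cfg)
    st <- simulate_expression_study(ge, cfg)
    eri <- compute_eri_table(ge, aggregate_expression(st$expr, st$meta, "region"))
    perm_map <- setNames(sample(cfg$regions$region_class),
                         cfg$regions$region)
    min(compare_region_classes(eri, perm_map)$p_value) < 0.05 / 8
  }, logical(1))
  # per-test level 0.05/8 across 8 lineages: family-wise rate near 0.05
  expect_lt(mean(reject), 0.15)
})
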