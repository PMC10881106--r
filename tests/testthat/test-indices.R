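# Expression-weighted indices: arithmetic, missingness contracts, oracle
# equivalence, invariances.

test_that("weighted index reproduces hand arithmetic", {
  expect_equal(weighted_index(c(0.1, 0.5), c(1, 3))$value, 0.4)
  # uniform weights give the arithmetic mean
  v <- c(0.2, 0.7, 1.1)
  expect_equal(weighted_index(v, rep(2, 3))$value, mean(v))
  # zero-weight entries are excluded
  wi <- weighted_index(c(0.3, 0.9), c(2, 0))
  expect_equal(wi$value, 0.3)
  expect_equal(wi$n_used, 1L)
  # missing values excluded pairwise
  wi2 <- weighted_index(c(NA, 0.4, 0.8), c(5, 1, 1))
  expect_equal(wi2$value, 0.6)
  expect_equal(wi2$n_used, 2L)
})

test_that("an all-zero-weight index is an error, never a silent NaN", {
  expect_error(weighted_index(c(0.1, 0.2), c(0, 0)),
               class = "evoindex_undefined_index")
  expect_error(weighted_index(c(NA_real_, NA_real_), c(1, 1)),
               class = "evoindex_undefined_index")
  expect_error(weighted_index(c(0.1), c(-1)),
               class = "evoindex_invalid_parameter")
  expect_error(weighted_index(c(0.1, 0.2), c(1)),
               class = "evoindex_invalid_parameter")
})

test_that("weighted index matches a naive loop on 1000 random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    v <- rgamma(n, 2, 4)
    v[runif(n) < 0.15] <- NA
    w <- rgamma(n, 1, 1)
    w[runif(n) < 0.1] <- 0
    oracle <- naive_weighted_index(v, w)
    if (oracle$n_used == 0 || !is.finite(oracle$value)) {
      expect_error(weighted_index(v, w), class = "evoindex_undefined_index")
    } else {
      got <- weighted_index(v, w)
      expect_equal(got$value, oracle$value, tolerance = 1e-12)
      expect_identical(got$n_used, oracle$n_used)
    }
  }
})

test_that("index tables match the brute-force double loop", {
  set.seed(55)
  dnds <- matrix(rgamma(6, 2, 6), 3, 2, dimnames = list(NULL, c("L1", "L2")))
  ge <- toy_gene_evo(dnds, age = c(5, 10, 60))
  ex <- toy_expr(matrix(rgamma(6, 2, 0.1), 3, 2,
                        dimnames = list(sprintf("g%d", 1:3), c("A", "B"))))
  eri <- compute_eri_table(ge, ex)
  oracle <- naive_index_table(ge, ex, "ERI")
  m <- match(paste(eri$group, eri$lineage), paste(oracle$group, oracle$lineage))
  expect_equal(eri$value, oracle$value[m], tolerance = 1e-12)
  expect_equal(eri$n_genes_used, oracle$n_genes_used[m])
  tai <- compute_tai_table(ge, ex)
  oracle_t <- naive_index_table(ge, ex, "TAI")
  expect_equal(tai$value, oracle_t$value[match(tai$group, oracle_t$group)],
               tolerance = 1e-12)
})

test_that("a gene missing dN/dS in one lineage cannot influence that lineage", {
  dnds <- matrix(c(0.1, 0.2, NA, 0.3, 0.1, 0.6), 3, 2,
                 dimnames = list(NULL, c("L1", "L2")))
  ge <- toy_gene_evo(dnds)
  ex_vals <- matrix(c(1, 1, 1e9), 3, 1,
                    dimnames = list(sprintf("g%d", 1:3), "A"))
  eri <- compute_eri_table(ge, toy_expr(ex_vals))
  # g3 has huge expression but missing L1: L1 value set by g1, g2 only
  expect_equal(eri$value[eri$lineage == "L1"], 0.15)
  expect_equal(eri$n_genes_used[eri$lineage == "L1"], 2L)
})

test_that("indices are invariant to rescaling the expression weights", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    v <- rgamma(n, 2, 5)
    w <- rgamma(n, 1, 0.01)
    c_scale <- runif(1, 1e-6, 1e6)
    expect_equal(weighted_index(v, c_scale * w)$value,
                 weighted_index(v, w)$value, tolerance = 1e-12)
  }
  # duplicating every group column leaves the table unchanged
  dnds <- matrix(rgamma(8, 2, 6), 4, 2, dimnames = list(NULL, c("L1", "L2")))
  ge <- toy_gene_evo(dnds)
  ex <- matrix(rgamma(8, 2, 0.1), 4, 2,
               dimnames = list(sprintf("g%d", 1:4), c("A", "B")))
  eri1 <- compute_eri_table(ge, toy_expr(ex))
  eri2 <- compute_eri_table(ge, toy_expr(2 * ex, genes = rownames(ex),
                                         samples = colnames(ex)))
  expect_equal(eri1$value, eri2$value, tolerance = 1e-12)
})

test_that("indices stay within the range of the retained values", {
  set.seed(88)
  for (i in 1:500) {
    n <- sample(2:25, 1)
    v <- c(rgamma(n, 1, 1), NA)
    w <- rgamma(n + 1, 1, 1)
    got <- weighted_index(v, w)$value
    expect_gte(got, min(v, na.rm = TRUE))
    expect_lte(got, max(v, na.rm = TRUE))
  }
})

test_that("TAI degenerates to the stratum age and is monotone in mass shifts", {
  ge <- toy_gene_evo(matrix(0.2, 3, 1, dimnames = list(NULL, "L1")),
                     age = c(20, 20, 20))
  ex <- toy_expr(matrix(c(1, 5, 3), 3, 1))
  expect_equal(compute_tai_table(ge, ex)$value, 20)
  # shifting weight from the oldest to the youngest gene lowers TAI
  ge2 <- toy_gene_evo(matrix(0.2, 2, 1, dimnames = list(NULL, "L1")),
                      age = c(64, 0))
  before <- compute_tai_table(ge2, toy_expr(matrix(c(5, 1), 2, 1)))$value
  after <- compute_tai_table(ge2, toy_expr(matrix(c(1, 5), 2, 1)))$value
  expect_lt(after, before)
  # and TAI always sits between min and max age over 100 random fixtures
  set.seed(9)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    a <- sample(c(0, 6.7, 9.1, 29.4, 64), n, replace = TRUE)
    gei <- toy_gene_evo(matrix(0.1, n, 1, dimnames = list(NULL, "L1")), age = a)
    exi <- toy_expr(matrix(rgamma(n, 1, 0.1), n, 1))
    tai <- compute_tai_table(gei, exi)$value
    eps <- 1e-9 * max(abs(a), 1)   # convexity bound up to float rounding
    expect_gte(tai, min(a) - eps)
    expect_lte(tai, max(a) + eps)
  }
})

test_that("per-sample mode and aggregate mode agree when weights balance", {
  # equal per-sample totals: the two computation orders coincide
  ge <- toy_gene_evo(matrix(c(0.1, 0.5), 2, 1, dimnames = list(NULL, "L1")))
  ex_vals <- matrix(c(1, 3, 3, 1), 2, 2,
                    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- toy_meta(c("s1", "s2"), "R1", "cortical")
  modes <- compare_index_modes(ge, toy_expr(ex_vals), meta)
  expect_equal(modes$difference, 0, tolerance = 1e-12)
  # unbalanced totals: a real discrepancy is measured and reported
  ex_vals2 <- matrix(c(1, 3, 30, 10), 2, 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
  modes2 <- compare_index_modes(ge, toy_expr(ex_vals2), meta)
  expect_gt(abs(modes2$difference), 0)
  expect_equal(modes2$per_sample_value,
               mean(c(weighted_index(c(0.1, 0.5), c(1, 3))$value,
                      weighted_index(c(0.1, 0.5), c(30, 10))$value)),
               tolerance = 1e-12)
})

test_that("per-sample bootstrap CIs bracket the group mean", {
  cfg <- sim_config(n_genes = 40, regions = generic_regions(1, 1),
                    n_samples_per_region = 8, seed = 13)
  st <- simulate_expression_study(simulate_gene_evo(cfg), cfg)
  ps <- per_sample_index(simulate_gene_evo(cfg), st$expr, st$meta,
                         kind = "ERI", n_boot = 200, seed = 4)
  expect_true(all(ps$ci_lo <= ps$value & ps$value <= ps$ci_hi))
  expect_equal(unique(ps$n_samples), 8L)
})
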