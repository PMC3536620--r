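test_that("spec validation errors name the offending field", {
  base <- list(n_regions = 4, groups = c(a = 4),
               module_membership = c(1L, 1L, 2L, 2L),
               factor_loadings = rep(1, 4))
  expect_error(synthetic_spec(4, c(a = 2),
                              base$module_membership, base$factor_loadings),
               "groups")
  expect_error(synthetic_spec(4, c(a = 4), base$module_membership,
                              base$factor_loadings, noise_sd = 0),
               "noise_sd")
  expect_error(synthetic_spec(4, c(a = 4), c(1L, 1L, 2L),
                              base$factor_loadings),
               "module_membership")
  expect_error(synthetic_spec(4, c(a = 4), base$module_membership,
                              base$factor_loadings, baseline_mean = -1),
               "baseline_mean")
  expect_error(synthetic_spec(4, c(a = 4), base$module_membership,
                              base$factor_loadings, negative_region = 9),
               "negative_region")
  expect_error(synthetic_spec(4, c(a = 4), base$module_membership,
                              base$factor_loadings, factor_correlation = 1),
               "factor_correlation")
})

test_that("noiseless rank-1 limit gives sample correlation 1", {
  spec <- synthetic_spec(
    n_regions = 2, groups = c(g = 8),
    module_membership = c(1L, 1L), factor_loadings = c(1, 1),
    noise_sd = 1e-8, baseline_mean = 100, rng_seed = 7)
  coh <- generate_cohort(spec)
  r <- pairwise_correlations(coh$g)$r
  expect_equal(r[1, 2], 1, tolerance = 1e-6)
})

test_that("within-module correlation converges to the planted closed form", {
  # lambda = 1, sigma = 1: expected r = 1/(1+1) = 0.5
  spec <- synthetic_spec(
    n_regions = 3, groups = c(g = 10000),
    module_membership = c(1L, 1L, 2L), factor_loadings = c(1, 1, 1),
    noise_sd = 1, baseline_mean = 100, rng_seed = 11)
  coh <- generate_cohort(spec)
  r <- pairwise_correlations(coh$g)$r
  expect_equal(r[1, 2], 0.5, tolerance = 0.02)
  # cross-module correlation converges to 0
  expect_lt(abs(r[1, 3]), 0.03)
})

test_that("unequal loadings follow lambda_i lambda_j normalization", {
  lam <- c(2, 0.8)
  expected <- prod(lam) / sqrt(prod(lam^2 + 1))
  spec <- synthetic_spec(
    n_regions = 2, groups = c(g = 10000),
    module_membership = c(1L, 1L), factor_loadings = lam,
    noise_sd = 1, baseline_mean = 100, rng_seed = 3)
  r <- pairwise_correlations(generate_cohort(spec)$g)$r
  expect_lt(abs(r[1, 2] - expected), 0.02)
  expect_equal(expected_correlations(spec)[1, 2], expected,
               tolerance = 1e-12)
})

test_that("the negative region attains the negated closed form", {
  spec <- synthetic_spec(
    n_regions = 3, groups = c(g = 10000),
    module_membership = c(1L, 1L, 1L), factor_loadings = c(1, 1, 1),
    noise_sd = 1, baseline_mean = 100, negative_region = 3, rng_seed = 5)
  r <- pairwise_correlations(generate_cohort(spec)$g)$r
  expect_equal(r[1, 2], 0.5, tolerance = 0.02)
  expect_equal(r[1, 3], -0.5, tolerance = 0.02)
  expect_equal(r[2, 3], -0.5, tolerance = 0.02)
})

test_that("a fixed seed reproduces the cohort exactly", {
  spec <- spec_modular(groups = c(a = 8, b = 8), seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  n1 <- generate_null_cohort(10, c(g = 5), seed = 9)
  n2 <- generate_null_cohort(10, c(g = 5), seed = 9)
  expect_identical(n1, n2)
})

test_that("null cohorts have no structure and no group effects", {
  coh <- generate_null_cohort(2, c(g = 1000), seed = 2)
  r <- pairwise_correlations(coh$g)$r
  expect_lt(abs(r[1, 2]), 0.1)
})

test_that("group effects shift the group means additively", {
  eff <- matrix(c(0, 0, 5, 0), nrow = 2, byrow = TRUE)
  spec <- synthetic_spec(
    n_regions = 2, groups = c(a = 2000, b = 2000),
    module_membership = c(0L, 0L), factor_loadings = c(0, 0),
    noise_sd = 1, baseline_mean = 20, group_effects = eff, rng_seed = 4)
  coh <- generate_cohort(spec)
  expect_equal(mean(coh$b$values[1, ]) - mean(coh$a$values[1, ]), 5,
               tolerance = 0.15)
  expect_equal(mean(coh$b$values[2, ]) - mean(coh$a$values[2, ]), 0,
               tolerance = 0.15)
})

test_that("generated values are truncated at zero", {
  spec <- synthetic_spec(
    n_regions = 4, groups = c(g = 200),
    module_membership = rep(1L, 4), factor_loadings = rep(3, 4),
    noise_sd = 1, baseline_mean = 0.5, rng_seed = 6)
  coh <- generate_cohort(spec)
  expect_true(all(coh$g$values >= 0))
  expect_true(any(coh$g$values == 0))   # truncation actually engaged
})

test_that("factor correlation plants the documented cross-module level", {
  # u = lambda/sqrt(lambda^2+1); cross r = u_i u_j rho
  spec <- synthetic_spec(
    n_regions = 2, groups = c(g = 10000),
    module_membership = c(1L, 2L), factor_loadings = c(2, 2),
    noise_sd = 1, baseline_mean = 100, factor_correlation = 0.5,
    rng_seed = 8)
  u <- 2 / sqrt(5)
  expect_equal(expected_correlations(spec)[1, 2], u^2 * 0.5,
               tolerance = 1e-12)
  r <- pairwise_correlations(generate_cohort(spec)$g)$r
  expect_equal(r[1, 2], u^2 * 0.5, tolerance = 0.03)
})

test_that("hub cross-loadings appear in the loading matrix", {
  spec <- synthetic_spec(
    n_regions = 4, groups = c(g = 4),
    module_membership = c(1L, 1L, 2L, 2L), factor_loadings = rep(2, 4),
    hub_set = 1L, hub_cross_loading = 0.7)
  lam <- loading_matrix(spec)
  expect_equal(lam[1, ], c(2, 0.7), ignore_attr = TRUE)
  expect_equal(lam[2, ], c(2, 0), ignore_attr = TRUE)
})
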