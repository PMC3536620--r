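# Task PLS and seed PLS with permutation and bootstrap inference.

two_cond <- function(m1, m2, regions = c("a", "b", "c")) {
  list(tiny_table(matrix(m1, length(regions), length(m1) / length(regions),
                         dimnames = list(regions, NULL)), "c1"),
       tiny_table(matrix(m2, length(regions), length(m2) / length(regions),
                         dimnames = list(regions, NULL)), "c2"))
}

test_that("identical condition means give a zero first singular value", {
  tabs <- two_cond(rep(10, 12), rep(10, 12))
  expect_equal(task_pls(tabs)$singular_values[1], 0, tolerance = 1e-12)
})

test_that("the 2x3 worked example yields s1 = 5*sqrt(2) on region 3", {
  v <- matrix(10, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  w <- v; w[3, ] <- 20
  fit <- task_pls(list(tiny_table(v, "ctrl"), tiny_table(w, "trained")))
  expect_equal(fit$singular_values[1], 5 * sqrt(2), tolerance = 1e-10)
  expect_equal(abs(fit$region_saliences[, 1]), c(a = 0, b = 0, c = 1),
               tolerance = 1e-10)
  # brute-force SVD oracle of the centered means [[0,0,-5],[0,0,5]]
  oracle <- svd(matrix(c(0, 0, 0, 0, -5, 5), 2, 3))
  expect_equal(fit$singular_values, oracle$d, tolerance = 1e-10)
})

test_that("condition order permutes design saliences consistently", {
  set.seed(1)
  m <- matrix(rnorm(4 * 10, 20), 4, 10,
              dimnames = list(letters[1:4], NULL))
  m2 <- m + 1.5
  t1 <- tiny_table(m, "c1"); t2 <- tiny_table(m2, "c2")
  f12 <- task_pls(list(t1, t2))
  f21 <- task_pls(list(t2, t1))
  expect_equal(abs(f12$design_saliences["c1", 1]),
               abs(f21$design_saliences["c1", 1]), tolerance = 1e-10)
  expect_equal(abs(f12$region_saliences[, 1]),
               abs(f21$region_saliences[, 1]), tolerance = 1e-10)
})

test_that("the SVD reconstructs the centered condition-mean matrix", {
  coh <- shifted_cohort(15, shift = 2, seed = 9)
  fit <- task_pls(coh)
  m <- rbind(rowMeans(coh[[1]]$values), rowMeans(coh[[2]]$values))
  mc <- sweep(m, 2, colMeans(m))
  rec <- fit$design_saliences %*% diag(fit$singular_values) %*%
    t(fit$region_saliences)
  expect_lt(max(abs(rec - mc)), 1e-10)
})

test_that("permutation p is reproducible and detects planted effects", {
  coh <- shifted_cohort(12, shift = 0, seed = 3)
  p1 <- permutation_test_lvs(coh, n_perm = 100, seed = 11)
  p2 <- permutation_test_lvs(coh, n_perm = 100, seed = 11)
  expect_identical(p1, p2)
  hits <- vapply(1:20, function(s) {
    coh <- shifted_cohort(12, shift = 3, shifted = 1:10, seed = 100 + s)
    permutation_test_lvs(coh, n_perm = 200, seed = s)[1] <= 0.01
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("bootstrap ratios flag planted regions and spare null ones", {
  flagged <- vapply(1:20, function(s) {
    coh <- shifted_cohort(12, shift = 3, shifted = 1:4, seed = 200 + s)
    bsr <- bootstrap_salience_ratios(coh, n_boot = 200, seed = s)
    all(bsr$reliable[1:4, 1])
  }, logical(1))
  expect_gte(sum(flagged), 16)
  null_rate <- vapply(1:10, function(s) {
    coh <- shifted_cohort(12, shift = 0, seed = 400 + s)
    bsr <- bootstrap_salience_ratios(coh, n_boot = 200, seed = s)
    mean(abs(bsr$bsr[, 1]) >= 3)
  }, numeric(1))
  expect_lte(mean(null_rate), 0.05)
  b1 <- bootstrap_salience_ratios(shifted_cohort(8, seed = 5),
                                  n_boot = 100, seed = 2)
  b2 <- bootstrap_salience_ratios(shifted_cohort(8, seed = 5),
                                  n_boot = 100, seed = 2)
  expect_identical(b1, b2)
})

test_that("seed PLS concentrates salience on the coupled region set", {
  # one condition, one seed; seed correlated with regions 2-3 only
  spec <- synthetic_spec(
    n_regions = 6, groups = c(g = 30),
    module_membership = c(1L, 1L, 1L, 0L, 0L, 0L),
    factor_loadings = c(4, 4, 4, 0, 0, 0),
    noise_sd = 1, baseline_mean = 50, rng_seed = 13)
  tb <- generate_cohort(spec)$g
  fit <- seed_pls(list(tb), seeds = "R001")
  sal <- abs(fit$region_saliences[, 1])
  expect_true(all(sal[1:3] > 0.4))
  expect_true(all(sal[4:6] < 0.25))
})

test_that("identical conditions give a near-zero second seed-PLS LV", {
  tb <- generate_cohort(synthetic_spec(
    n_regions = 5, groups = c(g = 8),
    module_membership = rep(1L, 5), factor_loadings = rep(2, 5),
    noise_sd = 1, baseline_mean = 30, rng_seed = 17))$g
  tb2 <- tb; tb2$group_label <- "copy"
  fit <- seed_pls(list(tb, tb2), seeds = "R001")
  expect_lt(fit$singular_values[2] / fit$singular_values[1], 1e-10)
})

test_that("a zero-variance seed names the seed and condition", {
  m <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("s", "t"), NULL))
  tb <- tiny_table(m, "ctrl")
  expect_error(seed_pls(list(tb), seeds = "s"), "s.*ctrl")
})

test_that("condition-specific seed coupling is detected by permutation", {
  hits <- vapply(1:20, function(s) {
    spec <- synthetic_spec(
      n_regions = 8, groups = c(g = 8),
      module_membership = c(rep(1L, 4), rep(0L, 4)),
      factor_loadings = c(rep(3, 4), rep(0, 4)),
      noise_sd = 1, baseline_mean = 50, rng_seed = 500 + s)
    trained <- generate_cohort(spec)$g
    control <- generate_null_cohort(8, c(ctrl = 8), seed = 800 + s)$ctrl
    control$regions <- trained$regions
    rownames(control$values) <- trained$regions
    # with two stacked correlation maps, the leading LV carries the map
    # shared by both conditions (dominated by the seed's self-correlation)
    # and the second LV the condition-specific coupling; permuting the
    # condition assignment collapses the latter
    p <- permutation_test_lvs(list(trained, control), n_perm = 500,
                              seed = s, seeds = "R001")
    p[2] <= 0.01
  }, logical(1))
  expect_gte(sum(hits), 18)
})
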