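# Correlation census, thresholds, network construction, and matrix-level
# comparisons.

make_corr <- function(r, n = 8, regions = NULL) {
  # correlation_matrix fixture from a raw symmetric matrix
  if (is.null(regions)) regions <- LETTERS[seq_len(nrow(r))]
  dimnames(r) <- list(regions, regions)
  structure(list(method = "pearson", n_subjects = n, r = r,
                 defined = matrix(TRUE, nrow(r), ncol(r),
                                  dimnames = dimnames(r)),
                 regions = regions, group_label = "fixture"),
            class = "correlation_matrix")
}

test_that("pearson coefficients match hand-computed examples", {
  m <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8), z = c(1, 3, 2, 4))
  corr <- pairwise_correlations(tiny_table(m))
  expect_equal(corr$r["x", "y"], 1)
  expect_equal(corr$r["x", "z"], 0.8)
  expect_error(pairwise_correlations(tiny_table(m[, 1:2])), "3 subjects")
})

test_that("spearman uses average ranks for ties", {
  m <- rbind(a = c(1, 2, 2, 5), b = c(3, 1, 4, 6))
  corr <- pairwise_correlations(tiny_table(m), method = "spearman")
  # ranks of a = (1, 2.5, 2.5, 4); of b = (2, 1, 3, 4)
  expect_equal(corr$r["a", "b"],
               cor(c(1, 2.5, 2.5, 4), c(2, 1, 3, 4)))
})

test_that("zero-variance regions are flagged undefined, not errors", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  corr <- pairwise_correlations(tiny_table(m))
  expect_false(corr$defined["a", "b"])
  expect_true(is.na(corr$r["a", "b"]))
  expect_true(corr$defined["a", "c"])
  net <- build_network(corr, threshold_spec(0.005, 4))
  expect_equal(igraph::degree(net$graph)[["b"]], 0)
})

test_that("critical r inverts the exact t transform", {
  expect_equal(round(critical_r(0.005, 8), 4), 0.8343)
  expect_equal(round(critical_r(0.0025, 8), 4), 0.8697)
  expect_equal(round(critical_r(0.01, 8), 4), 0.7887)
  expect_error(critical_r(0.6, 8), "alpha")
  expect_error(critical_r(0.005, 2), "n")
  # round trip: one-tailed p of r_crit equals alpha to 6 decimals
  for (alpha in c(0.05, 0.01, 0.005, 0.0025)) for (n in c(5, 8, 12)) {
    rc <- critical_r(alpha, n)
    t <- rc * sqrt((n - 2) / (1 - rc^2))
    expect_equal(1 - pt(t, n - 2), alpha, tolerance = 1e-6)
  }
})

test_that("thresholding keeps positive supra-threshold edges only", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- -0.95
  net <- build_network(make_corr(r), threshold_spec(0.005, 8))
  el <- igraph::as_edgelist(net$graph)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("A", "B"))
  expect_equal(igraph::E(net$graph)$weight, 0.9)
})

test_that("the threshold boundary is inclusive and nodes are kept", {
  rc <- critical_r(0.005, 8)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- rc          # exactly at the threshold
  r[1, 3] <- r[3, 1] <- rc - 1e-9   # just below
  net <- build_network(make_corr(r), threshold_spec(0.005, 8))
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::vcount(net$graph), 3)
  # all sub-threshold: zero edges, full node set
  net0 <- build_network(make_corr(diag(3)), threshold_spec(0.005, 8))
  expect_equal(igraph::ecount(net0$graph), 0)
  expect_equal(igraph::vcount(net0$graph), 3)
})

test_that("subject-count mismatch between matrix and threshold errors", {
  expect_error(build_network(make_corr(diag(3), n = 8),
                             threshold_spec(0.005, 9)),
               "does not match")
})

test_that("edge count is monotone non-increasing in the threshold", {
  coh <- generate_cohort(spec_modular(groups = c(g = 8), seed = 3))
  corr <- pairwise_correlations(coh$g)
  counts <- vapply(c(0.01, 0.005, 0.0025), function(a) {
    igraph::ecount(build_network(corr, threshold_spec(a, 8))$graph)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("null cohorts survive the threshold at the nominal rate", {
  rc <- critical_r(0.005, 8)
  frac <- vapply(1:200, function(s) {
    coh <- generate_null_cohort(30, c(g = 8), seed = 1000 + s)
    r <- pairwise_correlations(coh$g)$r
    mean(r[upper.tri(r)] >= rc)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.005), 0.002)
})

test_that("block mean contrasts behave on degenerate and simple blocks", {
  coh <- generate_cohort(spec_modular(n_modules = 2, module_size = 4,
                                      n_background = 0,
                                      groups = c(g = 8), seed = 5))
  tb <- coh$g
  same <- block_mean_contrast(tb, tb, rows = 1:4, cols = 1:4,
                              n_boot = 200, seed = 1)
  expect_equal(same$difference, 0)
  expect_false(same$reliably_different)
  single <- block_mean_contrast(tb, tb, rows = "R001", cols = "R002",
                                n_boot = 100, seed = 1)
  r12 <- pairwise_correlations(tb)$r["R001", "R002"]
  expect_equal(single$mean_a, r12)
  expect_equal(single$n_pairs, 1)
  expect_error(block_mean_contrast(tb, tb, rows = "R001", cols = "R001"),
               "no valid region pairs")
})

test_that("a planted block difference is reliably detected", {
  # block correlation 0.6 vs 0: lambda^2/(lambda^2+1) = 0.6
  lam <- sqrt(1.5)
  out <- vapply(1:20, function(s) {
    spec <- synthetic_spec(
      n_regions = 6, groups = c(g = 8),
      module_membership = rep(1L, 6), factor_loadings = rep(lam, 6),
      noise_sd = 1, baseline_mean = 30, rng_seed = 300 + s)
    ta <- generate_cohort(spec)$g
    tb <- generate_null_cohort(6, c(g = 8), seed = 600 + s)$g
    ct <- block_mean_contrast(ta, tb, rows = 1:6, cols = 1:6,
                              n_boot = 1000, seed = s)
    c(positive = ct$difference > 0, flag = ct$reliably_different)
  }, logical(2))
  # the point estimate recovers the planted direction essentially always;
  # the bootstrap CI flag fires in a clear majority (n = 8 subjects keeps
  # the percentile CI of a block-mean difference wide)
  expect_gte(sum(out["positive", ]), 19)
  expect_gte(sum(out["flag", ] & out["positive", ]), 12)
})

test_that("comparing a table with itself finds no significant pairs", {
  coh <- generate_null_cohort(6, c(a = 5, b = 5), seed = 12)
  res <- compare_matrices_permutation(coh$a, coh$a, n_perm = 200,
                                      seed = 1)
  expect_equal(nrow(res$significant), 0)
})

test_that("permutation p matches the exact 70-split enumeration oracle", {
  # 4+4 subjects, 3 regions; pair (1,2) strongly correlated in A only
  # regions share baseline and variance across tables so mixed relabelled
  # groups behave as genuine nulls
  spec <- synthetic_spec(
    n_regions = 3, groups = c(g = 4),
    module_membership = c(1L, 1L, 2L), factor_loadings = c(3, 3, 3),
    noise_sd = 1, baseline_mean = 100, rng_seed = 21)
  ta <- generate_cohort(spec)$g
  tb <- generate_null_cohort(3, c(g = 4), noise_sd = sqrt(10), seed = 22,
                             baseline_mean = 100)$g
  pooled <- cbind(ta$values, tb$values)
  up <- upper.tri(diag(3))
  splits <- combn(8, 4)
  obs <- (cor(t(ta$values)) - cor(t(tb$values)))[up]
  exact <- rowMeans(apply(splits, 2, function(cols) {
    st <- (cor(t(pooled[, cols])) - cor(t(pooled[, -cols])))[up]
    ifelse(obs >= 0, st >= obs, st <= obs)
  }))
  res <- compare_matrices_permutation(ta, tb, n_perm = 12000,
                                      fdr_q = 0.05, seed = 7)
  expect_lt(max(abs(res$pairs$p - exact)), 0.02)
  # the planted pair is the unique BH discovery at the 5% level
  expect_identical(
    paste(res$significant$region_a, res$significant$region_b),
    "R001 R002")
  expect_identical(res$significant$direction, "A>B")
})

test_that("mean degree vs threshold reproduces worked curves", {
  ones <- matrix(1, 3, 3)
  expect_equal(
    mean_degree_vs_threshold(make_corr(ones), 0.9)$mean_degree_proportion,
    1)
  expect_equal(
    mean_degree_vs_threshold(make_corr(diag(3)),
                             0.5)$mean_degree_proportion, 0)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.85
  r[2, 3] <- r[3, 2] <- 0.5
  out <- mean_degree_vs_threshold(make_corr(r), c(0.5, 0.83))
  expect_equal(out$mean_degree_proportion[2], mean(c(1, 0.5, 0.5)))
  expect_true(all(diff(out$mean_degree_proportion) <= 0))
  expect_error(mean_degree_vs_threshold(make_corr(r), c(0.9, 0.1)),
               "ascending")
})
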