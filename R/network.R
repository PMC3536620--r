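# Correlation matrices, significance thresholds, thresholded functional
# networks, and matrix-level group comparisons.

#' All pairwise inter-regional correlations of one group
#'
#' Computes the R(R-1)/2 unique correlation coefficients across subjects.
#' Spearman correlations use average ranks for ties. Regions with zero
#' variance yield flagged-undefined entries rather than errors.
#'
#' @param table An [activity_table()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `correlation_matrix` object: list with `method`, `n_subjects`,
#'   `r` (symmetric matrix, diagonal 1), `defined` (logical matrix, FALSE
#'   where either region had zero variance) and `regions`.
#' @export
pairwise_correlations <- function(table, method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "activity_table"))
  method <- match.arg(method)
  n <- length(table$subjects)
  if (n < 3L)
    stop("correlations need at least 3 subjects; got ", n)
  x <- t(table$values)
  sds <- apply(x, 2L, sd)
  ok <- sds > 0
  r <- suppressWarnings(cor(x, method = method))
  defined <- outer(ok, ok, `&`)
  r[!defined] <- NA_real_
  diag(r) <- 1
  structure(
    list(method = method, n_subjects = n, r = r,
         defined = defined, regions = table$regions,
         group_label = table$group_label),
    class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf(
    "Correlation matrix (%s, n = %d): %d regions, %d unique pairs\n",
    x$method, x$n_subjects, length(x$regions),
    choose(length(x$regions), 2)))
  invisible(x)
}

#' Critical correlation for a one-tailed significance level
#'
#' Inverts the exact t-to-r transform: `r_crit = t / sqrt(t^2 + df)` with
#' `t` the upper-`alpha` quantile of the t distribution on `df = n - 2`
#' degrees of freedom. At n = 8 this gives 0.8343 (alpha 0.005), 0.8697
#' (0.0025) and 0.7887 (0.01), the standard one-tailed thresholds for
#' eight-subject IEG cohorts.
#'
#' @param alpha One-tailed significance level, in (0, 0.5).
#' @param n Number of subjects (>= 3).
#' @return The critical r.
#' @export
#' @examples
#' critical_r(0.005, 8)  # 0.8343
critical_r <- function(alpha, n) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be a one-tailed level in (0, 0.5)")
  if (!is_count(n, 3L)) stop("'n' must be a subject count >= 3")
  df <- n - 2
  tc <- qt(1 - alpha, df)
  tc / sqrt(tc^2 + df)
}

#' Threshold specification for network construction
#'
#' @param alpha One-tailed level.
#' @param n Number of subjects the correlations were computed from.
#' @param tier Label: `"low"`, `"primary"` or `"high"` confidence.
#' @return A `threshold_spec` with the derived `r_crit`.
#' @export
threshold_spec <- function(alpha, n, tier = c("primary", "low", "high")) {
  tier <- match.arg(tier)
  structure(
    list(alpha = alpha, n = as.integer(n), df = as.integer(n - 2),
         r_crit = critical_r(alpha, n), tier = tier),
    class = "threshold_spec")
}

#' The three standard confidence tiers
#'
#' Low (alpha 0.01, r >= 0.7887 at n = 8), primary (0.005, 0.8343) and high
#' (0.0025, 0.8697) one-tailed tiers.
#'
#' @param n Number of subjects.
#' @return Named list of [threshold_spec()] objects.
#' @export
standard_tiers <- function(n = 8) {
  list(low = threshold_spec(0.01, n, "low"),
       primary = threshold_spec(0.005, n, "primary"),
       high = threshold_spec(0.0025, n, "high"))
}

#' Wrap an igraph object as a functional network
#'
#' Mostly used to build fixture networks in examples and tests; analysis
#' networks come from [build_network()].
#'
#' @param graph An undirected igraph object (vertices named) or a symmetric
#'   adjacency matrix.
#' @param r_crit,tier,n_subjects Optional threshold metadata.
#' @return A `functional_network`.
#' @export
functional_network <- function(graph, r_crit = NA_real_, tier = NA_character_,
                               n_subjects = NA_integer_) {
  if (is.matrix(graph))
    graph <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                                 weighted = TRUE)
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph))
    stop("functional networks are undirected")
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- sprintf("R%03d", seq_len(igraph::vcount(graph)))
  structure(
    list(graph = graph, regions = igraph::V(graph)$name,
         r_crit = r_crit, tier = tier, n_subjects = n_subjects),
    class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(
    "Functional network (%s tier, r_crit %s): %d nodes, %d edges, %d active\n",
    x$tier %||% NA, format(x$r_crit, digits = 4),
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    sum(igraph::degree(x$graph) >= 1)))
  invisible(x)
}

#' Build a functional network by thresholding a correlation matrix
#'
#' Edges connect region pairs whose defined correlation is at least
#' `r_crit` (inclusive); negative and undefined correlations never form
#' edges. All R regions stay in the node set, so nodes may be inactive
#' (degree 0). Edge weights carry the correlation.
#'
#' @param corr A [pairwise_correlations()] result.
#' @param thr A [threshold_spec()]; its `n` must match the matrix.
#' @return A `functional_network`.
#' @export
build_network <- function(corr, thr) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(thr, "threshold_spec"))
  if (thr$n != corr$n_subjects)
    stop(sprintf("threshold n (%d) does not match correlation n (%d)",
                 thr$n, corr$n_subjects))
  r <- corr$r
  adj <- !is.na(r) & corr$defined & r >= thr$r_crit
  diag(adj) <- FALSE
  w <- r
  w[!adj] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  net <- functional_network(g, r_crit = thr$r_crit, tier = thr$tier,
                            n_subjects = corr$n_subjects)
  net
}

# Region indices for a set given as names or indices.
.region_idx <- function(regions, set) {
  if (is.character(set)) {
    idx <- match(set, regions)
    if (anyNA(idx)) stop("unknown region: ", set[is.na(idx)][1L])
    idx
  } else as.integer(set)
}

# Unique unordered region pairs of a block (rows x cols), excluding self
# pairs; when rows == cols this is the unique off-diagonal set.
.block_pairs <- function(regions, rows, cols) {
  ri <- .region_idx(regions, rows)
  ci <- .region_idx(regions, cols)
  pairs <- expand.grid(i = ri, j = ci)
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  as.matrix(pairs)
}

#' Bootstrap contrast of block mean correlations between two groups
#'
#' Computes the mean correlation over a block of region pairs (e.g.
#' hippocampus x neocortex) in each group, then bootstraps subjects with
#' replacement within each group to get the 95% confidence interval of the
#' difference in block means. A difference is flagged reliable when the
#' interval excludes zero.
#'
#' @param table_a,table_b [activity_table()] objects sharing the block's
#'   regions.
#' @param rows,cols Region sets (names or indices) defining the block; with
#'   `rows == cols` only unique off-diagonal pairs enter the mean.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @param method Correlation method.
#' @return List with `mean_a`, `mean_b`, `difference`, `ci` (2.5/97.5
#'   percentiles of the bootstrapped difference), `reliably_different`,
#'   `n_pairs` and `n_boot`.
#' @export
block_mean_contrast <- function(table_a, table_b, rows, cols,
                                n_boot = 1000, seed = NULL,
                                method = "pearson") {
  stopifnot(inherits(table_a, "activity_table"),
            inherits(table_b, "activity_table"))
  pairs <- .block_pairs(table_a$regions, rows, cols)
  if (nrow(pairs) == 0L)
    stop("block contains no valid region pairs")
  block_mean <- function(values) {
    r <- suppressWarnings(cor(t(values), method = method))
    mean(r[pairs], na.rm = TRUE)
  }
  ma <- block_mean(table_a$values)
  mb <- block_mean(table_b$values)
  if (is.nan(ma) || is.nan(mb))
    stop("block contains no defined correlations")
  na <- length(table_a$subjects); nb <- length(table_b$subjects)
  with_rng(seed, {
    boot_a <- replicate(n_boot, block_mean(
      table_a$values[, sample.int(na, na, replace = TRUE), drop = FALSE]))
    boot_b <- replicate(n_boot, block_mean(
      table_b$values[, sample.int(nb, nb, replace = TRUE), drop = FALSE]))
    d <- boot_a - boot_b
    ci <- unname(quantile(d, c(0.025, 0.975), na.rm = TRUE))
    list(mean_a = ma, mean_b = mb, difference = ma - mb, ci = ci,
         reliably_different = (ci[1L] > 0 || ci[2L] < 0),
         n_pairs = nrow(pairs), n_boot = n_boot)
  })
}

#' Permutation comparison of two correlation matrices
#'
#' For every unique region pair the statistic is `r_A - r_B`. The null is
#' generated by shuffling subject-to-group labels (pooling the subjects of
#' both groups and reassigning them at the original group sizes) and
#' recomputing the statistic. The p-value counts exceedances in the observed
#' direction with the add-one convention,
#' `p = (#{perm stat at least as extreme as obs, same sign} + 1) / (n_perm + 1)`,
#' so a permutation p is never exactly zero; p-values are corrected by
#' Benjamini-Hochberg step-up over all pairs. Pairs whose statistic is
#' undefined under any permutation (a zero-variance region in some
#' relabelling) are dropped with a warning.
#'
#' @param table_a,table_b [activity_table()] objects over the same regions.
#' @param n_perm Number of permutations (>= 100).
#' @param fdr_q FDR level for the BH correction.
#' @param seed Optional RNG seed.
#' @param method Correlation method.
#' @return List with `pairs` (data frame over all retained pairs:
#'   `region_a`, `region_b`, `r_a`, `r_b`, `stat`, `p`, `q`, `significant`,
#'   `direction` with `"A>B"`/`"B>A"`), `significant` (the significant
#'   subset), `n_perm`, `fdr_q` and `n_dropped`.
#' @export
compare_matrices_permutation <- function(table_a, table_b, n_perm = 1000,
                                         fdr_q = 0.05, seed = NULL,
                                         method = "pearson") {
  stopifnot(inherits(table_a, "activity_table"),
            inherits(table_b, "activity_table"))
  if (!identical(table_a$regions, table_b$regions))
    stop("the two tables must share an identical region set and order")
  if (!is_count(n_perm, 100L))
    stop("'n_perm' must be a count >= 100")
  regs <- table_a$regions
  na <- length(table_a$subjects); nb <- length(table_b$subjects)
  pooled <- cbind(table_a$values, table_b$values)
  up <- upper.tri(diag(length(regs)))
  pair_stat <- function(cols_a) {
    ra <- suppressWarnings(cor(t(pooled[, cols_a, drop = FALSE]),
                               method = method))
    rb <- suppressWarnings(cor(t(pooled[, -cols_a, drop = FALSE]),
                               method = method))
    (ra - rb)[up]
  }
  ra_full <- suppressWarnings(cor(t(table_a$values), method = method))
  rb_full <- suppressWarnings(cor(t(table_b$values), method = method))
  obs <- (ra_full - rb_full)[up]
  count <- integer(length(obs))
  undef <- is.na(obs)
  with_rng(seed, {
    for (p in seq_len(n_perm)) {
      st <- pair_stat(sample.int(na + nb, na))
      undef <- undef | is.na(st)
      exceed <- ifelse(obs >= 0, st >= obs, st <= obs)
      count <- count + (!is.na(st) & exceed)
    }
  })
  pval <- (count + 1) / (n_perm + 1)
  ij <- which(up, arr.ind = TRUE)
  keep <- !undef
  if (any(undef))
    warning(sum(undef), " pair(s) dropped: undefined correlation under ",
            "some permutation")
  df <- data.frame(
    region_a = regs[ij[keep, 1L]],
    region_b = regs[ij[keep, 2L]],
    r_a = ra_full[up][keep],
    r_b = rb_full[up][keep],
    stat = obs[keep],
    p = pval[keep],
    stringsAsFactors = FALSE)
  df$q <- stats::p.adjust(df$p, method = "BH")
  df$significant <- df$q <= fdr_q
  df$direction <- ifelse(df$stat > 0, "A>B", "B>A")
  list(pairs = df,
       significant = df[df$significant, , drop = FALSE],
       n_perm = n_perm, fdr_q = fdr_q, n_dropped = sum(undef))
}

#' Mean per-node connection proportion across thresholds
#'
#' For each threshold r, every node's degree K (number of defined
#' correlations >= r with other regions) is expressed as a proportion of
#' its possible connections (R - 1) and averaged over nodes. The curve is
#' non-increasing in r.
#'
#' @param corr A [pairwise_correlations()] result.
#' @param thresholds Ascending numeric vector of correlation thresholds.
#' @return Data frame with columns `threshold` and `mean_degree_proportion`.
#' @export
mean_degree_vs_threshold <- function(corr, thresholds) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (is.unsorted(thresholds))
    stop("'thresholds' must be ascending")
  r <- corr$r
  diag(r) <- NA_real_
  R <- length(corr$regions)
  prop <- vapply(thresholds, function(th) {
    k <- rowSums(!is.na(r) & r >= th)
    mean(k / (R - 1))
  }, numeric(1))
  data.frame(threshold = thresholds, mean_degree_proportion = prop)
}
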