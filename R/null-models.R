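# Degree-matched random network ensembles and subject-bootstrap confidence
# intervals. Null networks share the observed network's node set, edge
# count and full degree sequence; they are produced by repeated double-edge
# swaps, the standard degree-preserving randomization.

#' Degree-preserving rewiring by double-edge swaps
#'
#' Attempts `swap_factor * |E|` swaps; each swap picks two disjoint edges
#' (a,b), (c,d) and replaces them with (a,d), (c,b) when the result stays a
#' simple graph. Every node's degree is unchanged. Graphs with no feasible
#' swap (e.g. a triangle) are returned unchanged.
#'
#' @param net A [functional_network()].
#' @param swap_factor Attempted swaps per edge (default 10, a standard
#'   mixing heuristic).
#' @param seed Optional RNG seed.
#' @return A rewired `functional_network` (edge weights are dropped: null
#'   networks are topological controls).
#' @export
rewire_preserving_degree <- function(net, swap_factor = 10, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  g <- net$graph
  if (igraph::ecount(g) < 2L) return(net)
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  with_rng(seed, {
    gr <- igraph::rewire(
      g,
      igraph::keeping_degseq(loops = FALSE,
                             niter = ceiling(swap_factor *
                                             igraph::ecount(g))))
    functional_network(gr, r_crit = net$r_crit, tier = net$tier,
                       n_subjects = net$n_subjects)
  })
}

#' Null distribution of a metric over a degree-matched ensemble
#'
#' Generates `ensemble_size` independent rewired realizations of the
#' network and evaluates the metric on each.
#'
#' @param net A [functional_network()].
#' @param metric One of [network_metrics()].
#' @param ensemble_size Ensemble size (default 1000).
#' @param swap_factor Passed to [rewire_preserving_degree()].
#' @param seed Optional RNG seed.
#' @return A `null_ensemble_summary`: list with `metric`, `ensemble_size`,
#'   `ensemble_mean`, `interval95` (2.5th/97.5th percentiles) and the
#'   per-realization `values`.
#' @export
null_distribution <- function(net, metric, ensemble_size = 1000,
                              swap_factor = 10, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  f <- .metric_fun(metric)
  vals <- with_rng(seed, {
    vapply(seq_len(ensemble_size), function(i) {
      f(rewire_preserving_degree(net, swap_factor = swap_factor))
    }, numeric(1))
  })
  n_bad <- sum(is.na(vals))
  if (n_bad > 0.1 * ensemble_size)
    stop(sprintf("metric '%s' undefined on %d of %d null realizations",
                 metric, n_bad, ensemble_size))
  structure(
    list(metric = metric, ensemble_size = ensemble_size,
         ensemble_mean = mean(vals, na.rm = TRUE),
         interval95 = unname(quantile(vals, c(0.025, 0.975),
                                      na.rm = TRUE)),
         values = vals),
    class = "null_ensemble_summary")
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Null ensemble (%d degree-matched networks): %s = %.4f [%.4f, %.4f]\n",
    x$ensemble_size, x$metric, x$ensemble_mean,
    x$interval95[1L], x$interval95[2L]))
  invisible(x)
}

#' Subject-bootstrap confidence interval for a network metric
#'
#' Each replicate resamples subjects with replacement, recomputes the
#' correlation matrix, re-thresholds at the original `r_crit` (the
#' threshold stays fixed at the original-n value) and recomputes the
#' metric. The point value comes from the original table; the CI from the
#' replicate 2.5/97.5 percentiles. Replicates yielding a network with no
#' active nodes (or an undefined metric) are excluded and counted.
#'
#' @param table An [activity_table()].
#' @param thr A [threshold_spec()].
#' @param metric One of [network_metrics()].
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Optional RNG seed.
#' @param method Correlation method.
#' @return A `metric_estimate`: list with `metric`, `value`, `ci95`,
#'   `n_boot`, `n_degenerate`.
#' @export
bootstrap_network_metric <- function(table, thr, metric, n_boot = 1000,
                                     seed = NULL, method = "pearson") {
  stopifnot(inherits(table, "activity_table"),
            inherits(thr, "threshold_spec"))
  if (!is_count(n_boot, 100L)) stop("'n_boot' must be a count >= 100")
  f <- .metric_fun(metric)
  point <- f(build_network(pairwise_correlations(table, method), thr))
  n <- length(table$subjects)
  reps <- with_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- activity_table(
        table$values[, idx, drop = FALSE], table$group_label)
      corr <- pairwise_correlations(tb, method)
      net <- build_network(corr, thr)
      if (length(active_nodes(net)) == 0L) return(NA_real_)
      tryCatch(f(net), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_deg <- sum(is.na(reps))
  if (n_deg > 0.5 * n_boot)
    stop(sprintf("%d of %d bootstrap replicates degenerate", n_deg, n_boot))
  structure(
    list(metric = metric, value = point,
         ci95 = unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE)),
         n_boot = n_boot, n_degenerate = n_deg),
    class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f, bootstrap 95%% CI [%.4f, %.4f] (%d reps, %d degenerate)\n",
              x$metric, x$value, x$ci95[1L], x$ci95[2L],
              x$n_boot, x$n_degenerate))
  invisible(x)
}
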