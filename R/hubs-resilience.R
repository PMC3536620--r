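# Hub identification across threshold tiers and resilience to sequential
# node attack.

# Percentile of each value among active nodes: fraction of active nodes
# with a strictly lower value, x100. Ties share a percentile, so a
# degree-regular network has every node at percentile 0.
.strict_percentile <- function(v) {
  100 * (rank(v, ties.method = "min") - 1) / length(v)
}

#' Identify candidate hub regions across threshold tiers
#'
#' Active nodes of every tier's network are ranked by degree and by
#' betweenness; the hub set contains the regions above the cutoff
#' percentile in *both* measures in *all* tiers. Inactive nodes are
#' excluded from ranking.
#'
#' @param nets Named list of [functional_network()] objects (one per tier)
#'   sharing a node set.
#' @param cutoff_percentile Percentile cutoff (default 80; hubs must exceed
#'   it strictly).
#' @return A `hub_report`: list with `hub_set` (character vector) and
#'   `tiers`, a per-tier data frame of degree, betweenness and their
#'   percentiles over active nodes.
#' @export
identify_hubs <- function(nets, cutoff_percentile = 80) {
  stopifnot(is.list(nets), length(nets) >= 1L)
  regions <- nets[[1L]]$regions
  for (net in nets) {
    stopifnot(inherits(net, "functional_network"))
    if (!setequal(net$regions, regions))
      stop("all tiers must share the same node set")
    if (igraph::ecount(net$graph) == 0L)
      stop("empty network in a tier: no edges to rank")
  }
  tier_tables <- lapply(nets, function(net) {
    cm <- centrality_measures(net)
    act <- cm$degree >= 1
    tab <- cm[act, , drop = FALSE]
    tab$degree_percentile <- .strict_percentile(tab$degree)
    tab$betweenness_percentile <- .strict_percentile(tab$betweenness)
    tab$hub <- tab$degree_percentile > cutoff_percentile &
      tab$betweenness_percentile > cutoff_percentile
    tab
  })
  hub_set <- Reduce(intersect,
                    lapply(tier_tables, function(t) t$region[t$hub]))
  structure(
    list(hub_set = hub_set, tiers = tier_tables,
         cutoff_percentile = cutoff_percentile),
    class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub report (> %gth percentile in degree AND betweenness, all %d tiers)\n",
              x$cutoff_percentile, length(x$tiers)))
  cat("hubs:", if (length(x$hub_set)) paste(x$hub_set, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# Largest-component sizes along one removal order (active-node indices of
# g, in removal order). Returns sizes after 0..length(order) removals.
.attack_sizes <- function(g, order) {
  sizes <- numeric(length(order) + 1L)
  sizes[1L] <- max(igraph::components(g)$csize)
  remaining <- g
  for (k in seq_along(order)) {
    remaining <- igraph::delete_vertices(remaining, as.character(order[k]))
    sizes[k + 1L] <- if (igraph::vcount(remaining) == 0L) 0
                     else max(igraph::components(remaining)$csize)
  }
  sizes
}

#' Simulate sequential node attack
#'
#' Active nodes are removed one at a time and the largest connected
#' component re-measured after every removal, expressed as a proportion of
#' the original largest component. Targeted attack removes nodes in
#' descending order of their *original* degree (static order; ties broken
#' by region order, i.e. matrix index). Random attack removes nodes
#' uniformly without replacement and averages the curve over `n_reps`
#' repetitions.
#'
#' @param net A [functional_network()] with at least one active node.
#' @param mode `"targeted"` or `"random"`.
#' @param n_reps Repetitions for random mode (default 100).
#' @param seed Optional RNG seed (random mode).
#' @return An `attack_curve`: list with `mode`, `points` (data frame:
#'   `n_removed`, `frac_removed`, `size` = mean largest-component size,
#'   `proportion` of the original largest component), `largest0`,
#'   `n_active`, `n_reps`, and for random mode the per-rep size matrix
#'   `reps`.
#' @export
attack_simulation <- function(net, mode = c("targeted", "random"),
                              n_reps = 100, seed = NULL) {
  stopifnot(inherits(net, "functional_network"))
  mode <- match.arg(mode)
  g <- net$graph
  deg <- igraph::degree(g)
  act <- which(deg >= 1)
  if (length(act) == 0L) stop("network has no active node")
  sub <- igraph::induced_subgraph(g, act)
  sdeg <- igraph::degree(sub)
  nm <- igraph::V(sub)$name
  largest0 <- max(igraph::components(sub)$csize)
  reps_mat <- NULL
  if (mode == "targeted") {
    ord <- nm[order(-sdeg, seq_along(sdeg))]
    sizes <- .attack_sizes(sub, ord)
  } else {
    if (!is_count(n_reps, 1L)) stop("'n_reps' must be a count >= 1")
    reps_mat <- with_rng(seed, {
      vapply(seq_len(n_reps), function(rep) {
        .attack_sizes(sub, sample(nm))
      }, numeric(length(nm) + 1L))
    })
    sizes <- rowMeans(reps_mat)
  }
  n_removed <- seq_along(sizes) - 1L
  structure(
    list(mode = mode,
         points = data.frame(
           n_removed = n_removed,
           frac_removed = n_removed / length(nm),
           size = sizes,
           proportion = sizes / largest0),
         largest0 = largest0, n_active = length(nm),
         n_reps = if (mode == "random") n_reps else NA_integer_,
         reps = reps_mat),
    class = "attack_curve")
}

#' Fraction of nodes removed at disintegration
#'
#' Scans the attack curve for the first point at which the largest
#' component falls below the disintegration criterion. By default
#' "complete disintegration" means a largest component of at most 2 nodes;
#' alternatively a proportion threshold (of the original largest
#' component) can be given.
#'
#' @param curve An [attack_simulation()] result.
#' @param threshold Optional proportion in (0, 1]; the first point with
#'   `proportion < threshold` counts. When `NULL` the absolute <= 2 node
#'   rule is applied to the (mean) component size.
#' @return List with `reached` (logical), `fraction` of active nodes
#'   removed (`NA` when never reached) and `n_removed`.
#' @export
disintegration_point <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "attack_curve"))
  pts <- curve$points
  hit <- if (is.null(threshold)) which(pts$size <= 2)
         else which(pts$proportion < threshold)
  if (length(hit) == 0L)
    return(list(reached = FALSE, fraction = NA_real_,
                n_removed = NA_integer_))
  k <- pts$n_removed[hit[1L]]
  list(reached = TRUE, fraction = k / curve$n_active, n_removed = k)
}
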