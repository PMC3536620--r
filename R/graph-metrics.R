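# Segregation, integration and centrality measures on the binary topology
# of a functional network. All averaged measures are computed on active
# nodes (degree >= 1); thresholding makes the graph effectively binary, so
# edge weights are kept only for export.

# igraph of active nodes only.
.active_subgraph <- function(net) {
  g <- net$graph
  igraph::induced_subgraph(g, which(igraph::degree(g) >= 1))
}

#' Active nodes of a functional network
#'
#' @param net A [functional_network()].
#' @return Character vector of regions with degree >= 1.
#' @export
active_nodes <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  net$regions[igraph::degree(net$graph) >= 1]
}

# Global efficiency of an igraph: mean of 1/d over all unordered vertex
# pairs, unreachable pairs contributing zero. Defined as 0 for < 2 nodes.
.global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Segregation metrics: mean clustering, transitivity, local efficiency
#'
#' The clustering coefficient of a node is the number of connections among
#' its direct neighbours divided by the number possible, taken as 0 for
#' degree < 2; `C` averages it over active nodes. Transitivity `T` is the
#' triangle-based whole-graph version (3 x triangles / connected triples).
#' Local efficiency `E_loc` averages, over active nodes, the global
#' efficiency of each node's neighbour-induced subgraph.
#'
#' @param net A [functional_network()].
#' @return Named list `C`, `T`, `E_loc`.
#' @export
segregation_metrics <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- .active_subgraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("network has no active nodes")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0   # no connected triples
  eloc <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) < 2L) return(0)
    .global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  list(C = mean(cc), T = trans, E_loc = mean(eloc))
}

#' Integration metrics: characteristic path length and global efficiency
#'
#' Unweighted shortest paths among active nodes. `L` averages path length
#' over reachable pairs only; `E_glob` averages inverse path length over
#' all active-node pairs, with unreachable pairs contributing zero (the
#' inverse of infinity).
#'
#' @param net A [functional_network()].
#' @return Named list `L`, `E_glob`.
#' @export
integration_metrics <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- .active_subgraph(net)
  if (igraph::vcount(g) < 2L)
    stop("integration metrics need at least 2 active nodes")
  d <- igraph::distances(g, weights = NA)
  finite <- is.finite(d) & upper.tri(d)
  list(L = mean(d[finite]),
       E_glob = .global_efficiency(g))
}

#' Per-node degree and betweenness
#'
#' Betweenness is the unnormalized count of shortest paths between other
#' node pairs passing through a node, with fractional attribution when
#' several shortest paths tie (Brandes accumulation). Inactive nodes get
#' degree 0 and betweenness 0.
#'
#' @param net A [functional_network()].
#' @return Data frame with columns `region`, `degree`, `betweenness`.
#' @export
centrality_measures <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- net$graph
  data.frame(
    region = net$regions,
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, weights = NA,
                                             directed = FALSE)),
    stringsAsFactors = FALSE)
}

#' Degree assortativity coefficient
#'
#' Pearson correlation between the degrees at the two ends of every edge,
#' each undirected edge counted in both orientations. Positive values mean
#' hubs attach to hubs. For a degree-regular graph the coefficient is
#' undefined (zero variance) and `NA` is returned.
#'
#' @param net A [functional_network()].
#' @return The assortativity coefficient, or `NA` when undefined.
#' @export
assortativity_coefficient <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  g <- net$graph
  if (igraph::ecount(g) < 2L)
    stop("assortativity needs at least 2 edges")
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  x <- c(deg[el[, 1L]], deg[el[, 2L]])
  y <- c(deg[el[, 2L]], deg[el[, 1L]])
  if (sd(x) == 0) return(NA_real_)
  cor(x, y)
}

# Named metric registry used by null ensembles and bootstrap CIs. Each
# entry computes only its own quantity (ensembles evaluate these thousands
# of times).
.metric_fun <- function(metric) {
  switch(metric,
    clustering = function(net) {
      g <- .active_subgraph(net)
      if (igraph::vcount(g) == 0L) stop("network has no active nodes")
      mean(igraph::transitivity(g, type = "local", isolates = "zero"))
    },
    transitivity = function(net) {
      g <- .active_subgraph(net)
      if (igraph::vcount(g) == 0L) stop("network has no active nodes")
      t <- igraph::transitivity(g, type = "global")
      if (is.nan(t)) 0 else t
    },
    local_efficiency = function(net) segregation_metrics(net)$E_loc,
    path_length = function(net) integration_metrics(net)$L,
    global_efficiency = function(net) {
      g <- .active_subgraph(net)
      if (igraph::vcount(g) < 2L)
        stop("integration metrics need at least 2 active nodes")
      .global_efficiency(g)
    },
    assortativity = function(net) assortativity_coefficient(net),
    stop("unknown metric: ", metric))
}

#' Names of the supported network metrics
#' @return Character vector.
#' @export
network_metrics <- function() {
  c("clustering", "transitivity", "local_efficiency",
    "path_length", "global_efficiency", "assortativity")
}
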