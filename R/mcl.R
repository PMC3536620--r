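# Markov Cluster Algorithm. Deterministic flow simulation on the binary
# adjacency of the active nodes: expansion (matrix squaring) spreads flow
# along walks, inflation (entrywise power + column renormalization)
# sharpens it, and the attractor structure of the limit matrix yields the
# partition. Self-loops are added before normalization (standard MCL
# practice) and the thresholded graph is treated as binary.

#' Markov Cluster Algorithm partition of a functional network
#'
#' @param net A [functional_network()] with at least one active node.
#' @param inflation Inflation parameter (> 1, default 2.6).
#' @param max_iter Maximum expansion/inflation iterations.
#' @param tol Convergence tolerance on the maximum entry change.
#' @return A `cluster_partition`: list with `assignment` (named integer
#'   vector over all regions; inactive regions form singleton clusters),
#'   `inflation`, `n_iterations`, `converged`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
#' mcl_cluster(functional_network(g))  # two clusters, one per triangle
mcl_cluster <- function(net, inflation = 2.6, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(net, "functional_network"))
  if (inflation <= 1) stop("'inflation' must be > 1")
  g <- net$graph
  act <- which(igraph::degree(g) >= 1)
  if (length(act) == 0L) stop("network has no active node")
  sub <- igraph::induced_subgraph(g, act)
  nodes <- igraph::V(sub)$name
  n <- length(nodes)
  a <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  a[a != 0] <- 1
  diag(a) <- 1
  m <- sweep(a, 2L, colSums(a), `/`)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mn <- m %*% m                     # expansion
    mn <- mn^inflation                # inflation
    mn[mn < 1e-14] <- 0
    mn <- sweep(mn, 2L, colSums(mn), `/`)
    delta <- max(abs(mn - m))
    m <- mn
    if (delta < tol) { converged <- TRUE; break }
  }
  # Attractors are the rows retaining mass in the limit matrix; attractor
  # rows sharing a column belong to one attractor system (= cluster).
  nz <- m > 1e-8
  attractors <- which(rowSums(nz) > 0)
  cl_of_attr <- seq_along(attractors)
  for (j in seq_len(n)) {
    rows <- match(which(nz[, j]), attractors)
    rows <- rows[!is.na(rows)]
    if (length(rows) > 1L) {
      tgt <- min(cl_of_attr[rows])
      cl_of_attr[cl_of_attr %in% cl_of_attr[rows]] <- tgt
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    rows <- match(which(nz[, j]), attractors)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L)           # numerically drained column
      rows <- match(which.max(m[, j]), attractors)
    assignment[j] <- min(cl_of_attr[rows])   # overlap: lowest cluster index
  }
  assignment <- match(assignment, sort(unique(assignment)))
  names(assignment) <- nodes
  # Inactive regions: one singleton cluster each.
  inact <- setdiff(net$regions, nodes)
  full <- c(assignment,
            setNames(max(assignment, 0L) + seq_along(inact), inact))
  full <- full[net$regions]
  structure(
    list(assignment = full, inflation = inflation,
         n_iterations = it, converged = converged,
         n_clusters = length(unique(full))),
    class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf(
    "MCL partition (inflation %.2f): %d clusters, %d iterations%s\n",
    x$inflation, x$n_clusters, x$n_iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Anatomical composition of clusters
#'
#' For each cluster and major brain subdivision: the member count, the
#' proportion of the cluster it represents, and the proportion of that
#' subdivision's regions captured by the cluster. A subdivision is flagged
#' over-represented in a cluster when its cluster proportion exceeds its
#' global proportion among all regions.
#'
#' @param partition A [mcl_cluster()] result.
#' @param metadata A [region_metadata()] table covering all regions.
#' @return Data frame with columns `cluster`, `subdivision`, `count`,
#'   `cluster_proportion`, `capture`, `over_represented`.
#' @export
cluster_composition <- function(partition, metadata) {
  stopifnot(inherits(partition, "cluster_partition"))
  regs <- names(partition$assignment)
  idx <- match(regs, metadata$abbreviation)
  if (anyNA(idx))
    stop("metadata does not cover region: ", regs[is.na(idx)][1L])
  subdiv <- metadata$subdivision[idx]
  global_prop <- table(subdiv) / length(subdiv)
  subdiv_total <- table(subdiv)
  out <- do.call(rbind, lapply(sort(unique(partition$assignment)),
                               function(cl) {
    members <- subdiv[partition$assignment == cl]
    tab <- table(members)
    data.frame(cluster = cl,
               subdivision = names(tab),
               count = as.integer(tab),
               cluster_proportion = as.numeric(tab) / length(members),
               capture = as.numeric(tab) /
                 as.numeric(subdiv_total[names(tab)]),
               stringsAsFactors = FALSE)
  }))
  out$over_represented <- out$cluster_proportion >
    as.numeric(global_prop[out$subdivision])
  rownames(out) <- NULL
  out
}
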