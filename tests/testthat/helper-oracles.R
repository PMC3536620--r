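# Brute-force graph oracles, independent of igraph and of the package's
# metric implementations. Graphs are plain symmetric 0/1 adjacency
# matrices. These enumerate paths/triangles directly and are only meant
# for small graphs (<= ~8 nodes).

bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0L) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(a[v, ] == 1)) {
          if (d[s, w] > dist) { d[s, w] <- dist; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# All shortest paths between s and t, as lists of vertex sequences.
bf_shortest_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  grow <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    out <- list()
    for (w in which(a[v, ] == 1)) {
      if (d[s, w] == d[s, v] + 1 && d[w, t] == d[v, t] - 1)
        out <- c(out, grow(c(path, w)))
    }
    out
  }
  grow(s)
}

# Unnormalized betweenness with fractional attribution over tied paths.
bf_betweenness <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- bf_shortest_paths(a, d, s, t)
    if (length(paths) == 0L) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      if (length(inner) > 0L)
        b[inner] <- b[inner] + 1 / length(paths)
    }
  }
  b
}

bf_triangles_at <- function(a, v) {
  nb <- which(a[v, ] == 1)
  if (length(nb) < 2L) return(0)
  sum(a[nb, nb]) / 2
}

bf_local_clustering <- function(a) {
  vapply(seq_len(nrow(a)), function(v) {
    k <- sum(a[v, ])
    if (k < 2) return(0)
    bf_triangles_at(a, v) / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_transitivity <- function(a) {
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(0)
  tri <- sum(vapply(seq_len(nrow(a)), function(v) bf_triangles_at(a, v),
                    numeric(1))) / 3
  3 * tri / triples
}

bf_global_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- bf_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

bf_local_efficiency <- function(a) {
  vapply(seq_len(nrow(a)), function(v) {
    nb <- which(a[v, ] == 1)
    if (length(nb) < 2L) return(0)
    bf_global_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
}

bf_path_length <- function(a) {
  d <- bf_distances(a)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

bf_assortativity <- function(a) {
  deg <- rowSums(a)
  ij <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  x <- c(deg[ij[, 1]], deg[ij[, 2]])
  y <- c(deg[ij[, 2]], deg[ij[, 1]])
  if (sd(x) == 0) return(NA_real_)
  cor(x, y)
}

# Helpers to build fixture networks.
net_from_adj <- function(a, names = NULL) {
  if (is.null(names)) names <- sprintf("v%02d", seq_len(nrow(a)))
  dimnames(a) <- list(names, names)
  functional_network(igraph::graph_from_adjacency_matrix(
    a, mode = "undirected"))
}

net_from_edges <- function(n, edges, names = NULL) {
  a <- matrix(0, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
  net_from_adj(a, names)
}

adj_of <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = FALSE))
}

# All non-isomorphic simple graphs on <= 6 nodes (graph atlas, entries
# 1..208 cover 1..6 vertices).
atlas_graphs <- function() {
  lapply(1:208, function(i) {
    g <- igraph::graph_from_atlas(i)
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  })
}
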