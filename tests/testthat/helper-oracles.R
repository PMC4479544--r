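# Brute-force graph-metric oracles, independent of the package (and of
# igraph): Floyd-Warshall distances, exhaustive geodesic enumeration for
# betweenness, explicit triangle counting. Only usable at small n.

make_net <- function(adj, tau = 0) {
  binary_network(adj, tau = tau, region_labels = paste0("r", seq_len(nrow(adj))))
}

adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

random_adj <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_density <- function(adj) {
  n <- nrow(adj)
  sum(adj) / (n * (n - 1))
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

oracle_char_path_length <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) NA_real_ else mean(v)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) tri <- tri + adj[nb[a], nb[b]]
    }
    2 * tri / (k * (k - 1))
  }, 0)
}

# all simple paths from s to t by depth-first enumeration
.all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- .all_paths(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, 0L)
      geo <- paths[lens == min(lens)]
      through <- numeric(n)
      for (p in geo) {
        mid <- setdiff(p, c(s, t))
        through[mid] <- through[mid] + 1
      }
      b <- b + through / length(geo)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}
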