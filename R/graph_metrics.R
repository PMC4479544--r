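# Graph-theory metrics on binary undirected networks.
#
# Network-level: density, global efficiency, characteristic path length,
# mean clustering, mean betweenness, smallworldness (analytic random-graph
# normalization), modularity. Node-level: degree, nodal efficiency,
# clustering, betweenness. Graph primitives (BFS distances, geodesic
# counting, greedy community detection) are delegated to igraph.

.as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

.check_net <- function(net) {
  if (!inherits(net, "binary_network")) {
    stop("expected a binary_network", call. = FALSE)
  }
  if (nrow(net$adjacency) < 2L) stop("network needs n >= 2 nodes", call. = FALSE)
  invisible(net)
}

#' Network density
#'
#' Fraction of possible node pairs that are connected: `2E / (n(n-1))`,
#' bounded by \[0, 1\].
#'
#' @param net A [binary_network()].
#' @return A fraction in \[0, 1\].
#' @export
net_density <- function(net) {
  .check_net(net)
  n <- nrow(net$adjacency)
  sum(net$adjacency) / (n * (n - 1))
}

#' All-pairs geodesic distances
#'
#' Unweighted shortest-path lengths in edges; unreachable pairs are `Inf`.
#'
#' @param net A [binary_network()].
#' @return Symmetric n x n numeric matrix with zero diagonal.
#' @export
net_distances <- function(net) {
  .check_net(net)
  igraph::distances(.as_igraph(net), algorithm = "unweighted")
}

#' Global efficiency
#'
#' Mean of the inverse geodesic distance over all ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs; bounded by \[0, 1\] and equal to 1 on
#' the complete graph.
#'
#' @param net A [binary_network()].
#' @param dist Optional precomputed [net_distances()] matrix.
#' @return A fraction in \[0, 1\].
#' @export
global_efficiency <- function(net, dist = NULL) {
  .check_net(net)
  if (is.null(dist)) dist <- net_distances(net)
  n <- nrow(dist)
  inv <- 1 / dist
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean geodesic distance over reachable ordered node pairs (unreachable
#' pairs are excluded, the Brain Connectivity Toolbox convention for
#' disconnected graphs). Equals 1 on the complete graph.
#'
#' @param net A [binary_network()].
#' @param dist Optional precomputed [net_distances()] matrix.
#' @return Mean geodesic distance, or `NA` with a warning when no pair is
#'   reachable.
#' @export
char_path_length <- function(net, dist = NULL) {
  .check_net(net)
  if (is.null(dist)) dist <- net_distances(net)
  d <- dist[upper.tri(dist)]
  d <- d[is.finite(d)]
  if (!length(d)) {
    warning("no reachable node pairs; characteristic path length undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(d)
}

#' Nodal efficiency
#'
#' Per-node mean inverse geodesic distance to every other node (`1/Inf = 0`).
#' This is the node-level integration measure paired with global efficiency;
#' the global efficiency is its mean across nodes.
#'
#' @param net A [binary_network()].
#' @param dist Optional precomputed [net_distances()] matrix.
#' @return Numeric vector of per-node fractions in \[0, 1\].
#' @export
nodal_efficiency <- function(net, dist = NULL) {
  .check_net(net)
  if (is.null(dist)) dist <- net_distances(net)
  inv <- 1 / dist
  diag(inv) <- 0
  unname(rowSums(inv)) / (nrow(dist) - 1)
}

#' Local efficiency of the neighborhood subgraph
#'
#' The Latora-Marchiori variant: global efficiency of the subgraph induced
#' by each node's neighbors. Provided for completeness; the pipeline's
#' node-level efficiency is [nodal_efficiency()].
#'
#' @param net A [binary_network()].
#' @return Numeric vector of per-node fractions (0 for degree < 2).
#' @export
local_efficiency_subgraph <- function(net) {
  .check_net(net)
  adj <- net$adjacency
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- binary_network(adj[nb, nb, drop = FALSE], tau = net$tau,
                          mode = net$mode,
                          region_labels = net$region_labels[nb])
    global_efficiency(sub)
  }, 0)
}

#' Clustering coefficient
#'
#' Per-node fraction of neighbor pairs that are themselves connected:
#' `2 * triangles / (k (k - 1))`, 0 for degree < 2.
#'
#' @param net A [binary_network()].
#' @return Numeric vector of per-node fractions in \[0, 1\]; use
#'   `mean()` of it for the network-level mean clustering coefficient.
#' @export
clustering_coef <- function(net) {
  .check_net(net)
  cc <- igraph::transitivity(.as_igraph(net), type = "localundirected",
                             isolates = "zero")
  unname(cc)
}

#' Betweenness centrality
#'
#' Per-node sum over node pairs of the fraction of geodesics passing through
#' the node (endpoints excluded), normalized by `(n-1)(n-2)/2` so values lie
#' in \[0, 1\] (1 = the center of a star).
#'
#' @param net A [binary_network()].
#' @return Numeric vector of per-node fractions in \[0, 1\].
#' @export
betweenness_centrality <- function(net) {
  .check_net(net)
  n <- nrow(net$adjacency)
  b <- igraph::betweenness(.as_igraph(net), directed = FALSE)
  unname(b) / ((n - 1) * (n - 2) / 2)
}

#' Analytic random-network reference values
#'
#' Expected clustering and path length of an Erdos-Renyi graph matched in
#' size and density: `C_rand` is the edge density `<k>/(n-1)`
#' (Watts-Strogatz), and `L_rand = (ln n - gamma)/ln <k> + 1/2` with gamma
#' the Euler-Mascheroni constant (Fronczak closed form).
#'
#' @param n Number of nodes.
#' @param mean_degree Mean degree `<k>`; must exceed 1 for the path-length
#'   formula to be defined.
#' @return List with `c_rand`, `l_rand` and `gamma_euler`.
#' @examples
#' random_reference(n = 100, mean_degree = 10) # l_rand ~ 2.2493
#' @export
random_reference <- function(n, mean_degree) {
  if (mean_degree <= 1) {
    stop("analytic random-graph path length requires mean degree > 1",
         call. = FALSE)
  }
  list(
    c_rand = mean_degree / (n - 1),
    l_rand = (log(n) - .EULER_GAMMA) / log(mean_degree) + 0.5,
    gamma_euler = .EULER_GAMMA
  )
}

#' Smallworldness
#'
#' `S = (C / C_rand) / (L / L_rand)`: clustering and path length normalized
#' to a random network of the same size and density, using the analytic
#' reference values of [random_reference()]. Approximately 1 for random
#' graphs and substantially greater for small-world networks.
#'
#' @param net A [binary_network()].
#' @return List with `smallworldness`, the observed `clustering` and
#'   `path_length`, and the `reference` values used.
#' @export
smallworldness <- function(net) {
  .check_net(net)
  n <- nrow(net$adjacency)
  kbar <- sum(net$adjacency) / n
  ref <- random_reference(n, kbar) # errors when mean degree <= 1
  cc <- mean(clustering_coef(net))
  pl <- char_path_length(net)
  list(
    smallworldness = (cc / ref$c_rand) / (pl / ref$l_rand),
    clustering = cc,
    path_length = pl,
    reference = ref
  )
}

#' Newman modularity of a greedy optimal partition
#'
#' Community structure by deterministic greedy modularity maximization
#' (fast-greedy agglomeration); returns the partition alongside Q so the
#' score is auditable.
#'
#' @param net A [binary_network()] with at least one edge.
#' @return List with `q` (modularity of the partition) and `membership`
#'   (integer community labels per node).
#' @export
modularity_q <- function(net) {
  .check_net(net)
  if (sum(net$adjacency) == 0) {
    stop("modularity undefined on an empty graph", call. = FALSE)
  }
  g <- .as_igraph(net)
  comm <- igraph::cluster_fast_greedy(g)
  list(q = igraph::modularity(comm), membership = igraph::membership(comm))
}

#' All network-level metrics of one network
#'
#' @param net A [binary_network()].
#' @param metrics Which metrics to compute.
#' @return Named list of scalar metric values; `smallworldness` is `NA`
#'   when the mean degree is 1 or less (analytic normalization undefined).
#' @export
global_metrics <- function(net,
                           metrics = c("density", "global_efficiency",
                                       "char_path_length", "mean_clustering",
                                       "mean_betweenness", "smallworldness")) {
  .check_net(net)
  metrics <- match.arg(metrics, several.ok = TRUE)
  dist <- NULL
  if (any(metrics %in% c("global_efficiency", "char_path_length",
                         "smallworldness"))) {
    dist <- net_distances(net)
  }
  out <- list()
  for (m in metrics) {
    out[[m]] <- switch(
      m,
      density = net_density(net),
      global_efficiency = global_efficiency(net, dist),
      char_path_length = suppressWarnings(char_path_length(net, dist)),
      mean_clustering = mean(clustering_coef(net)),
      mean_betweenness = mean(betweenness_centrality(net)),
      smallworldness = tryCatch({
        n <- nrow(net$adjacency)
        kbar <- sum(net$adjacency) / n
        ref <- random_reference(n, kbar)
        cc <- mean(clustering_coef(net))
        pl <- suppressWarnings(char_path_length(net, dist))
        (cc / ref$c_rand) / (pl / ref$l_rand)
      }, error = function(e) NA_real_),
      modularity = modularity_q(net)$q
    )
  }
  out
}

#' All node-level metrics of one network
#'
#' @param net A [binary_network()].
#' @return Named list of per-node vectors: `degree`, `nodal_efficiency`,
#'   `clustering`, `betweenness`.
#' @export
nodal_metrics <- function(net) {
  .check_net(net)
  dist <- net_distances(net)
  list(
    degree = unname(rowSums(net$adjacency)),
    nodal_efficiency = nodal_efficiency(net, dist),
    clustering = clustering_coef(net),
    betweenness = betweenness_centrality(net)
  )
}

# ---- metric curves ----------------------------------------------------------

#' Metric curve: one metric per subject across thresholds
#'
#' @param values Subject x threshold numeric matrix.
#' @param thresholds Strictly increasing threshold grid (integers for
#'   streamline mode, fractions for density mode).
#' @param metric Metric name.
#' @param subject_ids Subject identifiers (row order of `values`).
#' @param node Optional region index for node-level curves.
#' @return Object of class `metric_curve`.
#' @export
metric_curve <- function(values, thresholds, metric,
                         subject_ids = NULL, node = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(thresholds)) {
    stop("`values` must have one column per threshold", call. = FALSE)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(values = values, thresholds = as.numeric(thresholds),
         metric = metric, subject_ids = subject_ids, node = node),
    class = "metric_curve"
  )
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("<metric_curve> %s: %d subjects x %d thresholds [%s..%s]%s\n",
              x$metric, nrow(x$values), length(x$thresholds),
              format(min(x$thresholds)), format(max(x$thresholds)),
              if (is.null(x$node)) "" else paste0(" (node ", x$node, ")")))
  invisible(x)
}

#' Metric curves for a whole cohort
#'
#' Binarizes every subject's matrix at every threshold and computes the
#' requested metrics, producing the subject x threshold grids consumed by
#' [mtpc()] and [mtpc_nodewise()].
#'
#' @param cohort A [cohort_data()].
#' @param thresholds Streamline thresholds (mode `"streamline"`, default
#'   0:20) or target densities (mode `"density"`).
#' @param mode Threshold by raw streamline count or by matched density.
#' @param level `"global"` for network-level metrics, `"nodal"` for
#'   node-level metrics.
#' @param metrics Metric names; defaults to all network-level metrics for
#'   `level = "global"` and degree/nodal efficiency/clustering/betweenness
#'   for `level = "nodal"`.
#' @return For `level = "global"`: named list of [metric_curve()] objects.
#'   For `level = "nodal"`: named list of `nodal_curves` objects, each
#'   holding a subjects x thresholds x nodes array.
#' @export
metric_curves <- function(cohort, thresholds = 0:20,
                          mode = c("streamline", "density"),
                          level = c("global", "nodal"),
                          metrics = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  if (is.null(metrics)) {
    metrics <- if (level == "global") {
      c("density", "global_efficiency", "char_path_length",
        "mean_clustering", "mean_betweenness", "smallworldness")
    } else {
      c("degree", "nodal_efficiency", "clustering", "betweenness")
    }
  }
  S <- n_subjects(cohort)
  Tn <- length(thresholds)
  ids <- cohort$subjects$subject_id
  nets <- function(m, tau) {
    if (mode == "streamline") threshold_binarize(m, tau)
    else density_match_threshold(m, tau)
  }
  if (level == "global") {
    vals <- lapply(metrics, function(x) matrix(NA_real_, S, Tn))
    names(vals) <- metrics
    for (s in seq_len(S)) {
      for (t in seq_len(Tn)) {
        net <- nets(cohort$matrices[[s]], thresholds[t])
        gm <- global_metrics(net, metrics = metrics)
        for (m in metrics) vals[[m]][s, t] <- gm[[m]]
      }
    }
    out <- lapply(metrics, function(m) {
      metric_curve(vals[[m]], thresholds, m, subject_ids = ids)
    })
    names(out) <- metrics
    out
  } else {
    N <- length(cohort$region_labels)
    arrs <- lapply(metrics, function(x) array(NA_real_, c(S, Tn, N)))
    names(arrs) <- metrics
    for (s in seq_len(S)) {
      for (t in seq_len(Tn)) {
        net <- nets(cohort$matrices[[s]], thresholds[t])
        nm <- nodal_metrics(net)
        for (m in metrics) arrs[[m]][s, t, ] <- nm[[m]]
      }
    }
    out <- lapply(metrics, function(m) {
      structure(list(values = arrs[[m]], thresholds = as.numeric(thresholds),
                     metric = m, subject_ids = ids,
                     region_labels = cohort$region_labels),
                class = "nodal_curves")
    })
    names(out) <- metrics
    out
  }
}

#' @export
print.nodal_curves <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<nodal_curves> %s: %d subjects x %d thresholds x %d nodes\n",
              x$metric, d[1], d[2], d[3]))
  invisible(x)
}

#' Flatten metric curves to a long data frame
#'
#' Long format suitable for CSV export: one row per subject, threshold (and
#' node, for node-level curves), with columns `subject_id`, `tau`, `metric`,
#' `node`, `value` (`node` is `NA` for network-level metrics).
#'
#' @param curves A [metric_curve()], a `nodal_curves` object, or a list of
#'   either (as returned by [metric_curves()]).
#' @return A data frame.
#' @export
curves_to_df <- function(curves) {
  if (inherits(curves, "metric_curve") || inherits(curves, "nodal_curves")) {
    curves <- list(curves)
  }
  rows <- lapply(curves, function(cv) {
    ids <- cv$subject_ids %||% seq_len(nrow(as.matrix(cv$values)))
    if (inherits(cv, "metric_curve")) {
      data.frame(
        subject_id = rep(ids, times = length(cv$thresholds)),
        tau = rep(cv$thresholds, each = length(ids)),
        metric = cv$metric,
        node = if (is.null(cv$node)) NA_integer_ else cv$node,
        value = as.vector(cv$values)
      )
    } else {
      d <- dim(cv$values)
      data.frame(
        subject_id = rep(ids, times = d[2] * d[3]),
        tau = rep(rep(cv$thresholds, each = d[1]), times = d[3]),
        metric = cv$metric,
        node = rep(seq_len(d[3]), each = d[1] * d[2]),
        value = as.vector(cv$values)
      )
    }
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
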