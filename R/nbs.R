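# Network-based statistics: edge-level covariate-adjusted F maps,
# supra-threshold component extraction, and FWER-corrected component
# p-values from the permutation distribution of the maximal component size.

#' Network-based statistic (NBS)
#'
#' Tests every region pair's connectivity for a group effect with the same
#' covariate-adjusted ANCOVA F as the metric analysis, forms the graph of
#' edges whose F exceeds `f_threshold`, and assigns each connected component
#' a family-wise-corrected p-value by comparing its edge count to the
#' permutation distribution of the maximal supra-threshold component size.
#'
#' Edge statistics are computed on the raw streamline counts (the matrices
#' as supplied, before any binarization); set `log_transform = TRUE` for a
#' `log1p` variance-stabilizing transform. Edges with nonzero counts in
#' fewer than 2 subjects of either group are excluded (their F is
#' degenerate), as are edges with zero variance.
#'
#' @param cohort A [cohort_data()].
#' @param design A [design_spec()] aligned to the cohort.
#' @param f_threshold Initial edge-level F threshold (default 3.1).
#' @param n_perm Number of permutations (default 2500).
#' @param log_transform Apply `log1p` to counts before testing.
#' @return Object of class `nbs_result`: `f_edges` (per-edge F, data frame
#'   with region indices), `f_threshold`, `components` (list of edge-index
#'   data frames), `component_sizes`, `null_max_size`, `p_component`,
#'   `n_excluded` (edges not testable).
#' @export
nbs_test <- function(cohort, design, f_threshold = 3.1, n_perm = 2500,
                     log_transform = FALSE) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(design, "design_spec"))
  S <- n_subjects(cohort)
  if (S != length(design$g)) {
    stop("cohort subjects must match design subjects", call. = FALSE)
  }
  n <- length(cohort$region_labels)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Y <- matrix(0, S, nrow(ut))
  for (s in seq_len(S)) {
    Y[s, ] <- cohort$matrices[[s]]$counts[upper.tri(matrix(0, n, n))]
  }
  nz_per_group <- rowsum((Y > 0) * 1, design$group)
  testable <- nz_per_group[1, ] >= 2 & nz_per_group[2, ] >= 2 &
    apply(Y, 2, function(v) var(v) > 0)
  n_excluded <- sum(!testable)
  if (!any(testable)) stop("no testable edges", call. = FALSE)
  Yt <- Y[, testable, drop = FALSE]
  if (log_transform) Yt <- log1p(Yt)
  edge_idx <- ut[testable, , drop = FALSE]

  perms <- .perm_matrix(design)
  perms <- perms[seq_len(min(n_perm, nrow(perms))), , drop = FALSE]
  if (n_perm > design$n_perm) {
    # design carries the seed; honour the requested permutation count
    extra <- with_seed(derive_seed(design$seed, 1L), {
      t(vapply(seq_len(n_perm - design$n_perm), function(i) sample.int(S),
               integer(S)))
    })
    perms <- rbind(perms, extra)
  }
  p0 <- ncol(design$x0)
  ey <- qr.resid(design$qr0, Yt)
  rss0 <- colSums(ey^2)
  f_obs <- .f_group(design$g, design$qr0, ey, rss0, S, p0)

  comp_of <- function(fvals) {
    supra <- which(is.finite(fvals) & fvals > f_threshold)
    if (!length(supra)) return(list(sizes = integer(0), members = list()))
    el <- edge_idx[supra, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    memb <- igraph::components(g)$membership
    comp_id <- memb[el[, 1]] # both endpoints share a component
    sizes <- as.integer(table(comp_id))
    members <- split(supra, comp_id)
    ord <- order(sizes, decreasing = TRUE)
    list(sizes = sizes[ord], members = members[ord])
  }

  obs <- comp_of(f_obs)
  null_max <- vapply(seq_len(nrow(perms)), function(i) {
    fp <- .f_group(design$g[perms[i, ]], design$qr0, ey, rss0, S, p0)
    supra <- which(is.finite(fp) & fp > f_threshold)
    if (!length(supra)) return(0L)
    el <- edge_idx[supra, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    memb <- igraph::components(g)$membership
    max(as.integer(table(memb[el[, 1]])))
  }, 0L)
  p_comp <- vapply(obs$sizes, function(sz) {
    (1 + sum(null_max >= sz)) / (nrow(perms) + 1)
  }, 0)
  components <- lapply(obs$members, function(ix) {
    data.frame(region_i = edge_idx[ix, 1], region_j = edge_idx[ix, 2],
               f = f_obs[ix])
  })
  structure(
    list(
      f_edges = data.frame(region_i = edge_idx[, 1], region_j = edge_idx[, 2],
                           f = f_obs),
      f_threshold = f_threshold,
      components = components,
      component_sizes = obs$sizes,
      null_max_size = null_max,
      p_component = p_comp,
      n_excluded = n_excluded,
      n_perm = nrow(perms),
      region_labels = cohort$region_labels
    ),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> F threshold %.2f, %d permutations, %d edge(s) excluded\n",
              x$f_threshold, x$n_perm, x$n_excluded))
  if (!length(x$component_sizes)) {
    cat("  no supra-threshold components\n")
  } else {
    for (i in seq_along(x$component_sizes)) {
      cat(sprintf("  component %d: %d edges, p = %.4f%s\n", i,
                  x$component_sizes[i], x$p_component[i],
                  if (x$p_component[i] <= 0.05) " *" else ""))
    }
  }
  invisible(x)
}
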