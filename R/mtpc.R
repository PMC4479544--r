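# Group inference on metric curves: covariate-adjusted ANCOVA F statistics,
# multithreshold permutation correction (MTPC), node-level max-statistic
# correction, post-hoc t-tests, and contingency-table tests.

#' Design specification for group comparisons
#'
#' Captures the one-way ANCOVA design used throughout: a two-level group
#' factor adjusted for age (numeric), gender (two-level) and handedness
#' (three-level, two indicator columns against the "right" reference).
#'
#' @param group Two-level factor (`control`/`PE`) per subject, or a
#'   [cohort_data()] from which all fields are taken.
#' @param age Numeric age per subject.
#' @param gender Two-level factor (`male`/`female`).
#' @param handedness Three-level factor (`right`/`left`/`none`).
#' @param alpha Confidence level for the permutation tests (default 0.05).
#' @param n_perm Number of group-label permutations (default 500).
#' @param seed Random seed controlling the permutations.
#' @param scheme Permutation scheme: `"labels"` (default) permutes the raw
#'   group assignments with covariates fixed; `"freedman_lane"` permutes
#'   the residuals of the covariate-only model instead, which is more
#'   robust when covariates are imbalanced between groups.
#' @return Object of class `design_spec` holding the covariate model matrix
#'   `x0` (intercept + covariates) and group indicator `g` (PE = 1).
#' @export
design_spec <- function(group, age = NULL, gender = NULL, handedness = NULL,
                        alpha = 0.05, n_perm = 500, seed = 42,
                        scheme = c("labels", "freedman_lane")) {
  scheme <- match.arg(scheme)
  if (inherits(group, "cohort_data")) {
    subj <- group$subjects
    group <- subj$group
    age <- subj$age
    gender <- subj$gender
    handedness <- subj$handedness
  }
  group <- factor(as.character(group), levels = .GROUP_LEVELS)
  gender <- factor(as.character(gender), levels = .GENDER_LEVELS)
  handedness <- factor(as.character(handedness), levels = .HANDEDNESS_LEVELS)
  n <- length(group)
  if (length(age) != n || length(gender) != n || length(handedness) != n) {
    stop("group, age, gender, handedness must have equal length", call. = FALSE)
  }
  if (anyNA(group) || anyNA(age) || anyNA(gender) || anyNA(handedness)) {
    stop("missing values in group or covariates", call. = FALSE)
  }
  if (any(tabulate(group, 2) < 2)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("`alpha` must be in (0, 0.5)", call. = FALSE)
  }
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  x0 <- cbind(
    intercept = 1,
    age = as.numeric(age),
    gender_female = as.numeric(gender == "female"),
    hand_left = as.numeric(handedness == "left"),
    hand_none = as.numeric(handedness == "none")
  )
  # drop covariate columns that are constant in this sample (e.g. a cohort
  # with no left-handers); a constant column carries no adjustment
  keep <- c(TRUE, apply(x0[, -1, drop = FALSE], 2, function(v) var(v) > 0))
  x0 <- x0[, keep, drop = FALSE]
  qr0 <- qr(x0)
  if (qr0$rank < ncol(x0)) {
    bad <- colnames(x0)[qr0$pivot[(qr0$rank + 1):ncol(x0)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(group = group, g = as.numeric(group == "PE"), x0 = x0, qr0 = qr0,
         alpha = alpha, n_perm = as.integer(n_perm), seed = as.integer(seed),
         scheme = scheme),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %d subjects (%s), covariates: %s; alpha = %g, n_perm = %d, seed = %d\n",
    length(x$g),
    paste(sprintf("%s: %d", levels(x$group), tabulate(x$group, 2)),
          collapse = ", "),
    paste(colnames(x$x0)[-1], collapse = ", "), x$alpha, x$n_perm, x$seed))
  invisible(x)
}

# Extra-sum-of-squares F for adding the group indicator to the covariate
# model, vectorized over response columns. Because the group factor adds a
# single column, the group effect reduces to the regression of
# covariate-residualized y on the covariate-residualized indicator:
#   F = (RSS0 - RSS1) / (RSS1 / (n - p0 - 1)).
# `ey` is qr.resid(qr0, Y); `rss0` its column sums of squares.
.f_group <- function(g, qr0, ey, rss0, n, p0) {
  eg <- qr.resid(qr0, g)
  sg <- sum(eg^2)
  num <- drop(crossprod(eg, ey))^2 / sg
  rss1 <- pmax(rss0 - num, 0)
  df2 <- n - p0 - 1
  f <- num / (rss1 / df2)
  f[rss1 <= .Machine$double.eps * rss0] <- Inf
  f[rss0 <= 0] <- NaN # response constant across subjects: F undefined
  f
}

#' Covariate-adjusted ANCOVA F for a group effect
#'
#' F statistic (1 numerator df) for the group factor in the linear model
#' `value ~ group + age + gender + handedness`, computed as the extra sum of
#' squares of adding group to the covariate-only model.
#'
#' @param values Numeric response per subject.
#' @param design A [design_spec()].
#' @return List with `f`, degrees of freedom `df1`/`df2`, and the
#'   uncorrected parametric `p`.
#' @export
ancova_f <- function(values, design) {
  stopifnot(inherits(design, "design_spec"))
  values <- as.numeric(values)
  n <- length(design$g)
  if (length(values) != n) stop("length mismatch", call. = FALSE)
  if (anyNA(values)) stop("missing response values", call. = FALSE)
  p0 <- ncol(design$x0)
  ey <- qr.resid(design$qr0, values)
  rss0 <- sum(ey^2)
  if (rss0 <= 1e-10 * (1 + sum(values^2))) {
    # all responses identical: no group variance to explain
    return(list(f = 0, df1 = 1, df2 = n - p0 - 1, p = 1))
  }
  f <- .f_group(design$g, design$qr0, matrix(ey), rss0, n, p0)
  df2 <- n - p0 - 1
  list(f = f, df1 = 1, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE))
}

#' Post-hoc t statistic for the group effect
#'
#' t for the group coefficient in the same covariate-adjusted model used by
#' [ancova_f()]; its square equals the ANCOVA F, and its sign gives the
#' direction of the effect (PE minus control).
#'
#' @param values Numeric response per subject.
#' @param design A [design_spec()].
#' @param tau Optional threshold annotation (stored in the result).
#' @return List with `t`, `df`, two-sided `p`, `direction` (`"PE < control"`
#'   or `"PE > control"`), the group-coefficient `estimate`, and `tau`.
#' @export
posthoc_t <- function(values, design, tau = NULL) {
  stopifnot(inherits(design, "design_spec"))
  values <- as.numeric(values)
  n <- length(design$g)
  p0 <- ncol(design$x0)
  ey <- qr.resid(design$qr0, values)
  eg <- qr.resid(design$qr0, design$g)
  sg <- sum(eg^2)
  beta <- sum(eg * ey) / sg
  rss1 <- sum((ey - beta * eg)^2)
  df <- n - p0 - 1
  se <- sqrt(rss1 / df / sg)
  tval <- beta / se
  list(t = tval, df = df, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       direction = if (tval < 0) "PE < control" else "PE > control",
       estimate = beta, tau = tau)
}

# Supra-critical clusters of an F curve and their AUCs.
# AUC integrates the excess (F - f_crit) over each contiguous run of
# supra-critical thresholds by the trapezoid rule; a single-point cluster
# contributes (F - f_crit) * dtau, with dtau the median grid spacing.
.clusters_auc <- function(fvals, f_crit, taus) {
  ok <- is.finite(fvals)
  supra <- ok & (fvals > f_crit)
  if (!any(supra)) {
    return(list(clusters = list(), auc = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dtau <- if (length(taus) > 1) median(diff(taus)) else 1
  clusters <- list()
  auc <- numeric(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    h <- fvals[idx] - f_crit
    a <- if (length(idx) == 1) {
      h * dtau
    } else {
      sum((h[-1] + h[-length(h)]) / 2 * diff(taus[idx]))
    }
    clusters <- c(clusters, list(idx))
    auc <- c(auc, a)
  }
  list(clusters = clusters, auc = auc)
}

# Generate the permutation index matrix (n_perm x n) under the design seed.
.perm_matrix <- function(design) {
  n <- length(design$g)
  with_seed(design$seed, {
    t(vapply(seq_len(design$n_perm), function(i) sample.int(n), integer(n)))
  })
}

# Core MTPC machinery shared by mtpc() and mtpc_nodewise().
# y: subjects x (thresholds * nodes) matrix; returns observed and permuted F.
.f_curves <- function(y, design, perms) {
  n <- nrow(y)
  p0 <- ncol(design$x0)
  ey <- qr.resid(design$qr0, y)
  rss0 <- colSums(ey^2)
  f_obs <- .f_group(design$g, design$qr0, ey, rss0, n, p0)
  f_perm <- matrix(NA_real_, nrow(perms), ncol(y))
  if (identical(design$scheme, "freedman_lane")) {
    # permute covariate residuals, re-residualize, test the original labels
    for (i in seq_len(nrow(perms))) {
      eyp <- qr.resid(design$qr0, ey[perms[i, ], , drop = FALSE])
      f_perm[i, ] <- .f_group(design$g, design$qr0, eyp, colSums(eyp^2), n, p0)
    }
  } else {
    for (i in seq_len(nrow(perms))) {
      f_perm[i, ] <- .f_group(design$g[perms[i, ]], design$qr0, ey, rss0, n, p0)
    }
  }
  list(f_obs = f_obs, f_perm = f_perm)
}

.mtpc_decide <- function(f_obs, taus, f_crit, a_crit, null_max, n_perm) {
  cl <- .clusters_auc(f_obs, f_crit, taus)
  has <- length(cl$auc) > 0
  if (has) {
    supra_idx <- unlist(cl$clusters)
    peak <- supra_idx[which.max(f_obs[supra_idx])]
  } else {
    peak <- which.max(ifelse(is.finite(f_obs), f_obs, -Inf))
  }
  f_mtpc <- f_obs[peak]
  p_corr <- (1 + sum(null_max >= f_mtpc)) / (n_perm + 1)
  list(
    f_observed = f_obs, thresholds = taus, f_crit = f_crit,
    clusters = cl$clusters, a_mtpc = cl$auc, a_crit = a_crit,
    f_mtpc = f_mtpc, tau_mtpc = taus[peak], p_corr = p_corr,
    reject = has && max(cl$auc) > a_crit
  )
}

#' Multithreshold permutation correction (MTPC)
#'
#' Permutation family-wise error control for a group effect tested across a
#' sweep of network thresholds:
#' 1. the observed covariate-adjusted F is computed at every threshold;
#' 2. group labels are permuted (`n_perm` times, seeded) and the F curve
#'    recomputed for each permutation, covariates staying fixed;
#' 3. the maximum F across thresholds of each permutation forms the null
#'    distribution, whose (1 - alpha) empirical quantile is the critical
#'    value `f_crit`;
#' 4. contiguous runs of observed supra-critical F form clusters, each
#'    scored by the trapezoid AUC of (F - f_crit) over its thresholds;
#' 5. the critical AUC `a_crit` is the mean over all permutations of each
#'    permutation's maximal supra-critical cluster AUC (0 for permutations
#'    with none);
#' 6. the null hypothesis is rejected when the largest observed cluster AUC
#'    exceeds `a_crit`. The corrected p-value uses the add-one estimator
#'    on the null maxima against the peak supra-critical F.
#'
#' Thresholds at which the metric is undefined for any subject are dropped
#' with a warning rather than imputed.
#'
#' @param curve A [metric_curve()].
#' @param design A [design_spec()] aligned to the curve's subject rows.
#' @return Object of class `mtpc_result`: `f_observed`, `thresholds`,
#'   `f_crit`, `null_max`, `clusters` (threshold-index runs), `a_mtpc`,
#'   `a_crit`, `f_mtpc`, `tau_mtpc`, `p_corr`, `reject`.
#' @export
mtpc <- function(curve, design) {
  stopifnot(inherits(curve, "metric_curve"), inherits(design, "design_spec"))
  y <- curve$values
  taus <- curve$thresholds
  if (nrow(y) != length(design$g)) {
    stop("curve rows must match design subjects", call. = FALSE)
  }
  keep <- apply(y, 2, function(v) all(is.finite(v)))
  if (!all(keep)) {
    warning(sprintf("dropping %d threshold(s) with undefined %s values",
                    sum(!keep), curve$metric), call. = FALSE)
  }
  y <- y[, keep, drop = FALSE]
  taus <- taus[keep]
  # a threshold where the metric is constant across subjects has no group
  # variance to test; drop it rather than impute
  const <- apply(y, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant-valued threshold(s)", sum(const)),
            call. = FALSE)
    y <- y[, !const, drop = FALSE]
    taus <- taus[!const]
  }
  if (length(taus) < 2) {
    stop("fewer than 2 usable thresholds", call. = FALSE)
  }
  perms <- .perm_matrix(design)
  fc <- .f_curves(y, design, perms)
  null_max <- apply(fc$f_perm, 1, function(v) max(v[is.finite(v)]))
  f_crit <- quantile(null_max, 1 - design$alpha, type = 7, names = FALSE)
  perm_max_auc <- vapply(seq_len(nrow(fc$f_perm)), function(i) {
    a <- .clusters_auc(fc$f_perm[i, ], f_crit, taus)$auc
    if (length(a)) max(a) else 0
  }, 0)
  a_crit <- mean(perm_max_auc)
  res <- .mtpc_decide(fc$f_obs, taus, f_crit, a_crit, null_max, design$n_perm)
  res$null_max <- null_max
  res$metric <- curve$metric
  res$alpha <- design$alpha
  res$n_perm <- design$n_perm
  structure(res, class = "mtpc_result")
}

#' @export
print.mtpc_result <- function(x, ...) {
  cat(sprintf("<mtpc_result> %s: F_mtpc = %.3f at tau = %s, F_crit = %.3f\n",
              x$metric %||% "", x$f_mtpc, format(x$tau_mtpc), x$f_crit))
  cat(sprintf("  clusters: %d, max A_mtpc = %s, A_crit = %.4f\n",
              length(x$clusters),
              if (length(x$a_mtpc)) sprintf("%.4f", max(x$a_mtpc)) else "none",
              x$a_crit))
  cat(sprintf("  p_corr = %.4f -> %s\n", x$p_corr,
              if (x$reject) "REJECT null" else "retain null"))
  invisible(x)
}

#' Node-level MTPC with correction across regions
#'
#' As [mtpc()], but the permutation null maximum is taken across nodes as
#' well as thresholds, so one shared `f_crit` and `a_crit` correct for the
#' additional multiplicity of testing every region. Each node's clusters
#' are then evaluated against the shared critical values. With a single
#' node this reduces exactly to [mtpc()].
#'
#' @param curves A `nodal_curves` object from
#'   `metric_curves(..., level = "nodal")`.
#' @param design A [design_spec()].
#' @param nodes Optional subset of node indices to test (default all).
#' @return Object of class `mtpc_nodewise_result`: shared `f_crit`,
#'   `a_crit`, `null_max`, and `results`, a list of per-node
#'   `mtpc_result` objects.
#' @export
mtpc_nodewise <- function(curves, design, nodes = NULL) {
  stopifnot(inherits(curves, "nodal_curves"), inherits(design, "design_spec"))
  d <- dim(curves$values)
  if (d[1] != length(design$g)) {
    stop("curves subjects must match design subjects", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- seq_len(d[3])
  taus_full <- curves$thresholds
  # per-node usable thresholds: finite for all subjects and non-constant
  keep <- matrix(FALSE, d[2], length(nodes))
  for (jj in seq_along(nodes)) {
    v <- curves$values[, , nodes[jj], drop = FALSE]
    keep[, jj] <- apply(v[, , 1, drop = FALSE], 2, function(col)
      all(is.finite(col)) && var(col) > 0)
  }
  if (any(colSums(keep) < 2)) {
    stop("some nodes have fewer than 2 usable thresholds", call. = FALSE)
  }
  # stack usable (threshold, node) columns into one response matrix
  cols <- do.call(rbind, lapply(seq_along(nodes), function(jj) {
    data.frame(node = jj, t = which(keep[, jj]))
  }))
  y <- matrix(NA_real_, d[1], nrow(cols))
  for (r in seq_len(nrow(cols))) {
    y[, r] <- curves$values[, cols$t[r], nodes[cols$node[r]]]
  }
  perms <- .perm_matrix(design)
  fc <- .f_curves(y, design, perms)
  null_max <- apply(fc$f_perm, 1, function(v) max(v[is.finite(v)]))
  f_crit <- quantile(null_max, 1 - design$alpha, type = 7, names = FALSE)
  # a_crit: per permutation, max supra-critical cluster AUC across all nodes
  perm_max_auc <- vapply(seq_len(nrow(fc$f_perm)), function(i) {
    best <- 0
    for (jj in seq_along(nodes)) {
      sel <- cols$node == jj
      a <- .clusters_auc(fc$f_perm[i, sel], f_crit, taus_full[cols$t[sel]])$auc
      if (length(a)) best <- max(best, max(a))
    }
    best
  }, 0)
  a_crit <- mean(perm_max_auc)
  results <- lapply(seq_along(nodes), function(jj) {
    sel <- cols$node == jj
    res <- .mtpc_decide(fc$f_obs[sel], taus_full[cols$t[sel]], f_crit,
                        a_crit, null_max, design$n_perm)
    res$null_max <- NULL
    res$metric <- curves$metric
    res$node <- nodes[jj]
    res$region_label <- curves$region_labels[nodes[jj]]
    structure(res, class = "mtpc_result")
  })
  names(results) <- curves$region_labels[nodes]
  structure(
    list(metric = curves$metric, f_crit = f_crit, a_crit = a_crit,
         null_max = null_max, results = results, alpha = design$alpha,
         n_perm = design$n_perm),
    class = "mtpc_nodewise_result"
  )
}

#' @export
print.mtpc_nodewise_result <- function(x, ...) {
  rej <- vapply(x$results, function(r) r$reject, TRUE)
  cat(sprintf(
    "<mtpc_nodewise_result> %s: %d nodes tested, shared F_crit = %.3f, %d rejected\n",
    x$metric, length(x$results), x$f_crit, sum(rej)))
  if (any(rej)) cat("  rejected:", paste(names(x$results)[rej], collapse = ", "), "\n")
  invisible(x)
}

#' Summarize an MTPC result as a one-row data frame
#'
#' @param res An `mtpc_result`.
#' @return Data frame with the headline quantities.
#' @export
mtpc_summary <- function(res) {
  stopifnot(inherits(res, "mtpc_result"))
  data.frame(
    metric = res$metric %||% NA_character_,
    node = if (is.null(res$node)) NA_integer_ else res$node,
    f_mtpc = res$f_mtpc, tau_mtpc = res$tau_mtpc, f_crit = res$f_crit,
    a_mtpc = if (length(res$a_mtpc)) max(res$a_mtpc) else 0,
    a_crit = res$a_crit, p_corr = res$p_corr, reject = res$reject
  )
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's chi-squared without continuity correction, as used for the
#' cohort's gender and handedness comparisons.
#'
#' @param table An r x c matrix of counts.
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
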