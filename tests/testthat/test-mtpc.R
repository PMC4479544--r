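make_design <- function(n_per = 15, seed = 1, n_perm = 100, alpha = 0.05) {
  set.seed(seed)
  n <- 2 * n_per
  design_spec(
    group = rep(c("control", "PE"), each = n_per),
    age = rnorm(n, 20, 0.3),
    gender = sample(c("male", "female"), n, TRUE),
    handedness = sample(c("right", "left", "none"), n, TRUE, c(.7, .1, .2)),
    alpha = alpha, n_perm = n_perm, seed = seed
  )
}

test_that("ancova_f matches nested-model anova and handles degenerate input", {
  d <- make_design(20, seed = 3)
  set.seed(4)
  y <- rnorm(40) + 2 * d$g + 0.5 * d$x0[, "age"]
  res <- ancova_f(y, d)
  # independent route: extra-sum-of-squares F from two lm fits
  df <- data.frame(y = y, g = d$group, d$x0[, -1])
  full <- lm(y ~ ., data = df)
  red <- lm(y ~ . - g, data = df)
  ref <- anova(red, full)
  expect_equal(res$f, ref$F[2], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[2], tolerance = 1e-10)

  expect_equal(ancova_f(rep(3.14, 40), d)$f, 0)

  # strongly separated groups with orthogonal covariates -> very large F
  y2 <- ifelse(d$g == 1, 10, 0) + rnorm(40)
  expect_gt(ancova_f(y2, d)$f, 100)
})

test_that("design_spec validates inputs and flags collinearity", {
  expect_error(make_design(1), "at least 2")
  d <- make_design(10)
  expect_error(design_spec(d$group, rep(20, 20), rep("male", 20),
                           rep("right", 20), alpha = 0.7), "alpha")
  expect_error(design_spec(d$group, rnorm(20, 20), sample(c("male", "female"), 20, TRUE),
                           rep("right", 20), n_perm = 10), "n_perm")
})

test_that("posthoc t squares to the ANCOVA F and reports direction", {
  d <- make_design(12, seed = 5)
  set.seed(6)
  y <- rnorm(24) - 1.5 * d$g
  fa <- ancova_f(y, d)
  tt <- posthoc_t(y, d, tau = 3)
  expect_equal(tt$t^2, fa$f, tolerance = 1e-9)
  expect_equal(tt$direction, "PE < control")
  expect_equal(tt$tau, 3)
  y0 <- rnorm(24)
  y0 <- y0 - ave(y0, d$group) # equal group means after adjustment baseline
  expect_lt(abs(posthoc_t(y0, d)$t), 1.5)
})

test_that("parametric p-values are uniform under the null design", {
  d <- make_design(15, seed = 8)
  set.seed(9)
  ps <- replicate(400, ancova_f(rnorm(30), d)$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mtpc is deterministic, returns coherent structure, and matches invariants", {
  co <- small_cohort(c(12, 12), n_regions = 10, seed = 21)
  cv <- metric_curves(co, 0:4, metrics = "density")$density
  d <- design_spec(co, n_perm = 150, seed = 33)
  r1 <- mtpc(cv, d)
  r2 <- mtpc(cv, d)
  expect_identical(r1, r2)
  expect_s3_class(r1, "mtpc_result")
  expect_gte(r1$f_crit, 0)
  expect_equal(length(r1$null_max), 150)
  expect_true(r1$p_corr > 0 && r1$p_corr <= 1)
  # decision rule invariant: reject <=> max cluster AUC exceeds critical AUC
  expect_equal(r1$reject,
               length(r1$a_mtpc) > 0 && max(r1$a_mtpc) > r1$a_crit)
  expect_error(mtpc(metric_curve(cv$values[, 1, drop = FALSE], 0, "density"), d),
               "thresholds")
})

test_that("mtpc rejects a planted group gap with minimal corrected p", {
  co <- small_cohort(c(15, 15), n_regions = 10, seed = 10)
  cv <- metric_curves(co, 0:4, metrics = "density")$density
  # inject a large gap at every threshold for the PE rows
  pe <- co$subjects$group == "PE"
  cv$values[pe, ] <- cv$values[pe, ] + 0.4
  d <- design_spec(co, n_perm = 200, seed = 11)
  res <- mtpc(cv, d)
  expect_true(res$reject)
  expect_lte(res$p_corr, 1 / 201 + 1e-12)
  expect_gt(length(res$clusters), 0)
})

test_that("node-level correction reduces to mtpc for a single node and is conservative", {
  co <- small_cohort(c(12, 12), n_regions = 8, seed = 14)
  nod <- metric_curves(co, 0:4, level = "nodal", metrics = "degree")$degree
  d <- design_spec(co, n_perm = 120, seed = 15)
  one <- mtpc_nodewise(nod, d, nodes = 3)
  cv <- metric_curve(nod$values[, , 3], nod$thresholds, "degree",
                     subject_ids = nod$subject_ids)
  ref <- mtpc(cv, d)
  r <- one$results[[1]]
  expect_equal(r$f_observed, ref$f_observed)
  expect_equal(one$f_crit, ref$f_crit)
  expect_equal(one$a_crit, ref$a_crit)
  expect_equal(r$p_corr, ref$p_corr)
  expect_equal(r$reject, ref$reject)

  # shared max over nodes can only raise the critical value
  all_nodes <- mtpc_nodewise(nod, d)
  expect_gte(all_nodes$f_crit, one$f_crit)
})

test_that("nodewise mtpc localizes an effect planted at one node", {
  co <- small_cohort(c(20, 20), n_regions = 8, seed = 18)
  nod <- metric_curves(co, 0:3, level = "nodal", metrics = "nodal_efficiency")$nodal_efficiency
  pe <- co$subjects$group == "PE"
  nod$values[pe, , 5] <- nod$values[pe, , 5] * 0.5 - 0.3 # strong effect at node 5
  d <- design_spec(co, n_perm = 150, seed = 19)
  res <- mtpc_nodewise(nod, d)
  rej <- vapply(res$results, function(r) r$reject, TRUE)
  expect_true(rej[5])
  expect_lte(sum(rej[-5]), 1)
})

test_that("chi-squared contingency matches hand-computed and degenerate cases", {
  # by-hand expected counts: all marginals 30, expected 15 -> sum 4*(25/15)
  res <- chi_square_contingency(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # identical column proportions -> 0
  expect_equal(chi_square_contingency(matrix(c(10, 30, 20, 60), 2, 2))$statistic, 0)
  expect_error(chi_square_contingency(matrix(c(0, 0, 5, 3), nrow = 2, byrow = TRUE)),
               "marginal")
  # agreement with a Monte-Carlo permutation null
  tab <- matrix(c(95, 105, 115, 85), 2, 2)
  res2 <- chi_square_contingency(tab)
  set.seed(1)
  mc <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 4000)
  expect_lt(abs(res2$p - mc$p.value), 0.03)
})

test_that("the residual-permutation scheme is deterministic and calibrated like label permutation", {
  co <- small_cohort(c(15, 15), n_regions = 10, seed = 23)
  cv <- metric_curves(co, 0:3, metrics = "density")$density
  d_fl <- design_spec(co, n_perm = 150, seed = 24, scheme = "freedman_lane")
  r1 <- mtpc(cv, d_fl)
  r2 <- mtpc(cv, d_fl)
  expect_identical(r1, r2)
  # observed F does not depend on the permutation scheme
  d_lab <- design_spec(co, n_perm = 150, seed = 24)
  expect_equal(r1$f_observed, mtpc(cv, d_lab)$f_observed)
  # with balanced covariates the two null criticals are close
  expect_equal(r1$f_crit, mtpc(cv, d_lab)$f_crit, tolerance = 0.5)
})
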