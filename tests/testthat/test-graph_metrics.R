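complete_net <- function(n) make_net(matrix(1, n, n) - diag(n))
path3 <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3))))
star4 <- make_net(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))

test_that("density, efficiency and path length match hand-computed values", {
  expect_equal(net_density(complete_net(4)), 1)
  expect_equal(net_density(make_net(matrix(0, 4, 4))), 0)
  path4 <- make_net(adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4))))
  expect_equal(net_density(path4), 0.5)

  expect_equal(global_efficiency(complete_net(5)), 1)
  expect_equal(global_efficiency(path3), 5 / 6) # pairs: 1,1,1,1,1/2,1/2
  expect_equal(global_efficiency(make_net(matrix(0, 3, 3))), 0)

  expect_equal(char_path_length(complete_net(5)), 1)
  expect_equal(char_path_length(path3), 4 / 3)
  # two disconnected dyads: only reachable pairs counted
  dyads <- make_net(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  expect_equal(char_path_length(dyads), 1)
  d <- net_distances(dyads)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  expect_warning(cpl <- char_path_length(make_net(matrix(0, 3, 3))), "undefined")
  expect_true(is.na(cpl))
})

test_that("nodal efficiency matches pair enumeration", {
  expect_equal(nodal_efficiency(star4)[1], 1)
  expect_equal(nodal_efficiency(path3)[1], (1 + 0.5) / 2) # leaf of 1-2-3
  iso <- make_net(adj_from_edges(3, list(c(1, 2))))
  expect_equal(nodal_efficiency(iso)[3], 0)
  # global efficiency is the mean of nodal efficiencies
  set.seed(2)
  a <- random_adj(7, 0.4)
  expect_equal(mean(nodal_efficiency(make_net(a))),
               global_efficiency(make_net(a)))
})

test_that("clustering and betweenness match direct counting", {
  tri <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3))))
  expect_equal(clustering_coef(tri), rep(1, 3))
  expect_equal(clustering_coef(star4), rep(0, 4))
  # kite: triangle 1-2-3 plus pendant 4 on node 1
  kite <- make_net(adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(1, 4))))
  expect_equal(clustering_coef(kite), c(1 / 3, 1, 1, 0))

  expect_equal(betweenness_centrality(star4), c(1, 0, 0, 0))
  expect_equal(betweenness_centrality(path3), c(0, 1, 0))
  expect_equal(betweenness_centrality(complete_net(5)), rep(0, 5))
})

test_that("all metrics agree with brute-force oracles on random small graphs", {
  set.seed(202)
  for (i in 1:150) {
    n <- sample(3:6, 1)
    a <- random_adj(n, runif(1, 0.2, 0.9))
    net <- make_net(a)
    expect_equal(net_density(net), oracle_density(a))
    expect_equal(net_distances(net), oracle_distances(a), ignore_attr = TRUE)
    expect_equal(global_efficiency(net), oracle_global_efficiency(a))
    expect_equal(suppressWarnings(char_path_length(net)),
                 oracle_char_path_length(a))
    expect_equal(clustering_coef(net), oracle_clustering(a))
    expect_equal(betweenness_centrality(net), oracle_betweenness(a),
                 tolerance = 1e-12)
  }
})

test_that("metrics respect their bounds and monotonicity properties", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    net <- make_net(random_adj(n, runif(1, 0.1, 0.9)))
    expect_true(net_density(net) >= 0 && net_density(net) <= 1)
    ge <- global_efficiency(net)
    expect_true(ge >= 0 && ge <= 1)
    cc <- clustering_coef(net)
    expect_true(all(cc >= 0 & cc <= 1))
    bc <- betweenness_centrality(net)
    expect_true(all(bc >= 0 & bc <= 1))
    deg <- nodal_metrics(net)$degree
    expect_true(all(deg >= 0 & deg <= n - 1))
  }
  # global efficiency is monotone non-increasing under edge deletion
  set.seed(10)
  a <- random_adj(9, 0.5)
  ge_full <- global_efficiency(make_net(a))
  edges <- which(upper.tri(a) & a == 1)
  for (e in edges[seq_len(min(5, length(edges)))]) {
    a2 <- a
    a2[e] <- 0
    a2 <- a2 * upper.tri(a2) + t(a2 * upper.tri(a2))
    expect_lte(global_efficiency(make_net(a2)), ge_full + 1e-12)
  }
})

test_that("analytic random-graph references evaluate the closed forms", {
  ref <- random_reference(n = 100, mean_degree = 10)
  expect_equal(ref$l_rand, (log(100) - 0.5772156649) / log(10) + 0.5,
               tolerance = 1e-9)
  expect_equal(ref$l_rand, 2.2493, tolerance = 1e-4)
  expect_equal(ref$c_rand, 10 / 99)
  expect_error(random_reference(100, 1), "mean degree")
})

test_that("smallworldness is ~1 for random graphs and large for ring lattices", {
  set.seed(77)
  s_vals <- replicate(12, {
    smallworldness(make_net(random_adj(120, 0.12)))$smallworldness
  })
  expect_equal(mean(s_vals), 1, tolerance = 0.1)

  # ring lattice: each node connected to 3 neighbours either side
  n <- 100; k <- 3
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in 1:k) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  sw <- smallworldness(make_net(a))
  expect_gt(sw$smallworldness, 2)
  # mean degree <= 1 leaves the analytic reference undefined
  sparse <- make_net(adj_from_edges(6, list(c(1, 2), c(3, 4))))
  expect_error(smallworldness(sparse), "mean degree")
  expect_true(is.na(global_metrics(sparse, "smallworldness")$smallworldness))
})

test_that("modularity finds the two-clique partition and respects bounds", {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1
  a[5:8, 5:8] <- 1
  diag(a) <- 0
  res <- modularity_q(make_net(a))
  expect_equal(res$q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_true(all(res$membership[1:4] == res$membership[1]))

  km <- modularity_q(complete_net(6))
  expect_lt(km$q, 1e-9)
  expect_error(modularity_q(make_net(matrix(0, 4, 4))), "empty")
  set.seed(12)
  for (i in 1:10) {
    q <- modularity_q(make_net(random_adj(10, 0.4)))$q
    expect_true(q <= 1 && q >= -0.5)
  }
})

test_that("metric_curves produces aligned grids with expected structure", {
  co <- small_cohort(c(4, 4), n_regions = 10)
  curves <- metric_curves(co, 0:2, metrics = c("density", "global_efficiency"))
  expect_named(curves, c("density", "global_efficiency"))
  expect_equal(dim(curves$density$values), c(8, 3))
  # density curves non-increasing in tau for every subject
  expect_true(all(t(apply(curves$density$values, 1, diff)) <= 0))
  # identical matrices for all subjects -> zero between-subject variance
  co2 <- co
  for (i in seq_along(co2$matrices)) co2$matrices[[i]]$counts <- co$matrices[[1]]$counts
  cv2 <- metric_curves(co2, 0:2, metrics = "density")
  expect_equal(apply(cv2$density$values, 2, var), rep(0, 3))

  nod <- metric_curves(co, 0:2, level = "nodal", metrics = c("degree", "betweenness"))
  expect_equal(dim(nod$degree$values), c(8, 3, 10))
  df <- curves_to_df(curves)
  expect_equal(nrow(df), 2 * 8 * 3)
  expect_true(all(is.na(df$node)))
})
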