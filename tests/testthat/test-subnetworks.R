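test_that("overlap_mask applies the inclusive proportional-overlap rule", {
  fx <- generate_volume_fixtures(c(3, 1, 1), c(4, 5, 1),
                                 supra_fractions = c(0.2, 0.5, 0.9))
  def <- overlap_mask(fx$labels, fx$map, z_thresh = 4, min_frac = 0.5)
  expect_equal(def$nodes, c(2L, 3L)) # 0.5 included by the >= rule
  # fully supra region always included
  fx2 <- generate_volume_fixtures(c(2, 1, 1), c(2, 2, 2),
                                  supra_fractions = c(1, 0))
  expect_equal(overlap_mask(fx2$labels, fx2$map)$nodes, 1L)
  # monotone in z threshold: raising z never adds regions
  lo <- overlap_mask(fx$labels, fx$map, z_thresh = 2)$nodes
  hi <- overlap_mask(fx$labels, fx$map, z_thresh = 7)$nodes
  expect_true(all(hi %in% lo))
  # region with zero voxels excluded with a warning
  lab <- label_volume(array(c(1, 1, 1, 1), c(4, 1, 1)), c("A", "B"))
  mp <- stat_map_volume(array(8, c(4, 1, 1)))
  expect_warning(d2 <- overlap_mask(lab, mp), "zero voxels")
  expect_equal(d2$nodes, 1L)
})

test_that("derive_dmn weights maps by PCC activity and sums them", {
  fx <- generate_volume_fixtures(c(2, 2, 1), c(4, 4, 1),
                                 supra_fractions = c(1, 0.5, 0.25, 0))
  # single map: weight rescales values but not the induced node set when the
  # threshold scales accordingly; with weight 1 it is identical
  one <- derive_dmn(list(fx$map), fx$labels, pcc_region = 1,
                    z_thresh = 4 * mean(fx$map$voxels[fx$labels$voxels == 1]))
  ref <- overlap_mask(fx$labels, fx$map, z_thresh = 4)
  expect_equal(one$nodes, ref$nodes)
  # two maps with PCC means w and 0: result equals the first scaled by w
  m1 <- fx$map
  m2 <- stat_map_volume(fx$map$voxels * 0) # zero map, zero PCC weight
  w <- mean(m1$voxels[fx$labels$voxels == 1])
  both <- derive_dmn(list(m1, m2), fx$labels, pcc_region = 1,
                     z_thresh = 4 * w)
  expect_equal(both$nodes, ref$nodes)
  expect_equal(both$name, "DMN")
  expect_error(derive_dmn(list(m1), fx$labels, pcc_region = 99), "PCC")
})

test_that("induced subgraphs preserve counts and commute with binarization", {
  co <- tiny_cohort()
  m <- co$matrices[[1]]
  full <- subnetwork_definition("all", 1:4)
  expect_identical(induced_subgraph_matrix(m, full)$counts, m$counts)
  def <- subnetwork_definition("sub", c(1, 2, 4))
  sub <- induced_subgraph_matrix(m, def)
  expect_identical(unname(sub$counts), unname(m$counts[c(1, 2, 4), c(1, 2, 4)]))
  expect_identical(sub$region_labels, m$region_labels[c(1, 2, 4)])
  # binarize-then-induce equals induce-then-binarize
  tau <- 2
  b_then_i <- threshold_binarize(m, tau)$adjacency[def$nodes, def$nodes]
  i_then_b <- threshold_binarize(sub, tau)$adjacency
  expect_equal(unname(b_then_i), unname(i_then_b))
  expect_error(induced_subgraph_matrix(m, subnetwork_definition("x", 1)),
               "at least 2")
})

test_that("node-set files round-trip and resolve labels", {
  labs <- paste0("region_", 1:6)
  def <- subnetwork_definition("rich_club", c(2, 3, 5), labs)
  path <- withr::local_tempfile(fileext = ".txt")
  write_node_set(def, path)
  back <- read_node_set(path, labs, name = "rich_club")
  expect_equal(back$nodes, def$nodes)
  writeLines(c("# comment", "region_2", "region_9"), path)
  expect_error(read_node_set(path, labs), "region_9")
})

test_that("subnetwork analysis matches whole-network analysis on the full node set", {
  co <- small_cohort(c(10, 10), n_regions = 9, seed = 51)
  d <- design_spec(co, n_perm = 100, seed = 52)
  full_def <- subnetwork_definition("whole", seq_len(9))
  sub <- subnetwork_analysis(co, list(full_def), d, thresholds = 0:3,
                             metrics = "density")
  ref <- mtpc(metric_curves(co, 0:3, metrics = "density")$density, d)
  expect_equal(sub$whole$density$f_observed, ref$f_observed)
  expect_equal(sub$whole$density$p_corr, ref$p_corr)
  expect_equal(sub$whole$density$reject, ref$reject)
  summ <- attr(sub, "summary")
  expect_equal(nrow(summ), 1)
  expect_equal(summ$subnetwork, "whole")
})

test_that("an effect confined to one subnetwork is flagged there, not elsewhere", {
  co <- generate_cohort(cohort_spec(
    n_per_group = c(25, 25), n_regions = 12, n_modules = 3,
    effect_density = 0.5, effect_nodes = 1:4, seed = 55))
  d <- design_spec(co, n_perm = 150, seed = 56)
  inside <- subnetwork_definition("inside", 1:4)
  outside <- subnetwork_definition("outside", 9:12)
  res <- subnetwork_analysis(co, list(inside, outside), d,
                             thresholds = 0:3, metrics = "density")
  expect_true(res$inside$density$reject)
  expect_false(res$outside$density$reject)
})

test_that("volumes round-trip through NIfTI", {
  fx <- generate_volume_fixtures(c(2, 1, 1), c(3, 3, 3),
                                 supra_fractions = c(1 / 3, 1))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "labels.nii.gz")
  p2 <- file.path(dir, "map.nii.gz")
  write_volume(fx$labels, p1)
  write_volume(fx$map, p2)
  lab2 <- read_volume(p1, "labels", region_labels = fx$labels$region_labels)
  map2 <- read_volume(p2, "map")
  expect_equal(as.vector(lab2$voxels), as.vector(fx$labels$voxels))
  expect_equal(as.vector(map2$voxels), as.vector(fx$map$voxels))
  d1 <- overlap_mask(fx$labels, fx$map)
  d2 <- overlap_mask(lab2, map2)
  expect_equal(d1$nodes, d2$nodes)
})

test_that("packaged atlas resources resolve consistently", {
  labs <- aal116_labels()
  expect_length(labs, 116)
  expect_true(all(c("Precuneus_L", "Cingulum_Post_R", "Vermis_10") %in% labs))
  rc <- rich_club_definition()
  expect_s3_class(rc, "subnetwork_definition")
  expect_gte(length(rc$nodes), 3)
  expect_true(all(rc$nodes >= 1 & rc$nodes <= 116))
})
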