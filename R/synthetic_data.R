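# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: modular random connectomes with overdispersed streamline counts,
# group-balanced covariates, and a tunable group effect on edge probability.

#' Specification of a synthetic connectome cohort
#'
#' Defaults emulate the study design the package targets: two groups of
#' 123 (PE) and 125 (control) subjects, 116 atlas regions with a modular
#' block structure, streamline counts that are heavy-tailed so that the
#' 0-20 threshold sweep spans network densities of roughly 0.03-0.12, and
#' covariates (age about 20 years, gender and handedness proportions as in
#' a young population cohort) sampled identically in both groups.
#'
#' @param n_per_group Length-2 counts, `c(PE, control)` (default 123/125).
#' @param n_regions Number of atlas regions (default 116).
#' @param n_modules Number of blocks in the modular structure (default 6).
#' @param base_within_p Edge probability within a module (default 0.35).
#' @param base_between_p Edge probability between modules (default 0.08).
#' @param count_mean Mean streamline count on existing edges (default 15).
#' @param count_dispersion Negative-binomial size parameter of the count
#'   distribution; smaller is more overdispersed (default 1, geometric).
#' @param effect_density Multiplicative reduction of edge probability in
#'   the PE group: PE edges form with probability
#'   `(1 - effect_density) * p`. 0 is the null (default).
#' @param effect_nodes Optional node indices confining the effect to edges
#'   incident to these nodes (default: all edges).
#' @param covariate_effects Named list of slopes `age`, `gender`,
#'   `handedness` applied to the log edge probability (defaults all 0 so
#'   tests isolate the group factor).
#' @param seed Random seed (default 42).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(123, 125), n_regions = 116,
                        n_modules = 6, base_within_p = 0.35,
                        base_between_p = 0.08, count_mean = 15,
                        count_dispersion = 1, effect_density = 0,
                        effect_nodes = NULL,
                        covariate_effects = list(age = 0, gender = 0,
                                                 handedness = 0),
                        seed = 42) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2), n_regions >= 2,
            n_modules >= 1, base_within_p >= 0, base_within_p <= 1,
            base_between_p >= 0, base_between_p <= 1,
            effect_density >= 0, effect_density <= 1, count_mean >= 1)
  if (base_within_p == 0 && base_between_p == 0) {
    stop("degenerate spec: no edges possible", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
         n_modules = as.integer(n_modules), base_within_p = base_within_p,
         base_between_p = base_between_p, count_mean = count_mean,
         count_dispersion = count_dispersion, effect_density = effect_density,
         effect_nodes = effect_nodes, covariate_effects = covariate_effects,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# covariate sampling proportions for a young population cohort
.P_FEMALE <- 0.65
.P_HANDEDNESS <- c(right = 0.74, left = 0.07, none = 0.19)

#' Generate a synthetic cohort
#'
#' Per subject, a modular random adjacency is drawn (within-/between-module
#' edge probabilities); in the PE group the probability of edges incident
#' to `effect_nodes` (all edges when unset) is multiplied by
#' `(1 - effect_density)`. Existing edges receive streamline counts
#' `1 + NegBin(mean = count_mean - 1, size = count_dispersion)`. Covariates
#' are sampled with the same distributions in both groups; nonzero
#' `covariate_effects` slopes scale the log edge probability.
#'
#' The same spec (including seed) always regenerates an identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort_data()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_pe <- spec$n_per_group[1]
  n_ct <- spec$n_per_group[2]
  n <- n_pe + n_ct
  R <- spec$n_regions
  module <- ceiling(seq_len(R) / (R / spec$n_modules))
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  within <- module[ut[, 1]] == module[ut[, 2]]
  base_p <- ifelse(within, spec$base_within_p, spec$base_between_p)
  affected <- if (is.null(spec$effect_nodes)) {
    rep(TRUE, nrow(ut))
  } else {
    ut[, 1] %in% spec$effect_nodes | ut[, 2] %in% spec$effect_nodes
  }
  labels <- paste0("region_", seq_len(R))
  with_seed(spec$seed, {
    group <- rep(c("PE", "control"), c(n_pe, n_ct))
    age <- rnorm(n, mean = 20.07, sd = 0.25)
    gender <- ifelse(runif(n) < .P_FEMALE, "female", "male")
    handedness <- sample(names(.P_HANDEDNESS), n, replace = TRUE,
                         prob = .P_HANDEDNESS)
    ce <- spec$covariate_effects
    mats <- vector("list", n)
    for (s in seq_len(n)) {
      p <- base_p
      if (group[s] == "PE" && spec$effect_density > 0) {
        p <- ifelse(affected, p * (1 - spec$effect_density), p)
      }
      lp <- (ce$age %||% 0) * (age[s] - 20.07) +
        (ce$gender %||% 0) * (gender[s] == "female") +
        (ce$handedness %||% 0) * (handedness[s] != "right")
      if (lp != 0) p <- pmin(p * exp(lp), 1)
      edge <- runif(nrow(ut)) < p
      cnt_ut <- numeric(nrow(ut))
      ne <- sum(edge)
      if (ne) {
        cnt_ut[edge] <- 1 + rnbinom(ne, mu = spec$count_mean - 1,
                                    size = spec$count_dispersion)
      }
      counts <- matrix(0, R, R)
      counts[ut] <- cnt_ut
      counts <- counts + t(counts)
      mats[[s]] <- stream_matrix(counts, labels,
                                 subject_id = sprintf("sub%03d", s))
    }
    subjects <- data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = group, age = age, gender = gender, handedness = handedness,
      stringsAsFactors = FALSE
    )
    cohort_data(subjects, mats)
  })
}

#' Generate aligned label and statistical-map volume fixtures
#'
#' Tiles a small 3-D grid with cuboid regions and sets, for each region,
#' exactly the requested fraction of its voxels above the default map
#' threshold. Used to exercise the subnetwork-derivation operations with
#' exactly known proportional overlaps.
#'
#' @param region_grid Length-3 counts of regions along each axis (the
#'   number of regions is their product).
#' @param region_dim Length-3 voxel extent of each cuboid region
#'   (default `c(4, 4, 4)`).
#' @param supra_fractions Per-region fractions of voxels to place above
#'   threshold; each `fraction * prod(region_dim)` must be an integer.
#' @param z_supra Map value assigned to supra-threshold voxels
#'   (default 8, comfortably above the usual `z > 4` threshold); all other
#'   voxels are 0.
#' @return List with `labels` (a [label_volume()]) and `map`
#'   (a [stat_map_volume()]).
#' @export
generate_volume_fixtures <- function(region_grid, region_dim = c(4, 4, 4),
                                     supra_fractions, z_supra = 8) {
  stopifnot(length(region_grid) == 3, length(region_dim) == 3)
  n_regions <- prod(region_grid)
  if (length(supra_fractions) != n_regions) {
    stop("need one supra fraction per region (", n_regions, ")", call. = FALSE)
  }
  if (any(supra_fractions < 0 | supra_fractions > 1)) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  nvox <- prod(region_dim)
  k <- supra_fractions * nvox
  if (any(abs(k - round(k)) > 1e-9)) {
    bad <- which(abs(k - round(k)) > 1e-9)[1]
    stop(sprintf(
      "region %d is too small to realize fraction %g exactly (%g voxels)",
      bad, supra_fractions[bad], k[bad]), call. = FALSE)
  }
  k <- round(k)
  dims <- region_grid * region_dim
  lab <- array(0L, dims)
  map <- array(0, dims)
  r <- 0L
  for (kz in seq_len(region_grid[3])) for (ky in seq_len(region_grid[2])) {
    for (kx in seq_len(region_grid[1])) {
      r <- r + 1L
      xs <- (kx - 1) * region_dim[1] + seq_len(region_dim[1])
      ys <- (ky - 1) * region_dim[2] + seq_len(region_dim[2])
      zs <- (kz - 1) * region_dim[3] + seq_len(region_dim[3])
      lab[xs, ys, zs] <- r
      if (k[r] > 0) {
        block <- array(0, region_dim)
        block[seq_len(k[r])] <- z_supra
        map[xs, ys, zs] <- block
      }
    }
  }
  list(labels = label_volume(lab, paste0("region_", seq_len(n_regions))),
       map = stat_map_volume(map))
}
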