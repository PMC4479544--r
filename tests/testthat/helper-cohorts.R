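# Small synthetic cohorts shared across test files.

small_cohort <- function(n_per_group = c(10, 10), n_regions = 12,
                         effect_density = 0, seed = 7, ...) {
  generate_cohort(cohort_spec(
    n_per_group = n_per_group, n_regions = n_regions, n_modules = 3,
    effect_density = effect_density, seed = seed, ...))
}

# a cohort whose matrices are handcrafted (not random), for I/O tests
tiny_cohort <- function() {
  labs <- c("A", "B", "C", "D")
  base <- matrix(0, 4, 4)
  base[upper.tri(base)] <- c(5, 0, 2, 7, 1, 3)
  base <- base + t(base)
  mats <- lapply(1:4, function(i) {
    stream_matrix(base + (base > 0) * (i - 1), labs, paste0("s", i))
  })
  subjects <- data.frame(
    subject_id = paste0("s", 1:4),
    group = c("PE", "PE", "control", "control"),
    age = c(20.1, 19.9, 20.0, 20.2),
    gender = c("male", "female", "female", "male"),
    handedness = c("right", "left", "right", "none")
  )
  cohort_data(subjects, mats)
}
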