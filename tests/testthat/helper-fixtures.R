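# Shared fixtures. Expensive objects are memoized for the test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A clean, sparse rendering regime for orientation work: many long thin
# fibers, no background noise.
phantom_params <- function(k, seed, mu = 45, n_fibers = 60) {
  fiber_class_params("normal", n_fibers = n_fibers, length_mean = 200,
                     length_sd = 30, width_mean = 2.5, dispersion_k = k,
                     mean_orientation = mu, noise_sd = 0,
                     background_level = 0, seed = seed)
}

# Reduced cohort for fast integration tests: 4+3+3 samples, 128 px images,
# geometry scaled to the smaller field of view.
small_presets <- function() {
  scale_p <- function(p, f = 4) {
    p$n_fibers <- max(4L, as.integer(p$n_fibers / f))
    p$length_mean <- p$length_mean / f
    p$length_sd <- p$length_sd / f
    p
  }
  lapply(fiber_class_presets(),
         function(ch) lapply(ch, scale_p))
}

small_design <- function(seed = 11L) {
  cohort_design(n_scar_sections = 4L, n_normal_sections = 4L,
                n_adjacent_specimens = 3L, regions_min = 2L,
                regions_max = 2L, image_size = 128L,
                presets = small_presets(), master_seed = seed)
}

small_feature_table <- function() {
  fixture("small_feature_table", function() {
    cohort_feature_table(generate_cohort(small_design()))
  })
}

# Full default-design cohort (the study-scale conditions); used by the
# acceptance suite.
default_cohort <- function() {
  fixture("default_cohort", function() {
    generate_cohort(cohort_design(master_seed = 20260L))
  })
}

default_feature_table <- function() {
  fixture("default_feature_table", function() {
    cohort_feature_table(default_cohort())
  })
}

random_feature_table <- function(n = 20, p = 6, seed = 1) {
  withr::with_seed(seed, {
    tab <- tibble::as_tibble(
      stats::setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                      sprintf("f%02d", seq_len(p))))
    tab$class_label <- sample(rep(c("normal", "scar"), length.out = n))
    tab$sample_id <- sprintf("s%02d", seq_len(n))
    tab
  })
}
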