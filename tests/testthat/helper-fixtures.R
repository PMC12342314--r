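# Shared fixture builders (all generated in code at test time).

# Pooled homogeneous-Poisson trial sets over the analysis window.
poisson_trials <- function(n_trials, rate, window = c(-75, 250)) {
  replicate(n_trials, {
    n <- stats::rpois(1, rate * diff(window) / 1000)
    sort(stats::runif(n, window[1], window[2]))
  }, simplify = FALSE)
}

# FRA response table with a rectangular known excitatory region.
rect_fra_responses <- function(freqs, levels, region_freqs, region_levels,
                               amplitude = 5, reps = 4, noise_sd = 0.2,
                               seed = 1) {
  withr::with_seed(seed, {
    g <- expand.grid(frequency_hz = freqs, level_db = levels,
                     rep = seq_len(reps))
    mu <- ifelse(g$frequency_hz %in% region_freqs &
                   g$level_db %in% region_levels, amplitude, 0)
    g$corrected_count <- mu + stats::rnorm(nrow(g), 0, noise_sd)
    tibble::as_tibble(g[c("frequency_hz", "level_db", "corrected_count")])
  })
}

# Small two-group cohort configuration for end-to-end tests.
two_group_config <- function(n_units = 4, seed = 11, dev_mult_exposed = 1,
                             n_subjects = 1) {
  groups <- dplyr::bind_rows(
    tibble::tibble(sex = "M", age = "adult", exposure = "control",
                   deviance_gain_mult = 1),
    tibble::tibble(sex = "M", age = "adult", exposure = "VPA",
                   deviance_gain_mult = dev_mult_exposed)
  )
  groups$n_subjects <- n_subjects
  groups$n_units <- n_units
  cohort_config(groups = groups, seed = seed)
}
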