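#' Parametric model of a tuned, adapting, deviance-sensitive neuron
#'
#' The simulator represents a single unit as an inhomogeneous-Poisson process
#' whose instantaneous rate on each trial is
#'
#' \deqn{r(t) = r_{spont} + P \cdot g(f, L) \cdot s(f, n) \cdot d \cdot k(t)}
#'
#' where `P` is the peak evoked rate, `g(f, L)` a Gaussian tuning curve in
#' log2 frequency with a saturating level term above threshold, `s(f, n)` the
#' frequency-specific adaptation state after the n-th presentation of
#' frequency `f` (`s(n) = a n^b + c`, the same power law later fitted to the
#' data), `d` the deviance gain applied when the tone is a deviant, and
#' `k(t)` a peak-normalised alpha function starting at the response latency.
#' Each frequency keeps its own presentation counter, so cascade tones adapt
#' roughly ten times more slowly per channel than an oddball standard — the
#' property that makes the cascade a repetition-free control.
#'
#' @param spontaneous_rate Spontaneous firing rate, spikes/s (>= 0).
#' @param best_frequency Centre of the tuning curve, Hz.
#' @param tuning_bandwidth Gaussian SD of the tuning curve, octaves.
#' @param threshold Minimal response threshold, dB SPL.
#' @param level_saturation dB above threshold at which the level gain reaches 1.
#' @param peak_evoked_rate Peak driven rate at full gain, spikes/s.
#' @param latency Response latency, ms.
#' @param kernel_width Alpha-function time constant, ms (time to peak).
#' @param adapt_a,adapt_b,adapt_c Power-law adaptation parameters: initial
#'   gain `a` (>= 0), decay exponent `b` (<= 0) and steady-state floor
#'   `c` (>= 0); the per-channel gain after n presentations is `a n^b + c`.
#' @param deviance_gain Multiplier applied to the evoked component of deviant
#'   tones (>= 0); 1 means no deviance sensitivity. Values below 1 reproduce
#'   the negative prediction-error indices typical of the inferior colliculus.
#' @return An object of class `"neuron_model"` (a validated named list).
#' @examples
#' nm <- neuron_model(best_frequency = 8000)
#' nm$spontaneous_rate
#' @export
neuron_model <- function(spontaneous_rate = 5,
                         best_frequency = 8000,
                         tuning_bandwidth = 1,
                         threshold = 20,
                         level_saturation = 20,
                         peak_evoked_rate = 100,
                         latency = 10,
                         kernel_width = 10,
                         adapt_a = 1,
                         adapt_b = -0.6,
                         adapt_c = 0.2,
                         deviance_gain = 0.9) {
  nm <- list(
    spontaneous_rate = spontaneous_rate, best_frequency = best_frequency,
    tuning_bandwidth = tuning_bandwidth, threshold = threshold,
    level_saturation = level_saturation, peak_evoked_rate = peak_evoked_rate,
    latency = latency, kernel_width = kernel_width,
    adapt_a = adapt_a, adapt_b = adapt_b, adapt_c = adapt_c,
    deviance_gain = deviance_gain
  )
  for (nm_field in names(nm)) stopifnot_scalar_number(nm[[nm_field]], nm_field)
  if (spontaneous_rate < 0) abort("`spontaneous_rate` must be >= 0.")
  if (peak_evoked_rate < 0) abort("`peak_evoked_rate` must be >= 0.")
  if (best_frequency <= 0) abort("`best_frequency` must be positive.")
  if (tuning_bandwidth <= 0) abort("`tuning_bandwidth` must be positive.")
  if (kernel_width <= 0) abort("`kernel_width` must be positive.")
  if (adapt_b > 0) abort("`adapt_b` must be <= 0 (non-increasing adaptation).")
  if (adapt_c < 0) abort("`adapt_c` must be >= 0.")
  if (deviance_gain < 0) abort("`deviance_gain` must be >= 0.")
  structure(nm, class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf(
    "<neuron_model: BF %.0f Hz, spont %.1f sp/s, peak %.0f sp/s, adapt (%.2g, %.2g, %.2g), dev gain %.2g>\n",
    x$best_frequency, x$spontaneous_rate, x$peak_evoked_rate,
    x$adapt_a, x$adapt_b, x$adapt_c, x$deviance_gain))
  invisible(x)
}

# Tuning gain in [0, 1]: Gaussian in log2 frequency x saturating level term.
tuning_gain <- function(neuron, frequency_hz, level_db) {
  fg <- exp(-0.5 * (log2(frequency_hz / neuron$best_frequency) / neuron$tuning_bandwidth)^2)
  lg <- pmin(1, pmax(0, (level_db - neuron$threshold) / neuron$level_saturation))
  fg * lg
}

# Power-law adaptation state after the n-th presentation of a channel,
# clipped at 0 (clip count returned via attribute).
adaptation_state <- function(neuron, n) {
  s <- neuron$adapt_a * n^neuron$adapt_b + neuron$adapt_c
  clipped <- sum(s < 0)
  s <- pmax(s, 0)
  attr(s, "n_clipped") <- clipped
  s
}

# Expected evoked spikes for a unit alpha kernel: integral of the
# peak-normalised alpha function (t/tau) exp(1 - t/tau) is tau * e (ms).
alpha_kernel_area_ms <- function(tau) tau * exp(1)

ANALYSIS_WINDOW_MS <- c(-75, 250)

#' Simulate one unit's spike trains under a stimulus sequence
#'
#' For every tone of `sequence`, draws an inhomogeneous-Poisson spike train
#' over the analysis window \[−75, 250\] ms around tone onset. Baseline
#' spikes are homogeneous at the spontaneous rate; evoked spikes are an
#' independent Poisson draw with mass set by the tuning, adaptation and
#' deviance terms of the [neuron_model()], with times distributed as the
#' alpha kernel shifted to the response latency (evoked spikes landing beyond
#' 250 ms are dropped). Adaptation counters advance per frequency channel in
#' presentation order. Negative adaptation states are clipped to zero and
#' counted in a warning.
#'
#' @param neuron A [neuron_model()].
#' @param sequence A [stim_sequence].
#' @param seed Integer seed; same (neuron, sequence, seed) reproduces the
#'   identical spike table.
#' @return A tibble with one row per spike: `tone_index`, `condition`,
#'   `frequency_hz`, `spike_time_ms` (ms relative to that tone's onset),
#'   sorted by tone and time. Tones without spikes simply contribute no rows.
#'   The expected per-tone evoked mass is attached as attribute
#'   `"evoked_mass"` (ground truth for recovery tests).
#' @export
simulate_unit <- function(neuron, sequence, seed) {
  if (!inherits(neuron, "neuron_model")) abort("`neuron` must be a <neuron_model>.")
  if (!inherits(sequence, "stim_sequence")) abort("`sequence` must be a <stim_sequence>.")
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")

  n_tones <- nrow(sequence)
  # presentation counter per frequency channel
  pres <- stats::ave(rep(1, n_tones), sequence$frequency_hz, FUN = cumsum)
  state <- adaptation_state(neuron, pres)
  if (attr(state, "n_clipped") > 0)
    warn(sprintf("%d adaptation states clipped at 0.", attr(state, "n_clipped")))
  gain <- tuning_gain(neuron, sequence$frequency_hz, sequence$level_db)
  dev_mult <- ifelse(sequence$condition == "DEV", neuron$deviance_gain, 1)
  amp <- neuron$peak_evoked_rate * gain * as.numeric(state) * dev_mult
  evoked_mass <- amp * alpha_kernel_area_ms(neuron$kernel_width) / 1000

  win <- ANALYSIS_WINDOW_MS
  base_mass <- neuron$spontaneous_rate * diff(win) / 1000

  with_local_seed(seed, {
    n_base <- rpois(n_tones, base_mass)
    n_ev <- rpois(n_tones, evoked_mass)
    base_times <- runif(sum(n_base), win[1], win[2])
    ev_times <- neuron$latency +
      rgamma(sum(n_ev), shape = 2, scale = neuron$kernel_width)
    tone_b <- rep.int(seq_len(n_tones), n_base)
    tone_e <- rep.int(seq_len(n_tones), n_ev)
    keep <- ev_times <= win[2]
    spikes <- tibble(
      tone_index = c(tone_b, tone_e[keep]),
      spike_time_ms = c(base_times, ev_times[keep])
    )
  })
  spikes <- arrange(spikes, .data$tone_index, .data$spike_time_ms)
  spikes$condition <- sequence$condition[spikes$tone_index]
  spikes$frequency_hz <- sequence$frequency_hz[spikes$tone_index]
  out <- select(spikes, "tone_index", "condition", "frequency_hz", "spike_time_ms")
  attr(out, "evoked_mass") <- evoked_mass
  out
}

#' Simulate a frequency response area
#'
#' Presents `reps` repetitions of every frequency x level combination (fresh
#' adaptation state, as in the randomly interleaved FRA protocol) and builds
#' the response-magnitude map from baseline-corrected spike counts in the
#' \[0, 180\] ms window.
#'
#' @param neuron A [neuron_model()].
#' @param freq_grid,level_grid Frequencies (Hz) and levels (dB SPL) to test.
#' @param reps Repetitions per combination (>= 1; the recording protocol used
#'   3–5).
#' @param seed Integer seed.
#' @param noiseless If `TRUE`, responses are the exact expected counts (no
#'   Poisson draw) — useful for construction-based tests.
#' @return An [fra] object (see [build_fra()]).
#' @export
simulate_fra <- function(neuron, freq_grid, level_grid, reps = 5, seed = 1,
                         noiseless = FALSE) {
  if (!inherits(neuron, "neuron_model")) abort("`neuron` must be a <neuron_model>.")
  if (length(freq_grid) == 0L || length(level_grid) == 0L)
    abort("`freq_grid` and `level_grid` must be non-empty.")
  if (reps < 1) abort("`reps` must be >= 1.")

  grid <- tidyr::expand_grid(frequency_hz = sort(unique(freq_grid)),
                             level_db = sort(unique(level_grid)),
                             rep = seq_len(reps))
  state1 <- neuron$adapt_a + neuron$adapt_c # first-presentation state
  amp <- neuron$peak_evoked_rate * state1 *
    tuning_gain(neuron, grid$frequency_hz, grid$level_db)
  mass <- amp * alpha_kernel_area_ms(neuron$kernel_width) / 1000
  # expected evoked mass inside the [0, 180] ms count window
  p_in <- stats::pgamma(180 - neuron$latency, shape = 2, scale = neuron$kernel_width)
  expected <- mass * p_in

  if (noiseless) {
    grid$corrected_count <- expected
  } else {
    win <- ANALYSIS_WINDOW_MS
    with_local_seed(seed, {
      n_ev <- rpois(nrow(grid), mass)
      ev_in <- stats::rbinom(nrow(grid), n_ev, p_in)
      n_base_in <- rpois(nrow(grid), neuron$spontaneous_rate * 0.180)
      n_base_pre <- rpois(nrow(grid), neuron$spontaneous_rate * 0.075)
    })
    baseline_hat <- n_base_pre / 0.075
    grid$corrected_count <- ev_in + n_base_in - baseline_hat * 0.180
  }
  build_fra(select(grid, "frequency_hz", "level_db", "corrected_count"))
}
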