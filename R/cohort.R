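#' Configure a synthetic recording cohort
#'
#' A cohort emulates the study design: eight experimental groups
#' (sex x age x prenatal exposure), each contributing several subjects with
#' several isolated units, every unit assigned to an inferior-colliculus
#' division (lemniscal / non-lemniscal) and a sound-level class (high >= 40
#' dB SPL / low < 40 dB SPL). Group rows carry multiplicative effects on the
#' base neuron: `spont_mult` scales the gamma-distributed subject spontaneous
#' rate, `adapt_a_mult`/`adapt_b_mult`/`adapt_c_mult` scale the power-law
#' adaptation parameters, and `deviance_gain_mult` scales the deviance gain.
#'
#' @param groups Tibble with one row per group. Required columns `sex`
#'   (`"F"`/`"M"`), `age` (`"prepubertal"`/`"adult"`), `exposure`
#'   (`"control"`/`"VPA"`). Optional columns `n_subjects`, `n_units` (per
#'   subject) and the multipliers above; missing ones take the defaults.
#'   Default: all eight groups, all multipliers 1.
#' @param n_subjects,n_units Defaults applied where `groups` does not set them.
#' @param base Base [neuron_model()] shared by the cohort.
#' @param spont_gamma_shape Shape of the gamma distribution of per-subject
#'   spontaneous rates (mean = `spont_mult` x base rate); small shapes give
#'   the positive, right-skewed rates seen in vivo.
#' @param division_probs Named probabilities for `lemniscal` /
#'   `non_lemniscal` unit assignment.
#' @param level_probs Named probabilities for `high` / `low` level class.
#' @param nl_adapt_c_mult Steady-state adaptation multiplier applied to
#'   non-lemniscal units (< 1 deepens standard adaptation there, reproducing
#'   the stronger mismatch of the non-lemniscal division).
#' @param bf_range_hz Range from which unit best frequencies are drawn
#'   (log-uniform).
#' @param seed Master seed for the whole cohort.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(groups = default_groups(),
                          n_subjects = 2L,
                          n_units = 5L,
                          base = neuron_model(),
                          spont_gamma_shape = 2,
                          division_probs = c(lemniscal = 0.5, non_lemniscal = 0.5),
                          level_probs = c(high = 0.7, low = 0.3),
                          nl_adapt_c_mult = 0.3,
                          bf_range_hz = c(2000, 30000),
                          seed = 1L) {
  groups <- as_tibble(groups)
  need <- c("sex", "age", "exposure")
  if (!all(need %in% names(groups)))
    abort("`groups` must have columns sex, age, exposure.")
  defaults <- list(n_subjects = n_subjects, n_units = n_units,
                   spont_mult = 1, adapt_a_mult = 1, adapt_b_mult = 1,
                   adapt_c_mult = 1, deviance_gain_mult = 1)
  for (col in names(defaults)) {
    if (is.null(groups[[col]])) groups[[col]] <- defaults[[col]]
    groups[[col]][is.na(groups[[col]])] <- defaults[[col]]
  }
  mult_cols <- c("spont_mult", "adapt_a_mult", "adapt_b_mult",
                 "adapt_c_mult", "deviance_gain_mult")
  if (any(as.matrix(groups[mult_cols]) <= 0))
    abort("All group multipliers must be > 0.")
  if (nrow(groups) == 0L) abort("`groups` must contain at least one group.")
  if (!inherits(base, "neuron_model")) abort("`base` must be a <neuron_model>.")
  structure(
    list(groups = groups, base = base, spont_gamma_shape = spont_gamma_shape,
         division_probs = division_probs, level_probs = level_probs,
         nl_adapt_c_mult = nl_adapt_c_mult, bf_range_hz = bf_range_hz,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_groups <- function() {
  tidyr::expand_grid(sex = c("F", "M"),
                     age = c("prepubertal", "adult"),
                     exposure = c("control", "VPA"))
}

#' Simulate a recording cohort
#'
#' Draws subjects and units per group according to a [cohort_config()] and
#' runs the full experimental set on every unit: a 0.5-octave 10-tone scale
#' centred on the unit's best frequency, the two oddball sequences in which
#' the central pair swap standard and deviant roles, and the ascending and
#' descending cascade controls — 400 tones each at 4 Hz. Per-subject
#' spontaneous rates are gamma distributed (right-skewed, strictly positive)
#' with mean `spont_mult` x base rate; unit rates add a lognormal jitter.
#'
#' The same master seed always reproduces the identical dataset, and every
#' unit's draws depend only on its own (group, subject, unit) labels.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"simulated_cohort"`: a list with
#'   * `units`: one row per unit — ids, group labels, division, level class,
#'     stimulation parameters and the ground-truth neuron parameters;
#'   * `tones`: one row per presented tone (unit, sequence, index, condition,
#'     frequency);
#'   * `spikes`: one row per spike (unit, sequence, tone, condition,
#'     frequency, time in ms relative to tone onset);
#'   * `config`: the generating configuration.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a <cohort_config>.")
  g <- config$groups
  units_list <- list()
  tones_list <- list()
  spikes_list <- list()
  unit_counter <- 0L

  for (gi in seq_len(nrow(g))) {
    row <- g[gi, ]
    if (row$n_subjects < 1L || row$n_units < 1L) next
    glabel <- paste(row$sex, row$age, row$exposure, sep = "_")
    for (si in seq_len(row$n_subjects)) {
      subj_id <- sprintf("%s_s%02d", glabel, si)
      subj_seed <- derive_seed(config$seed, "subject", gi, si)
      subj_spont <- with_local_seed(subj_seed, rgamma(
        1, shape = config$spont_gamma_shape,
        scale = row$spont_mult * config$base$spontaneous_rate / config$spont_gamma_shape
      ))
      for (ui in seq_len(row$n_units)) {
        unit_counter <- unit_counter + 1L
        unit_id <- sprintf("u%04d", unit_counter)
        useed <- derive_seed(config$seed, "unit", gi, si, ui)
        draw <- with_local_seed(useed, list(
          bf = 2^runif(1, log2(config$bf_range_hz[1]), log2(config$bf_range_hz[2])),
          division = sample(names(config$division_probs), 1,
                            prob = config$division_probs),
          level_class = sample(names(config$level_probs), 1,
                               prob = config$level_probs),
          jitter = exp(stats::rnorm(1, 0, 0.3))
        ))
        div_c_mult <- if (draw$division == "non_lemniscal") config$nl_adapt_c_mult else 1
        nm <- neuron_model(
          spontaneous_rate = subj_spont * draw$jitter,
          best_frequency = draw$bf,
          tuning_bandwidth = config$base$tuning_bandwidth,
          threshold = config$base$threshold,
          level_saturation = config$base$level_saturation,
          peak_evoked_rate = config$base$peak_evoked_rate,
          latency = config$base$latency,
          kernel_width = config$base$kernel_width,
          adapt_a = config$base$adapt_a * row$adapt_a_mult,
          adapt_b = config$base$adapt_b * row$adapt_b_mult,
          adapt_c = config$base$adapt_c * row$adapt_c_mult * div_c_mult,
          deviance_gain = config$base$deviance_gain * row$deviance_gain_mult
        )
        level <- if (draw$level_class == "high") 60 else 30
        rec <- simulate_experimental_set(nm, level, useed)

        units_list[[unit_counter]] <- tibble(
          unit_id = unit_id, subject_id = subj_id,
          sex = row$sex, age = row$age, exposure = row$exposure,
          division = draw$division, level_class = draw$level_class,
          level_db = level,
          f_low = rec$f_low, f_high = rec$f_high,
          best_frequency = nm$best_frequency,
          spont_rate_true = nm$spontaneous_rate,
          peak_evoked_rate = nm$peak_evoked_rate,
          adapt_a = nm$adapt_a, adapt_b = nm$adapt_b, adapt_c = nm$adapt_c,
          deviance_gain = nm$deviance_gain
        )
        rec$tones$unit_id <- unit_id
        rec$spikes$unit_id <- unit_id
        tones_list[[unit_counter]] <- rec$tones
        spikes_list[[unit_counter]] <- rec$spikes
      }
    }
  }
  if (unit_counter == 0L) abort("Configuration produced no units.")
  structure(
    list(units = bind_rows(units_list),
         tones = bind_rows(tones_list),
         spikes = bind_rows(spikes_list),
         config = config),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort: %d units, %d spikes, seed %d>\n",
              nrow(x$units), nrow(x$spikes), x$config$seed))
  invisible(x)
}

# One complete experimental set: scale centred on the BF, both oddball
# directions for the central pair, both cascade directions.
simulate_experimental_set <- function(neuron, level, seed) {
  scale <- neuron$best_frequency * 2^(0.5 * (seq_len(10L) - 5.5))
  f_low <- scale[5]
  f_high <- scale[6]
  seqs <- list(
    odd_asc = make_oddball(f_low, f_high, level = level,
                           seed = derive_seed(seed, "odd_asc")),
    odd_desc = make_oddball(f_high, f_low, level = level,
                            seed = derive_seed(seed, "odd_desc")),
    cas_asc = make_cascade(scale, "ascending", level = level),
    cas_desc = make_cascade(scale, "descending", level = level)
  )
  tones <- purrr::imap(seqs, function(s, nm_) {
    tibble(sequence = nm_, tone_index = s$index, condition = s$condition,
           frequency_hz = s$frequency_hz)
  })
  spikes <- purrr::imap(seqs, function(s, nm_) {
    sp <- simulate_unit(neuron, s, seed = derive_seed(seed, "spikes", nm_))
    sp$sequence <- nm_
    sp
  })
  list(f_low = f_low, f_high = f_high,
       tones = bind_rows(tones),
       spikes = select(bind_rows(spikes), "sequence", "tone_index",
                       "condition", "frequency_hz", "spike_time_ms"))
}

#' Write a simulated cohort to CSV files
#'
#' Emits `units.csv` (metadata incl. ground truth), `tones.csv` (the
#' presented sequences) and `spikes.csv` (the spike table) into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "simulated_cohort")) abort("not a <simulated_cohort>.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$units, file.path(dir, "units.csv"))
  readr::write_csv(cohort$tones, file.path(dir, "tones.csv"))
  readr::write_csv(cohort$spikes, file.path(dir, "spikes.csv"))
  invisible(dir)
}
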