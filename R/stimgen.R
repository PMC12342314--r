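#' Stimulus sequences for the auditory oddball paradigm and its cascade control
#'
#' A stimulus sequence is a tibble of 400 tone events delivered at 4 Hz
#' (250 ms onset-to-onset), one row per tone, with columns `index` (1-based
#' position), `onset_ms`, `frequency_hz`, `level_db` and `condition`
#' (`"DEV"`, `"STD"` or `"CAS"`). Sequence-level metadata (kind, rate, seed,
#' frequency set) is carried in attributes and preserved by
#' [write_sequence()] / [read_sequence()]. Tones are 75 ms pure tones with
#' 5 ms rise/fall ramps; duration and ramps are metadata only (no audio is
#' synthesised).
#'
#' @name stim_sequence
NULL

SEQ_LENGTH <- 400L
SEQ_RATE_HZ <- 4
TONE_DURATION_MS <- 75
TONE_RAMP_MS <- 5
N_DEVIANTS <- 40L
MIN_STD_GAP <- 3L # standards required before every deviant
N_LEAD_STD <- 10L # opening tones that are always standards

new_stim_sequence <- function(df, kind, seed = NA_integer_, frequency_set = NULL,
                              standard_frequency = NA_real_, deviant_frequency = NA_real_) {
  out <- as_tibble(df)
  attr(out, "kind") <- kind
  attr(out, "rate_hz") <- SEQ_RATE_HZ
  attr(out, "seed") <- seed
  attr(out, "frequency_set") <- frequency_set
  attr(out, "standard_frequency") <- standard_frequency
  attr(out, "deviant_frequency") <- deviant_frequency
  attr(out, "tone_duration_ms") <- TONE_DURATION_MS
  attr(out, "tone_ramp_ms") <- TONE_RAMP_MS
  class(out) <- c("stim_sequence", class(out))
  out
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence: %s, %d tones @ %g Hz, seed %s>\n",
              attr(x, "kind"), nrow(x), attr(x, "rate_hz"),
              format(attr(x, "seed"))))
  NextMethod()
}

seq_kind <- function(x) attr(x, "kind") %||% NA_character_

is_oddball <- function(x) {
  inherits(x, "stim_sequence") && seq_kind(x) %in% c("oddball_ascending", "oddball_descending")
}

#' Generate an oddball sequence
#'
#' Builds a 400-tone oddball sequence at 4 Hz in which the deviant tone
#' appears with 10% probability (exactly 40 occurrences) under the paradigm's
#' ordering constraints: the first 10 tones are always standards and every
#' deviant is preceded by at least 3 consecutive standards. Deviant positions
#' are drawn uniformly at random over all position sets satisfying these
#' constraints, via a combinatorial bijection (sample 40 of 273 slots and
#' re-inflate the minimum gaps), so the draw is exact and always terminates.
#'
#' The sequence is `oddball_ascending` when the deviant frequency is above
#' the standard, `oddball_descending` otherwise.
#'
#' @param standard_freq,deviant_freq Tone frequencies in Hz; must differ.
#' @param level Sound level in dB SPL, stored per tone.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return A [stim_sequence] tibble of 400 rows.
#' @examples
#' s <- make_oddball(8000, 8000 * 2^0.5, level = 60, seed = 1)
#' table(s$condition)
#' @export
make_oddball <- function(standard_freq, deviant_freq, level = 60, seed) {
  stopifnot_scalar_number(standard_freq, "standard_freq", positive = TRUE)
  stopifnot_scalar_number(deviant_freq, "deviant_freq", positive = TRUE)
  stopifnot_scalar_number(level, "level")
  if (standard_freq == deviant_freq)
    abort("`standard_freq` and `deviant_freq` must differ.")
  if (missing(seed) || is.null(seed))
    abort("`seed` is required: oddball sequences are pseudorandom.")

  dev_pos <- with_local_seed(seed, draw_deviant_positions(
    n_tones = SEQ_LENGTH, n_dev = N_DEVIANTS,
    lead = N_LEAD_STD, gap = MIN_STD_GAP
  ))

  condition <- rep("STD", SEQ_LENGTH)
  condition[dev_pos] <- "DEV"
  freq <- ifelse(condition == "DEV", deviant_freq, standard_freq)

  kind <- if (deviant_freq > standard_freq) "oddball_ascending" else "oddball_descending"
  new_stim_sequence(
    tibble(
      index = seq_len(SEQ_LENGTH),
      onset_ms = (seq_len(SEQ_LENGTH) - 1) * 1000 / SEQ_RATE_HZ,
      frequency_hz = freq,
      level_db = level,
      condition = condition
    ),
    kind = kind, seed = as.integer(seed),
    standard_frequency = standard_freq, deviant_frequency = deviant_freq
  )
}

# Uniform draw of n_dev positions from (lead, n_tones] with >= gap standards
# between consecutive deviants (and before the first, guaranteed by the lead).
# Bijection: sorted q_1<...<q_k from 1..(n_tones-lead-(k-1)*gap) maps to
# p_i = lead + q_i + gap*(i-1); every admissible set corresponds to exactly
# one q-set, so sampling q uniformly samples p uniformly.
draw_deviant_positions <- function(n_tones, n_dev, lead, gap) {
  m <- n_tones - lead - (n_dev - 1L) * gap
  if (m < n_dev)
    abort("Deviant placement constraints are unsatisfiable for these parameters.")
  q <- sort(sample.int(m, n_dev))
  lead + q + gap * (seq_len(n_dev) - 1L)
}

#' Generate a cascade control sequence
#'
#' The cascade control presents the 10 sequence frequencies as a regular
#' ascending or descending scale, repeated for 40 full traversals (400 tones
#' at 4 Hz). Each frequency therefore occurs exactly 40 times — the same 10%
#' presentation probability as the oddball deviant — but never in immediate
#' repetition, so no repetition-based regularity is established.
#'
#' @param frequency_set Exactly 10 distinct positive frequencies in Hz.
#' @param direction `"ascending"` or `"descending"`.
#' @param level Sound level in dB SPL.
#' @return A [stim_sequence] tibble of 400 rows, all tones labelled `"CAS"`.
#' @export
make_cascade <- function(frequency_set, direction = c("ascending", "descending"),
                         level = 60) {
  direction <- match.arg(direction)
  if (length(frequency_set) != 10L)
    abort("`frequency_set` must contain exactly 10 frequencies.")
  if (anyDuplicated(frequency_set))
    abort("`frequency_set` must contain 10 distinct frequencies.")
  if (any(!is.finite(frequency_set)) || any(frequency_set <= 0))
    abort("All frequencies must be positive and finite.")
  stopifnot_scalar_number(level, "level")

  scale <- sort(frequency_set, decreasing = (direction == "descending"))
  freq <- rep(scale, times = SEQ_LENGTH / 10L)
  new_stim_sequence(
    tibble(
      index = seq_len(SEQ_LENGTH),
      onset_ms = (seq_len(SEQ_LENGTH) - 1) * 1000 / SEQ_RATE_HZ,
      frequency_hz = freq,
      level_db = level,
      condition = "CAS"
    ),
    kind = paste0("cascade_", direction),
    frequency_set = sort(frequency_set)
  )
}

#' Select the analysable trials of an oddball sequence
#'
#' Only the last standard before each deviant enters the analysis, so a
#' 400-tone oddball run yields exactly 40 deviant trials and 40 matched
#' last-standard trials per tone of interest.
#'
#' @param sequence An oddball [stim_sequence].
#' @return A list with integer vectors `dev_indices` and `std_indices`
#'   (each of length 40, disjoint; `std_indices[i] == dev_indices[i] - 1`).
#' @export
select_analyzed_trials <- function(sequence) {
  if (!is_oddball(sequence))
    abort("`sequence` must be an oddball stimulus sequence.")
  dev <- which(sequence$condition == "DEV")
  list(dev_indices = dev, std_indices = dev - 1L)
}

#' Choose stimulation frequencies from a frequency response area
#'
#' Places a 10-tone scale with exact 0.5-octave spacing on a unit's frequency
#' response area (FRA) so that as many consecutive scale members as possible
#' fall inside the excitatory region at the test level, and returns all
#' adjacent in-region scale pairs as oddball frequency candidates. The test
#' level defaults to `level_offset` dB above the unit's minimal response
#' threshold, snapped to the nearest recorded level.
#'
#' @param fra An [fra] object (see [build_fra()]).
#' @param level_offset dB above the minimal response threshold at which to
#'   stimulate (10–20 dB is typical); default 15.
#' @param level Optional explicit test level in dB SPL (overrides the offset).
#' @return A list of class `"frequency_selection"` with elements `scale`
#'   (10 frequencies in Hz), `in_region` (logical per scale member),
#'   `oddball_pairs` (tibble with `f_low`, `f_high`) and `level`.
#' @export
select_stimulus_frequencies <- function(fra, level_offset = 15, level = NULL) {
  if (!inherits(fra, "fra")) abort("`fra` must be an <fra> object.")
  levels <- sort(unique(fra$grid$level_db))
  if (is.null(level)) {
    # Anchor the offset at the lowest level showing a coherent excitatory
    # region (>= 2 adjacent excitatory frequencies); then try recorded levels
    # in order of proximity to threshold + offset (ties towards the lower
    # level) and keep the first that supports a valid scale. With 3-5 FRA
    # repetitions single cells are noisy, so one fixed level would be brittle.
    thr <- robust_response_threshold(fra)
    if (!is.finite(thr))
      abort("FRA has no excitatory region at any level; cannot select frequencies.")
    ord <- levels[order(abs(levels - (thr + level_offset)), levels)]
    for (lv in ord) {
      sel <- tryCatch(place_scale(fra, lv), error = function(e) NULL)
      if (!is.null(sel)) return(sel)
    }
    abort("Fewer than 2 consecutive scale members fall in the excitatory region at every level.")
  }
  place_scale(fra, level)
}

place_scale <- function(fra, level) {
  cells <- fra$grid[fra$grid$level_db == level & fra$grid$excitatory, , drop = FALSE]
  if (nrow(cells) == 0L)
    abort("FRA has no excitatory region at the chosen level.")

  region <- sort(cells$frequency_hz)
  freqs <- sort(unique(fra$grid$frequency_hz))

  # Candidate anchors: scales through each recorded frequency, each shifted so
  # that 1..10 of its members sit below the anchor. Membership of a scale tone
  # is decided by its nearest recorded frequency (within a quarter octave).
  best <- NULL
  for (anchor in freqs) {
    for (shift in 0:9) {
      scale <- anchor * 2^(0.5 * (seq_len(10L) - 1L - shift))
      inreg <- vapply(scale, function(f) {
        j <- which.min(abs(log2(freqs / f)))
        abs(log2(freqs[j] / f)) <= 0.25 && freqs[j] %in% region
      }, logical(1))
      run <- max_consecutive_run(inreg)
      score <- c(run, sum(inreg))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2])) {
        best <- list(scale = scale, in_region = inreg, score = score)
      }
    }
  }
  if (best$score[1] < 2L)
    abort("Fewer than 2 consecutive scale members fall in the excitatory region.")

  idx <- which(best$in_region[-10L] & best$in_region[-1L])
  pairs <- tibble(f_low = best$scale[idx], f_high = best$scale[idx + 1L])
  structure(
    list(scale = best$scale, in_region = best$in_region,
         oddball_pairs = pairs, level = level),
    class = "frequency_selection"
  )
}

max_consecutive_run <- function(x) {
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else max(runs)
}

#' Write / read a stimulus sequence
#'
#' Sequences serialise to a CSV with columns
#' `index,onset_ms,frequency_hz,level_db,condition` plus a JSON sidecar
#' (`<path>.json`) holding kind, seed, rate and the frequency metadata.
#'
#' @param sequence A [stim_sequence].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_sequence()` returns `path` invisibly; `read_sequence()`
#'   returns the reconstructed [stim_sequence].
#' @export
write_sequence <- function(sequence, path) {
  if (!inherits(sequence, "stim_sequence")) abort("not a <stim_sequence>.")
  readr::write_csv(as_tibble(unclass_sequence(sequence)), path)
  meta <- list(
    kind = seq_kind(sequence),
    rate_hz = attr(sequence, "rate_hz"),
    seed = attr(sequence, "seed"),
    frequency_set = attr(sequence, "frequency_set"),
    standard_frequency = attr(sequence, "standard_frequency"),
    deviant_frequency = attr(sequence, "deviant_frequency"),
    tone_duration_ms = attr(sequence, "tone_duration_ms"),
    tone_ramp_ms = attr(sequence, "tone_ramp_ms")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

unclass_sequence <- function(x) {
  class(x) <- setdiff(class(x), "stim_sequence")
  for (a in c("kind", "rate_hz", "seed", "frequency_set", "standard_frequency",
              "deviant_frequency", "tone_duration_ms", "tone_ramp_ms"))
    attr(x, a) <- NULL
  x
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(condition = readr::col_character()))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_stim_sequence(df, kind = meta$kind,
                    seed = meta$seed %||% NA_integer_,
                    frequency_set = meta$frequency_set,
                    standard_frequency = meta$standard_frequency %||% NA_real_,
                    deviant_frequency = meta$deviant_frequency %||% NA_real_)
}
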