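#' Extract per-condition responses from a simulated cohort
#'
#' For every unit and each of its two tones of interest, collects the 40
#' analysable trials per condition — deviant trials from the oddball run in
#' which the tone is deviant, the last-standard trials from the run in which
#' it is standard, and the tone's 40 cascade presentations (ascending
#' cascade for the upper tone of the pair, descending for the lower) — and
#' reduces each trial set to a baseline-corrected spike count.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param kernel_sd SDF kernel SD in ms (default 6).
#' @return A list of class `"response_tables"`:
#'   * `responses`: per (unit, tone, condition) — `unit_id`, `frequency_hz`,
#'     `condition`, `n_trials`, `baseline_rate`, `corrected_count`, and a
#'     `trials` list-column holding the spike-time sets;
#'   * `trial_responses`: per-trial counts for adaptation time courses —
#'     `unit_id`, `frequency_hz`, `condition`, `trial`, `response`.
#' @export
extract_responses <- function(cohort, kernel_sd = SDF_KERNEL_SD_MS) {
  if (!inherits(cohort, "simulated_cohort")) abort("`cohort` must be a <simulated_cohort>.")
  resp <- list(); tr <- list(); k <- 0L
  for (uid in cohort$units$unit_id) {
    u <- cohort$units[cohort$units$unit_id == uid, ]
    tones <- cohort$tones[cohort$tones$unit_id == uid, ]
    spikes <- cohort$spikes[cohort$spikes$unit_id == uid, ]
    plan <- trial_plan(tones, u$f_low, u$f_high)
    for (j in seq_len(nrow(plan))) {
      sp <- spikes[spikes$sequence == plan$sequence[j], ]
      trials <- spike_trains(sp, plan$tone_indices[[j]])
      er <- evoked_response(trials, kernel_sd = kernel_sd)
      k <- k + 1L
      resp[[k]] <- tibble(
        unit_id = uid, frequency_hz = plan$frequency_hz[j],
        condition = plan$condition[j], n_trials = er$n_trials,
        baseline_rate = er$baseline_rate, corrected_count = er$corrected_count,
        trials = list(trials)
      )
      tr[[k]] <- tibble(
        unit_id = uid, frequency_hz = plan$frequency_hz[j],
        condition = plan$condition[j],
        trial = seq_along(trials),
        response = trial_counts(trials, baseline = er$baseline_rate,
                                kernel_sd = kernel_sd)
      )
    }
  }
  structure(list(responses = bind_rows(resp), trial_responses = bind_rows(tr)),
            class = "response_tables")
}

# Which trials of which sequence feed each (tone of interest, condition).
trial_plan <- function(tones, f_low, f_high) {
  seq_of <- function(s) tones[tones$sequence == s, ]
  dev_pos <- function(s) seq_of(s)$tone_index[seq_of(s)$condition == "DEV"]
  cas_pos <- function(s, f) {
    tt <- seq_of(s)
    tt$tone_index[abs(log2(tt$frequency_hz / f)) < 1e-9]
  }
  tibble(
    frequency_hz = rep(c(f_high, f_low), each = 3),
    condition = rep(c("DEV", "STD", "CAS"), 2),
    sequence = c("odd_asc", "odd_desc", "cas_asc",
                 "odd_desc", "odd_asc", "cas_desc"),
    tone_indices = list(
      dev_pos("odd_asc"), dev_pos("odd_desc") - 1L, cas_pos("cas_asc", f_high),
      dev_pos("odd_desc"), dev_pos("odd_asc") - 1L, cas_pos("cas_desc", f_low)
    )
  )
}

#' Monte-Carlo significance screen for all unit-frequency combinations
#'
#' Runs [monte_carlo_p()] on every (unit, tone, condition) trial set of an
#' [extract_responses()] result and pivots the p-values into one row per
#' unit-frequency combination, ready for [filter_units()]. Seeds are derived
#' per combination from `seed`, so conditions are independent and the screen
#' is reproducible.
#'
#' @param tables An [extract_responses()] result.
#' @param n_sim Null replicates per test (analysis default 1,000).
#' @param seed Integer seed.
#' @return Tibble: `unit_id`, `frequency_hz`, `p_dev`, `p_std`, `p_cas`.
#' @export
significance_table <- function(tables, n_sim = 1000, seed) {
  if (!inherits(tables, "response_tables")) abort("`tables` must come from extract_responses().")
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  r <- tables$responses
  r$p <- vapply(seq_len(nrow(r)), function(i) {
    monte_carlo_p(r$trials[[i]], baseline = r$baseline_rate[i],
                  n_sim = n_sim,
                  seed = derive_seed(seed, r$unit_id[i],
                                     round(r$frequency_hz[i]), r$condition[i]))$p
  }, numeric(1))
  r |>
    select("unit_id", "frequency_hz", "condition", "p") |>
    mutate(condition = tolower(.data$condition)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "p",
                       names_prefix = "p_")
}

#' Per-point index table
#'
#' Joins the DEV/STD/CAS corrected counts of the retained unit-frequency
#' combinations, normalises each triplet and computes the mismatch indices,
#' then attaches the unit metadata. One row per analysed point
#' (unit x frequency).
#'
#' @param tables An [extract_responses()] result.
#' @param filtered A [filter_units()] result (rows with `retained == FALSE`
#'   are dropped); omit to keep all combinations.
#' @param units Unit metadata tibble (e.g. `cohort$units`).
#' @param rectify Passed to [normalize_triplet()].
#' @return Tibble with ids, group labels, normalised responses and indices.
#' @export
index_table <- function(tables, units, filtered = NULL, rectify = TRUE) {
  if (!inherits(tables, "response_tables")) abort("`tables` must come from extract_responses().")
  wide <- tables$responses |>
    select("unit_id", "frequency_hz", "condition", "corrected_count") |>
    mutate(condition = tolower(.data$condition)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "corrected_count")
  if (!is.null(filtered)) {
    keep <- filtered |> filter(.data$retained) |>
      select("unit_id", "frequency_hz")
    wide <- dplyr::semi_join(wide, keep, by = c("unit_id", "frequency_hz"))
  }
  if (nrow(wide) == 0L) abort("No unit-frequency combinations retained.")
  idx <- mismatch_indices(wide$dev, wide$std, wide$cas, rectify = rectify)
  meta_cols <- intersect(
    c("unit_id", "subject_id", "sex", "age", "exposure", "division",
      "level_class", "level_db"),
    names(units))
  bind_cols(wide, idx) |>
    left_join(units[meta_cols], by = "unit_id")
}

#' Configure an end-to-end analysis run
#'
#' @param cohort A [cohort_config()] describing the simulated dataset.
#' @param alpha Monte-Carlo filter level (default 0.05).
#' @param n_sim Null replicates per Monte-Carlo test (default 1,000; lower it
#'   for quick demonstrations).
#' @param fdr_q FDR level for group comparisons (default 0.1).
#' @param kernel_sd SDF kernel SD in ms (default 6).
#' @param min_units Minimum units contributing before an adaptation time
#'   course is fitted (default 3).
#' @param seed Master seed; every stage derives its stream from it.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_config(), alpha = 0.05, n_sim = 1000,
                       fdr_q = 0.1, kernel_sd = SDF_KERNEL_SD_MS,
                       min_units = 3L, seed = 1L) {
  if (!inherits(cohort, "cohort_config")) abort("`cohort` must be a <cohort_config>.")
  for (p in c(alpha, n_sim, fdr_q, kernel_sd)) stopifnot_scalar_number(p, "parameter", positive = TRUE)
  structure(list(cohort = cohort, alpha = alpha, n_sim = n_sim, fdr_q = fdr_q,
                 kernel_sd = kernel_sd, min_units = as.integer(min_units),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `cohort` key
#' mirrors [cohort_config()] (`groups` as a list of row records, `base` as
#' [neuron_model()] arguments).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ccall <- y$cohort %||% list()
  if (!is.null(ccall$groups)) ccall$groups <- bind_rows(ccall$groups)
  if (!is.null(ccall$base)) ccall$base <- do.call(neuron_model, ccall$base)
  cohort <- do.call(cohort_config, ccall)
  args <- y[setdiff(names(y), "cohort")]
  do.call(run_config, c(list(cohort = cohort), args))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> extract -> Monte-Carlo filter -> indices ->
#' group summary + comparisons -> adaptation fits, all seeded from the
#' master seed (rerunning with the same configuration reproduces every
#' number). When `out_dir` is given, writes the cohort tables, response,
#' significance, index, summary, comparison and adaptation CSVs plus a JSON
#' run manifest (seed, parameter echo, per-stage counts, file list).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `"pipeline_run"` with elements `cohort`,
#'   `responses`, `significance`, `points`, `group_summary`, `comparisons`,
#'   `adaptation`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) abort("`config` must be a <run_config>.")
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, "cohort")
  cohort <- simulate_cohort(cohort_cfg)
  ext <- extract_responses(cohort, kernel_sd = config$kernel_sd)
  sig <- significance_table(ext, n_sim = config$n_sim,
                            seed = derive_seed(config$seed, "mc"))
  filt <- filter_units(sig, alpha = config$alpha)
  points <- index_table(ext, cohort$units, filtered = filt)
  summary_tab <- summarize_groups(points, q = config$fdr_q)
  comparisons <- tryCatch(compare_groups(points, q = config$fdr_q),
                          error = function(e) tibble())
  adaptation <- adaptation_fits(ext, cohort$units, min_units = config$min_units)

  manifest <- list(
    package = "mismatchkit",
    version = as.character(utils::packageVersion("mismatchkit")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = list(alpha = config$alpha, n_sim = config$n_sim,
                      fdr_q = config$fdr_q, kernel_sd = config$kernel_sd,
                      min_units = config$min_units),
    counts = list(
      units = nrow(cohort$units),
      combinations = nrow(sig),
      retained = attr(filt, "filter_log")$n_retained,
      points = nrow(points),
      comparisons = nrow(comparisons),
      adaptation_fits = nrow(adaptation),
      adaptation_failed = sum(!adaptation$converged)
    )
  )
  run <- structure(
    list(cohort = cohort, responses = ext$responses |> select(-"trials"),
         trial_responses = ext$trial_responses,
         significance = filt, points = points, group_summary = summary_tab,
         comparisons = comparisons, adaptation = adaptation,
         manifest = manifest),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d units, %d points retained, seed %d>\n",
              x$manifest$counts$units, x$manifest$counts$points,
              x$manifest$seed))
  invisible(x)
}

# Group x division x level x condition adaptation fits with half-adaptation
# of the standard course.
adaptation_fits <- function(ext, units, min_units = 3L) {
  tr <- ext$trial_responses |>
    left_join(units[c("unit_id", "sex", "age", "exposure", "division",
                      "level_class")], by = "unit_id") |>
    mutate(group = paste(.data$sex, .data$age, .data$exposure, sep = "_"))
  strata <- tr |> dplyr::distinct(.data$group, .data$division,
                                  .data$level_class, .data$condition)
  purrr::map(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    d <- tr |>
      dplyr::semi_join(s, by = c("group", "division", "level_class", "condition")) |>
      mutate(unit_id = paste(.data$unit_id, .data$frequency_hz))
    if (dplyr::n_distinct(d$unit_id) < min_units) return(NULL)
    tc <- average_time_course(d)
    f <- tryCatch(fit_power_law(tc), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    half <- if (s$condition == "STD") {
      tryCatch(half_adaptation_time(tc), error = function(e) NULL)
    } else NULL
    tibble(group = s$group, division = s$division,
           level_class = s$level_class, condition = s$condition,
           n_units = dplyr::n_distinct(d$unit_id),
           a = f$a, b = f$b, c = f$c, r2 = f$r2,
           high_quality = f$high_quality, converged = f$converged,
           half_adaptation_s = if (!is.null(half) && half$defined)
             half$crossing_time_s else NA_real_)
  }) |> bind_rows()
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(run$cohort, out_dir)
  files <- c(
    responses = "responses.csv", trial_responses = "trial_responses.csv",
    significance = "significance.csv", points = "points.csv",
    group_summary = "group_summary.csv", comparisons = "comparisons.csv",
    adaptation = "adaptation_fits.csv"
  )
  for (nm in names(files)) {
    obj <- run[[nm]]
    if (is.data.frame(obj) && nrow(obj) > 0)
      readr::write_csv(obj, file.path(out_dir, files[[nm]]))
  }
  run$manifest$files <- c("units.csv", "tones.csv", "spikes.csv",
                          unname(files[vapply(names(files), function(nm)
                            is.data.frame(run[[nm]]) && nrow(run[[nm]]) > 0,
                            logical(1))]))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
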