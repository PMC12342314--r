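#' Averaged adaptation time course
#'
#' Averages per-trial responses across units at each analysed trial position
#' (position 1 = first analysed trial of the condition; at 4 Hz one oddball
#' run yields 40 positions per condition).
#'
#' @param unit_courses Tibble with columns `unit_id`, `trial` (1-based
#'   position) and `response`.
#' @return A tibble of class `"time_course"` with columns `trial`,
#'   `mean_response`, `n_units`.
#' @export
average_time_course <- function(unit_courses) {
  unit_courses <- as_tibble(unit_courses)
  need <- c("unit_id", "trial", "response")
  if (!all(need %in% names(unit_courses)) || nrow(unit_courses) == 0L)
    abort("`unit_courses` must be non-empty with unit_id, trial, response.")
  out <- unit_courses |>
    filter(!is.na(.data$response)) |>
    group_by(.data$trial) |>
    summarise(mean_response = mean(.data$response), n_units = n(),
              .groups = "drop") |>
    arrange(.data$trial)
  class(out) <- c("time_course", class(out))
  out
}

as_time_course <- function(x) {
  if (inherits(x, "time_course")) return(x)
  x <- as_tibble(x)
  if (!all(c("trial", "mean_response") %in% names(x)))
    abort("Need columns `trial` and `mean_response` (or a <time_course>).")
  x
}

#' Fit a power-law adaptation model
#'
#' Fits `y(t) = a t^b + c` to an averaged time course by bounded nonlinear
#' least squares (`b <= 0`, `c >= 0`), where `a` captures the initial
#' response strength, `b` the adaptation velocity and `c` the steady state.
#' Trials are indexed from 1 so the model is defined at every point. A fixed
#' multi-start grid (`a` in \{0.1, 0.5, 1\} plus a data-driven start,
#' `b` in \{−0.3, −0.8, −1.5\}, `c` in \{0, median(y)\}) makes the fit
#' deterministic; the best converged start by residual sum of squares wins.
#' Fits with `r^2 >= 0.65` are flagged high quality; a constant series has
#' undefined `r^2` and is reported as failed, as is non-convergence from all
#' starts.
#'
#' @param tc A [average_time_course()] result, or any data frame with
#'   columns `trial` and `mean_response`.
#' @return Object of class `"power_law_fit"`: list with `a`, `b`, `c`, `r2`,
#'   `high_quality`, `converged`, `n`, `data` and `fitted`.
#' @examples
#' tc <- tibble::tibble(trial = 1:40, mean_response = 0.5 * (1:40)^-0.8 + 1.2)
#' coef_tidy <- tidy(fit_power_law(tc))
#' @export
fit_power_law <- function(tc) {
  tc <- as_time_course(tc)
  t <- as.numeric(tc$trial)
  y <- as.numeric(tc$mean_response)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 4L)
    abort("Need at least 4 trial positions to fit 3 parameters.")
  ss_tot <- sum((y - mean(y))^2)

  failed <- function() {
    structure(list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NA_real_,
                   high_quality = FALSE, converged = FALSE, n = length(t),
                   data = tibble(trial = t, mean_response = y),
                   fitted = rep(NA_real_, length(t))),
              class = "power_law_fit")
  }
  if (ss_tot == 0) return(failed())

  starts <- tidyr::expand_grid(
    a = unique(c(0.1, 0.5, 1, max(y[1] - median(y), 0.1))),
    b = c(-0.3, -0.8, -1.5),
    c = unique(c(0, max(median(y), 0)))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * t^b + c,
        start = as.list(starts[i, ]),
        lower = c(a = -Inf, b = -Inf, c = 0),
        upper = c(a = Inf, b = 0, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed())

  cf <- stats::coef(best$fit)
  r2 <- 1 - best$rss / ss_tot
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
         r2 = r2, high_quality = r2 >= 0.65, converged = TRUE, n = length(t),
         data = tibble(trial = t, mean_response = y),
         fitted = unname(cf["a"]) * t^unname(cf["b"]) + unname(cf["c"])),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<power_law_fit: failed (no convergence or constant series)>\n")
  } else {
    cat(sprintf("<power_law_fit: y = %.4g t^%.4g + %.4g, r2 = %.3f%s, n = %d>\n",
                x$a, x$b, x$c, x$r2,
                if (x$high_quality) " (high quality)" else "", x$n))
  }
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(r2 = x$r2, high_quality = x$high_quality,
         converged = x$converged, n = x$n)
}

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$trial else newdata$trial
  object$a * t^object$b + object$c
}

#' Bootstrap distribution of power-law coefficients
#'
#' Quantifies the variability of an averaged-course power-law fit: each of
#' `n_iter` iterations resamples units with replacement, averages their
#' courses, linearly interpolates the average onto the common 1..T trial
#' grid, and refits the power law (started at the point-fit coefficients,
#' falling back to the multi-start grid). Failed iterations are dropped and
#' counted.
#'
#' @inheritParams average_time_course
#' @param n_iter Number of bootstrap iterations (the analysis default is
#'   1,000).
#' @param seed Integer seed.
#' @param point_fit Optional [fit_power_law()] result for the full average;
#'   computed if omitted. A warning is raised when it is not high quality.
#' @return A tibble of class `"power_law_boot"` with columns `iter`, `a`,
#'   `b`, `c`, `r2`; the number of failed iterations is attribute
#'   `"n_failed"`.
#' @export
bootstrap_fit <- function(unit_courses, n_iter = 1000, seed, point_fit = NULL) {
  unit_courses <- as_tibble(unit_courses)
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  ids <- unique(unit_courses$unit_id)
  if (length(ids) < 2L) abort("Need >= 2 units to bootstrap.")
  if (is.null(point_fit)) point_fit <- fit_power_law(average_time_course(unit_courses))
  if (!isTRUE(point_fit$high_quality))
    warn("Point fit is not high quality (r2 < 0.65); bootstrap may be unstable.")
  grid <- sort(unique(unit_courses$trial))
  courses <- unit_courses |>
    tidyr::pivot_wider(id_cols = "trial", names_from = "unit_id",
                       values_from = "response") |>
    arrange(.data$trial)
  mat <- as.matrix(courses[, ids, drop = FALSE])

  start0 <- if (point_fit$converged) {
    list(a = point_fit$a, b = min(point_fit$b, -1e-6), c = max(point_fit$c, 0))
  } else NULL

  res <- with_local_seed(seed, {
    purrr::map(seq_len(n_iter), function(it) {
      take <- sample(length(ids), replace = TRUE)
      avg <- rowMeans(mat[, take, drop = FALSE], na.rm = TRUE)
      # interpolate onto the common 1..T grid (identity when already aligned)
      avg <- approx(grid, avg, xout = grid, rule = 2)$y
      f <- quick_power_fit(grid, avg, start0)
      if (is.null(f)) return(NULL)
      tibble(iter = it, a = f["a"], b = f["b"], c = f["c"], r2 = f["r2"])
    })
  })
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) abort("All bootstrap iterations failed to fit.")
  out <- bind_rows(res[ok])
  attr(out, "n_failed") <- sum(!ok)
  class(out) <- c("power_law_boot", class(out))
  out
}

# Single-start (with grid fallback) power-law fit used inside the bootstrap.
quick_power_fit <- function(t, y, start0) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NULL)
  try_one <- function(st) {
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * t^b + c, start = st,
        lower = c(a = -Inf, b = -Inf, c = 0), upper = c(a = Inf, b = 0, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
  }
  fit <- if (!is.null(start0)) try_one(start0) else NULL
  if (is.null(fit)) {
    for (b0 in c(-0.3, -0.8, -1.5)) {
      fit <- try_one(list(a = max(y[1] - median(y), 0.1), b = b0,
                          c = max(median(y), 0)))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  c(cf, r2 = 1 - sum(stats::residuals(fit)^2) / ss_tot)
}

#' @export
tidy.power_law_boot <- function(x, conf_level = 0.95, ...) {
  a2 <- (1 - conf_level) / 2
  x |>
    tidyr::pivot_longer(c("a", "b", "c"), names_to = "term",
                        values_to = "estimate") |>
    group_by(.data$term) |>
    summarise(median = median(.data$estimate),
              conf_low = quantile(.data$estimate, a2),
              conf_high = quantile(.data$estimate, 1 - a2),
              .groups = "drop")
}

#' Half-adaptation time of a response time course
#'
#' Short-term adaptation summary: within the first `window_s` seconds of
#' stimulation (at 4 Hz, `window_s * 4` trial positions), the initial level
#' is the value at trial 1 and the final level the mean of the last five
#' in-window values; the half level is their midpoint and the crossing is
#' the first linearly interpolated trial at which the course falls to or
#' below it. When the course does not decay (final >= initial) or never
#' crosses, the half-adaptation time is undefined (`NA` with
#' `defined = FALSE`) — adaptation has vanished.
#'
#' @param tc A [average_time_course()] result (or data frame with `trial`,
#'   `mean_response`).
#' @param window_s Analysis window in seconds (default 15).
#' @param rate_hz Stimulus presentation rate (default 4).
#' @return A list of class `"half_adaptation"`: `half_level`,
#'   `crossing_trial`, `crossing_time_s`, `initial`, `final`, `defined`.
#' @examples
#' tc <- tibble::tibble(trial = 1:10,
#'                      mean_response = c(1, .8, .6, .5, .5, .5, .5, .5, .5, .5))
#' half_adaptation_time(tc)$crossing_trial
#' @export
half_adaptation_time <- function(tc, window_s = 15, rate_hz = SEQ_RATE_HZ) {
  tc <- as_time_course(tc)
  tc <- arrange(tc, .data$trial)
  n_in <- min(nrow(tc), as.integer(window_s * rate_hz))
  y <- tc$mean_response[seq_len(n_in)]
  trial <- tc$trial[seq_len(n_in)]
  if (n_in < 6L) abort("Time course too short for half-adaptation analysis.")
  initial <- y[1]
  final <- mean(tail(y, 5))
  half <- (initial + final) / 2

  und <- function() structure(
    list(half_level = half, crossing_trial = NA_real_,
         crossing_time_s = NA_real_, initial = initial, final = final,
         defined = FALSE),
    class = "half_adaptation")
  if (!(final < initial)) return(und())

  below <- which(y <= half)
  below <- below[below > 1L]
  if (length(below) == 0L) return(und())
  i <- below[1]
  frac <- (y[i - 1] - half) / (y[i - 1] - y[i])
  crossing <- trial[i - 1] + frac * (trial[i] - trial[i - 1])
  structure(
    list(half_level = half, crossing_trial = crossing,
         crossing_time_s = (crossing - 1) / rate_hz,
         initial = initial, final = final, defined = TRUE),
    class = "half_adaptation"
  )
}

#' @export
print.half_adaptation <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<half_adaptation: level %.4g, trial %.3g, %.3g s>\n",
                x$half_level, x$crossing_trial, x$crossing_time_s))
  } else {
    cat("<half_adaptation: undefined (no decay within window)>\n")
  }
  invisible(x)
}
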