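test_that("spike-density function matches Gaussian closed forms", {
  z <- compute_sdf(list(numeric(0), numeric(0)))
  expect_true(all(z$density == 0))
  expect_equal(attr(z, "n_trials"), 2L)
  expect_equal(z$time_ms, seq(-75, 250, 1))

  one <- compute_sdf(list(50))
  expect_equal(one$density[one$time_ms == 50], 1000 / (sqrt(2 * pi) * 6))
  # two trials share the kernel mass
  two <- compute_sdf(list(50, numeric(0)))
  expect_equal(two$density[two$time_ms == 50], 1000 / (sqrt(2 * pi) * 6) / 2)
  expect_error(compute_sdf(list()), "non-empty")
})

test_that("SDF conserves spike mass for interior spikes", {
  withr::with_seed(42, {
    trials <- replicate(30, sort(runif(rpois(1, 6), -40, 210)), simplify = FALSE)
  })
  # all spikes are >= ~5.8 kernel SDs from the window edges
  sdf <- compute_sdf(trials)
  total <- sum(lengths(trials))
  integral <- mismatchkit:::trapz(sdf$time_ms, sdf$density) / 1000 * length(trials)
  expect_lt(abs(integral - total), 1e-6)
})

test_that("SDF of homogeneous Poisson trials estimates the rate", {
  withr::with_seed(7, trials <- poisson_trials(500, 20))
  sdf <- compute_sdf(trials)
  interior <- sdf$time_ms > -50 & sdf$time_ms < 225
  expect_lt(abs(mean(sdf$density[interior]) - 20), 1)
})

test_that("baseline rate is spikes in the pre-stimulus window over time", {
  expect_equal(baseline_rate(list(c(-50, -20, -10, 30))), 3 / 0.075)
  expect_equal(baseline_rate(list(c(10, 100), c(200))), 0)
  forty <- replicate(40, c(-30, 120), simplify = FALSE)
  expect_equal(baseline_rate(forty), 40 / (40 * 0.075))
  # boundary convention: spike at exactly 0 is not baseline
  expect_equal(baseline_rate(list(c(0, -75))), 1 / 0.075)
})

test_that("corrected count integrates SDF minus baseline over 0-180 ms", {
  z <- compute_sdf(list(numeric(0)))
  expect_equal(corrected_spike_count(z, 0), 0)
  # density == 0, baseline 10 -> -1.8 spikes (signed integral preserved)
  expect_equal(corrected_spike_count(z, 10), -1.8)
  expect_equal(corrected_spike_count(z, 10, rectify = TRUE), 0)
  # one interior spike, zero baseline -> ~1 spike of kernel mass
  one <- compute_sdf(list(90))
  expect_lt(abs(corrected_spike_count(one, 0) - 1), 1e-6)
})

test_that("corrected count is linear in density and decreasing in baseline at 0.18", {
  withr::with_seed(3, trials <- poisson_trials(20, 15))
  sdf <- compute_sdf(trials)
  c0 <- corrected_spike_count(sdf, 0)
  for (b in c(1, 5, 12))
    expect_equal(corrected_spike_count(sdf, b), c0 - 0.18 * b)
  # doubling the density doubles the zero-baseline count
  sdf2 <- sdf
  sdf2$density <- 2 * sdf$density
  expect_equal(corrected_spike_count(sdf2, 0), 2 * c0)
})

test_that("analytic kernel-mass count agrees with the SDF-grid integral", {
  withr::with_seed(9, trials <- poisson_trials(40, 10))
  er <- evoked_response(trials)
  fast <- mismatchkit:::count_from_spikes(unlist(trials), length(trials),
                                          er$baseline_rate)
  # they differ only by the trapezoid boundary term at 0 and 180 ms
  expect_lt(abs(fast - er$corrected_count), 5e-3)
})

test_that("baseline estimator converges to the true rate with more trials", {
  rate <- 12
  errs <- vapply(c(20, 200, 2000), function(n) {
    withr::with_seed(n, tr <- poisson_trials(n, rate))
    abs(baseline_rate(tr) - rate)
  }, numeric(1))
  for (i in seq_along(errs)) {
    se <- sqrt(rate / (c(20, 200, 2000)[i] * 0.075))
    expect_lt(errs[i], 4 * se)
  }
  expect_lt(errs[3], errs[1])
})

test_that("waveform SNR follows the printed formula and the strict > 5 rule", {
  withr::with_seed(5, {
    template <- 10 * sin(seq(0, 2 * pi, length.out = 48)) # range 20
    wf <- t(replicate(300, template + rnorm(48, 0, 4)))
  })
  ws <- waveform_snr(wf)
  expect_lt(abs(ws$snr - 20 / 4), 0.3)
  # exact arithmetic on a hand-built matrix, and the strict > 5 acceptance
  m <- c(0, 10, -10, 0)
  resid <- rbind(c(1, -1, 1, -1), c(-1, 1, -1, 1))
  exact <- waveform_snr(rbind(m + resid[1, ], m + resid[2, ]))
  expect_equal(exact$snr, 20 / sd(as.vector(resid)))
  expect_identical(exact$accepted, exact$snr > 5)
  ident <- rbind(template, template)
  expect_warning(ws0 <- waveform_snr(ident), "Zero residual")
  expect_true(is.infinite(ws0$snr))
  expect_true(ws0$accepted)
  expect_error(waveform_snr(matrix(template, 1)), "at least 2")
})

test_that("FRA construction marks the excitatory region correctly", {
  # single supra-threshold cell
  g <- expand.grid(frequency_hz = c(1000, 2000, 4000), level_db = c(30, 50))
  g$corrected_count <- 0
  g$corrected_count[g$frequency_hz == 2000 & g$level_db == 50] <- 3
  fra <- build_fra(g)
  expect_equal(sum(fra$grid$excitatory), 1L)
  hit <- fra$grid[fra$grid$excitatory, ]
  expect_equal(c(hit$frequency_hz, hit$level_db), c(2000, 50))
  expect_equal(fra$thresholds$threshold_db, 50)
  # all cells at spontaneous level -> empty mask
  g$corrected_count <- 0
  expect_equal(sum(build_fra(g)$grid$excitatory), 0L)
  expect_error(build_fra(g[0, ]), "non-empty")
})

test_that("simulated tuned unit yields a mask centred on the best frequency", {
  nm <- neuron_model(best_frequency = 8000, spontaneous_rate = 3)
  freqs <- 1000 * 2^(0.5 * (0:10))
  fra <- simulate_fra(nm, freqs, seq(20, 70, 10), reps = 20, seed = 2)
  ex <- fra$grid[fra$grid$excitatory & fra$grid$level_db >= 50, ]
  expect_gt(nrow(ex), 0)
  centre <- stats::weighted.mean(log2(ex$frequency_hz), ex$response)
  expect_lt(abs(centre - log2(8000)), 0.5)
})
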