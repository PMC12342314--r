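test_that("neuron model validates its parameters", {
  expect_s3_class(neuron_model(), "neuron_model")
  expect_error(neuron_model(spontaneous_rate = -1), ">= 0")
  expect_error(neuron_model(adapt_b = 0.5), "adapt_b")
  expect_error(neuron_model(deviance_gain = -0.1), "deviance_gain")
})

test_that("with no evoked component spike counts are Poisson at the spontaneous rate", {
  nm <- neuron_model(peak_evoked_rate = 0, spontaneous_rate = 8)
  s <- make_cascade(2000 * 2^(0.5 * (0:9)), "ascending", level = 60)
  # 3 sequences of 400 tones = 1,200 trials
  counts <- unlist(lapply(1:3, function(k) {
    sp <- simulate_unit(nm, s, seed = k)
    tabulate(sp$tone_index, nbins = 400)
  }))
  mu <- 8 * 0.325
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # index of dispersion ~ 1 for Poisson counts
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.15)
})

test_that("simulation is deterministic given (neuron, sequence, seed)", {
  nm <- neuron_model()
  s <- make_oddball(8000, 11314, 60, seed = 2)
  expect_identical(simulate_unit(nm, s, seed = 9), simulate_unit(nm, s, seed = 9))
  expect_false(identical(simulate_unit(nm, s, seed = 9),
                         simulate_unit(nm, s, seed = 10)))
})

test_that("deviance gain doubles the evoked component when adaptation is off", {
  # a = 0, c = 1: adaptation state fixed at 1 for every presentation
  nm <- neuron_model(adapt_a = 0, adapt_c = 1, deviance_gain = 2,
                     spontaneous_rate = 4, peak_evoked_rate = 60,
                     best_frequency = 8000, tuning_bandwidth = 2)
  s <- make_oddball(8000, 8000 * 2^0.5, 60, seed = 1)
  counts_dev <- c(); counts_std <- c()
  for (k in 1:5) { # 5 x 400 tones = 2,000 trials
    sp <- simulate_unit(nm, s, seed = 20 + k)
    cnt <- tabulate(sp$tone_index, nbins = 400)
    counts_dev <- c(counts_dev, cnt[s$condition == "DEV"])
    counts_std <- c(counts_std, cnt[s$condition == "STD"])
  }
  base <- nm$spontaneous_rate * 0.325
  ratio <- (mean(counts_dev) - base) / (mean(counts_std) - base)
  # expected ratio = 2 x tuning(dev)/tuning(std); correct for tuning
  tun <- mismatchkit:::tuning_gain(nm, c(8000 * 2^0.5, 8000), 60)
  expect_lt(abs(ratio / (tun[1] / tun[2]) - 2), 0.25)
})

test_that("noiseless FRA peaks at the best frequency and quiets below threshold", {
  nm <- neuron_model(best_frequency = 8000, threshold = 30)
  freqs <- 1000 * 2^(0.5 * (0:10))
  fra <- simulate_fra(nm, freqs, seq(0, 70, 10), reps = 3, seed = 1,
                      noiseless = TRUE)
  top <- fra$grid[which.max(fra$grid$response), ]
  expect_equal(top$frequency_hz, freqs[which.min(abs(log2(freqs / 8000)))])
  sub <- simulate_fra(nm, freqs, c(0, 10, 20), reps = 3, seed = 1,
                      noiseless = TRUE)
  expect_true(all(sub$grid$response == 0))
})

test_that("FRA cell variability shrinks with more repetitions", {
  nm <- neuron_model(best_frequency = 8000)
  est <- function(reps, seed) {
    f <- simulate_fra(nm, 8000, 60, reps = reps, seed = seed)
    f$grid$response[1]
  }
  lo <- vapply(1:20, function(k) est(3, k), numeric(1))
  hi <- vapply(1:20, function(k) est(60, 100 + k), numeric(1))
  expect_lt(sd(hi), sd(lo))
})

test_that("noiseless per-channel evoked mass follows the generating power law", {
  nm <- neuron_model(adapt_a = 0.8, adapt_b = -0.7, adapt_c = 0.3,
                     spontaneous_rate = 0, best_frequency = 8000,
                     tuning_bandwidth = 2)
  s <- make_cascade(8000 * 2^(0.5 * (-4:5)), "ascending", 60)
  sp <- simulate_unit(nm, s, seed = 1)
  mass <- attr(sp, "evoked_mass")
  ch <- s$frequency_hz == 8000 # 40 presentations of one channel
  y <- mass[ch]
  fit <- fit_power_law(tibble::tibble(trial = 1:40, mean_response = y))
  scale_k <- y[1] / (nm$adapt_a + nm$adapt_c) # per-channel gain-to-mass factor
  expect_lt(abs(fit$b - nm$adapt_b) / abs(nm$adapt_b), 0.01)
  expect_lt(abs(fit$a - scale_k * nm$adapt_a) / (scale_k * nm$adapt_a), 0.01)
  expect_lt(abs(fit$c - scale_k * nm$adapt_c) / (scale_k * nm$adapt_c), 0.01)
})

test_that("cohort simulation is deterministic and honours the group plan", {
  cfg <- two_group_config(n_units = 2, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$units, b$units)
  expect_identical(a$spikes, b$spikes)
  expect_equal(nrow(a$units), 4L)
  expect_setequal(unique(a$units$exposure), c("control", "VPA"))
  expect_true(all(a$spikes$spike_time_ms >= -75 & a$spikes$spike_time_ms <= 250))
  # ground truth retrievable per unit
  expect_true(all(c("adapt_a", "adapt_b", "adapt_c", "deviance_gain",
                    "spont_rate_true") %in% names(a$units)))
})

test_that("a group with zero units is absent without disturbing the others", {
  groups <- default_groups()[1:2, ]
  groups$n_subjects <- 1L
  groups$n_units <- c(3L, 0L)
  cfg <- cohort_config(groups = groups, seed = 4)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$units), 3L)
  expect_equal(unique(paste(co$units$sex, co$units$age, co$units$exposure)),
               paste(groups$sex[1], groups$age[1], groups$exposure[1]))
  # the populated group's draws are unaffected by the empty one
  groups2 <- groups[1, ]
  co2 <- simulate_cohort(cohort_config(groups = groups2, seed = 4))
  expect_identical(co$spikes, co2$spikes)
})

test_that("per-subject spontaneous rates are gamma-like: positive and right-skewed", {
  groups <- default_groups()[1, ]
  groups$n_subjects <- 60L
  groups$n_units <- 1L
  co <- simulate_cohort(cohort_config(groups = groups, seed = 8))
  r <- co$units$spont_rate_true
  expect_true(all(r > 0))
  skew <- mean((r - mean(r))^3) / sd(r)^3
  expect_gt(skew, 0.3)
})
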