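test_that("oddball sequences satisfy the paradigm's ordering constraints", {
  s <- make_oddball(8000, 8000 * 2^0.5, level = 60, seed = 1)
  expect_s3_class(s, "stim_sequence")
  expect_equal(nrow(s), 400L)
  expect_equal(sum(s$condition == "DEV"), 40L)
  expect_true(all(s$condition[1:10] == "STD"))
  dev <- which(s$condition == "DEV")
  # every deviant preceded by >= 3 consecutive standards
  for (k in dev) expect_true(all(s$condition[(k - 3):(k - 1)] == "STD"))
  expect_equal(s$onset_ms, (s$index - 1) * 250)
  expect_setequal(unique(s$frequency_hz[s$condition == "DEV"]), 8000 * 2^0.5)
  expect_setequal(unique(s$frequency_hz[s$condition == "STD"]), 8000)
})

test_that("oddball constraints hold across many seeds and draws are seeded", {
  for (seed in 1:100) {
    s <- make_oddball(4000, 4000 * 2^-0.5, level = 40, seed = seed)
    dev <- which(s$condition == "DEV")
    expect_length(dev, 40L)
    expect_true(min(dev) > 10L)
    expect_true(all(diff(dev) >= 4L))
  }
  a <- make_oddball(4000, 5000, 60, seed = 7)
  b <- make_oddball(4000, 5000, 60, seed = 7)
  expect_identical(a, b)
  expect_false(identical(which(a$condition == "DEV"),
                         which(make_oddball(4000, 5000, 60, seed = 8)$condition == "DEV")))
})

test_that("oddball input validation", {
  expect_error(make_oddball(8000, 8000, 60, seed = 1), "differ")
  expect_error(make_oddball(8000, 9000, 60), "seed")
  expect_error(make_oddball(-1, 9000, 60, seed = 1), "positive")
  # generic detection of unsatisfiable placement constraints
  expect_error(mismatchkit:::draw_deviant_positions(50, 40, 10, 3), "unsatisfiable")
})

test_that("cascade sequences are regular scales at 10% per frequency", {
  fs <- 2000 * 2^(0.5 * (0:9))
  up <- make_cascade(fs, "ascending", level = 50)
  dn <- make_cascade(fs, "descending", level = 50)
  expect_equal(nrow(up), 400L)
  expect_true(all(up$condition == "CAS"))
  expect_equal(as.integer(table(up$frequency_hz)), rep(40L, 10))
  # one traversal is the sorted scale; descending is its exact reverse
  expect_equal(up$frequency_hz[1:10], sort(fs))
  expect_equal(dn$frequency_hz[1:10], rev(sort(fs)))
  expect_equal(dn$frequency_hz, rep(rev(sort(fs)), 40))
  expect_error(make_cascade(fs[1:9], "ascending"), "exactly 10")
  expect_error(make_cascade(c(fs[1:9], -5), "ascending"), "distinct|positive")
})

test_that("analysed-trial selection returns 40 deviants and their preceding standards", {
  s <- make_oddball(8000, 11314, 60, seed = 3)
  sel <- select_analyzed_trials(s)
  expect_length(sel$dev_indices, 40L)
  expect_length(sel$std_indices, 40L)
  expect_true(all(s$condition[sel$dev_indices] == "DEV"))
  expect_true(all(s$condition[sel$std_indices] == "STD"))
  expect_equal(sel$std_indices + 1L, sel$dev_indices)
  expect_length(intersect(sel$dev_indices, sel$std_indices), 0L)
  expect_error(select_analyzed_trials(make_cascade(2000 * 2^(0.5 * (0:9)), "ascending")),
               "oddball")
})

test_that("sequence serialisation round-trips and is byte-stable under a seed", {
  dir <- withr::local_tempdir()
  s <- make_oddball(8000, 11314, 60, seed = 5)
  p1 <- file.path(dir, "seq1.csv")
  p2 <- file.path(dir, "seq2.csv")
  write_sequence(s, p1)
  write_sequence(make_oddball(8000, 11314, 60, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
  r <- read_sequence(p1)
  expect_equal(as.data.frame(r), as.data.frame(s))
  expect_identical(attr(r, "kind"), attr(s, "kind"))
  expect_identical(attr(r, "seed"), attr(s, "seed"))
})

test_that("frequency selection places a 0.5-octave scale inside a known region", {
  freqs <- 1000 * 2^(0.5 * (0:10))
  levels <- seq(0, 70, 10)
  region <- freqs[4:7] # 1.5-octave excitatory block at 40-70 dB
  resp <- rect_fra_responses(freqs, levels, region, c(40, 50, 60, 70))
  fra <- build_fra(resp)
  sel <- select_stimulus_frequencies(fra)
  expect_s3_class(sel, "frequency_selection")
  expect_equal(diff(log2(sel$scale)), rep(0.5, 9))
  expect_gte(nrow(sel$oddball_pairs), 2L)
  # every returned pair is adjacent in the scale and inside the region
  for (i in seq_len(nrow(sel$oddball_pairs)))
    expect_equal(log2(sel$oddball_pairs$f_high[i] / sel$oddball_pairs$f_low[i]), 0.5)
})

test_that("frequency selection fails on narrow or absent excitatory regions", {
  freqs <- 1000 * 2^(0.5 * (0:10))
  levels <- seq(0, 70, 10)
  # region narrower than half an octave: a single frequency column
  resp <- rect_fra_responses(freqs, levels, freqs[5], c(50, 60, 70),
                             noise_sd = 0)
  expect_error(select_stimulus_frequencies(build_fra(resp)), "consecutive")
  flat <- rect_fra_responses(freqs, levels, numeric(0), numeric(0), noise_sd = 0)
  expect_error(select_stimulus_frequencies(build_fra(flat)),
               "no excitatory region")
})
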