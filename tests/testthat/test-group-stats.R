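test_that("Friedman test handles ties, strong orderings, and matches wrappers", {
  tied <- friedman_test(rep(1, 10), rep(1, 10), rep(1, 10))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_raw, 1)

  withr::with_seed(2, {
    dev <- 10 + rnorm(50, 0, 0.1)
    cas <- 5 + rnorm(50, 0, 0.1)
    std <- 1 + rnorm(50, 0, 0.1)
  })
  strong <- friedman_test(dev, std, cas)
  expect_lt(strong$p_raw, 0.001)
  expect_error(friedman_test(1:3, 1:4, 1:3), "equal length")
})

test_that("small-sample Friedman p equals the exact permutation null", {
  null_stats <- oracle_friedman_null(6)
  withr::with_seed(31, {
    for (i in 1:200) {
      y <- matrix(rnorm(18), ncol = 3)
      res <- friedman_test(y[, 1], y[, 2], y[, 3])
      stat <- oracle_friedman_stat(y)
      p_exact <- mean(null_stats >= stat - 1e-9)
      expect_true(res$exact)
      expect_equal(res$statistic, stat, tolerance = 1e-9)
      expect_equal(res$p_raw, p_exact, tolerance = 1e-9)
    }
  })
  # large samples fall back to the chi-square approximation
  withr::with_seed(32, big <- matrix(rnorm(60), ncol = 3))
  res_big <- friedman_test(big[, 1], big[, 2], big[, 3])
  expect_false(res_big$exact)
  expect_equal(res_big$p_raw, stats::friedman.test(big)$p.value)
})

test_that("rank-sum test matches exhaustive enumeration for small samples", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p_raw, oracle_wilcoxon_exact(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(w$p_raw, 2 / choose(6, 3))
  expect_equal(w$median_diff, 2 - 11)

  withr::with_seed(13, {
    for (i in 1:200) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 1), 1))
      expect_equal(wilcoxon_ranksum(x, y)$p_raw,
                   oracle_wilcoxon_exact(x, y), tolerance = 1e-10)
    }
  })
})

test_that("rank-sum normal approximation behaves on ties and identical samples", {
  x <- rep(c(1, 2, 3), 10)
  same <- wilcoxon_ranksum(x, x)
  expect_gt(same$p_raw, 0.9)
  expect_false(same$exact)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum test has high power for a 1-SD shift at n = 100", {
  withr::with_seed(41, {
    hits <- vapply(1:200, function(i) {
      wilcoxon_ranksum(rnorm(100), rnorm(100, 1))$p_raw < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.99)
})

test_that("BH step-up matches a direct threshold-scan oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.1)
  expect_equal(sum(out$significant), 3L)
  expect_equal(sum(bh_fdr(rep(1, 6))$significant), 0L)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  withr::with_seed(7, {
    for (i in 1:300) {
      m <- sample(1:20, 1)
      p <- runif(m)^sample(1:3, 1)
      q <- sample(c(0.05, 0.1, 0.2), 1)
      res <- bh_fdr(p, q)
      expect_identical(res$significant, oracle_bh_decisions(p, q))
      # adjusted p monotone in raw-p rank
      expect_true(all(diff(res$p_adj[order(res$p_raw)]) >= -1e-12))
    }
  })
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03, 0.04, 0.05))[1], 0.05)
  expect_equal(bonferroni(c(0.5, 0.6, 0.7, 0.8)), rep(1, 4))
  expect_equal(bonferroni(0.3), 0.3)
})

test_that("Spearman correlation matches the rank-difference formula", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman(x, x)$statistic, 1)
  expect_equal(spearman(x, -x)$statistic, -1)
  withr::with_seed(19, {
    for (i in 1:100) {
      a <- rnorm(5); b <- rnorm(5)
      expect_equal(spearman(a, b)$statistic, oracle_spearman_rho(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman(rep(1, 5), rnorm(5)), "Constant")
  expect_error(spearman(1:2, 2:3), "3 complete")
})

make_points <- function(n, group, imm_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    dev <- pmax(rnorm(n, 0.6 + imm_shift, 0.05), 0)
    std <- pmax(rnorm(n, 0.35, 0.05), 0)
    cas <- pmax(rnorm(n, 0.69, 0.05), 0)
  })
  dplyr::bind_cols(
    tibble::tibble(unit_id = paste0(group$exposure, "_", rep(seq_len(ceiling(n / 2)),
                                                             each = 2)[1:n]),
                   sex = group$sex, age = group$age, exposure = group$exposure,
                   division = "lemniscal", level_class = "high"),
    mismatch_indices(dev, std, cas)
  )
}

test_that("group summaries report medians and Friedman p per stratum", {
  g1 <- list(sex = "F", age = "prepubertal", exposure = "control")
  pts <- make_points(80, g1, seed = 3)
  tab <- summarize_groups(pts)
  row <- tab[tab$exposure == "control" & !is.na(tab$n_points), ]
  expect_equal(row$n_points, 80L)
  expect_equal(row$n_neurons, 40L)
  expect_equal(row$dev, median(pts$dev_norm))
  # constructed around (0.60, 0.35, 0.69): median iMM near 0.25
  expect_lt(abs(row$imm - 0.25), 0.05)
  expect_lt(row$p_imm, 0.001)
  expect_true(all(c("p_imm_adj", "p_irs_adj", "p_ipe_adj") %in% names(tab)))
})

test_that("empty strata appear as missing-value rows without disturbing others", {
  a <- make_points(30, list(sex = "M", age = "adult", exposure = "control"),
                   seed = 8)
  b <- make_points(30, list(sex = "F", age = "adult", exposure = "VPA"),
                   seed = 9)
  tab <- summarize_groups(dplyr::bind_rows(a, b))
  # full crossing of observed labels: 2 sexes x 1 age x 2 exposures
  expect_equal(nrow(tab), 4L)
  empty <- tab[tab$sex == "M" & tab$exposure == "VPA", ]
  expect_equal(empty$n_points, 0L)
  expect_true(is.na(empty$imm))
  full <- tab[tab$sex == "M" & tab$exposure == "control", ]
  expect_equal(full$n_points, 30L)
  expect_false(is.na(full$imm))
})

test_that("group comparisons recover an injected mismatch reduction", {
  ctrl <- make_points(60, list(sex = "M", age = "adult", exposure = "control"),
                      seed = 5)
  vpa <- make_points(60, list(sex = "M", age = "adult", exposure = "VPA"),
                     imm_shift = -0.12, seed = 6)
  cmp <- compare_groups(dplyr::bind_rows(ctrl, vpa))
  imm_row <- cmp[cmp$measure == "imm", ]
  expect_equal(nrow(imm_row), 1L)
  # orient the difference as control minus exposed, whatever the row order
  ctrl_minus_vpa <- if (grepl("control", imm_row$group_a))
    imm_row$median_diff else -imm_row$median_diff
  expect_gt(ctrl_minus_vpa, 0)
  expect_true(imm_row$significant)
  expect_error(compare_groups(ctrl), "two groups")
})
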