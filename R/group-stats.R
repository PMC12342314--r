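#' Nonparametric statistical layer
#'
#' All tests return one-row "stat result" tibbles with a common shape:
#' `test`, `statistic`, `p_raw`, `p_adj`, `correction`, `n1`, `n2` (plus
#' test-specific extras), so batteries of comparisons bind into tidy tables
#' and flow straight into the correction helpers.
#'
#' @name group_stats
NULL

stat_result <- function(test, statistic, p_raw, n1, n2 = NA_integer_, ...) {
  tibble(test = test, statistic = unname(statistic), p_raw = unname(p_raw),
         p_adj = NA_real_, correction = "none",
         n1 = n1, n2 = n2, ...)
}

#' Friedman test across matched conditions
#'
#' Rank test for a difference among the paired DEV/STD/CAS responses of the
#' same unit-frequency points. For small samples (<= 10 complete tuples, no
#' within-tuple ties) the p-value comes from the exact permutation null of
#' the Friedman statistic (computed by dynamic programming over rank-sum
#' states — the chi-square approximation is off by up to ~0.13 at these
#' sizes); larger or tied samples use the chi-square approximation. With
#' every row fully tied the statistic is 0 and p = 1. `cas` may be omitted
#' for the two-condition (paired-sign) variant used for the per-index tests.
#'
#' @param dev,std,cas Numeric vectors, matched by position (same points).
#' @return A one-row stat-result tibble (with `df` and `exact`).
#' @export
friedman_test <- function(dev, std, cas = NULL) {
  cols <- if (is.null(cas)) list(dev, std) else list(dev, std, cas)
  n <- unique(lengths(cols))
  if (length(n) != 1L) abort("Condition vectors must have equal length.")
  y <- do.call(cbind, cols)
  y <- y[complete.cases(y), , drop = FALSE]
  if (nrow(y) < 2L) abort("Need >= 2 complete condition tuples.")
  if (all(apply(y, 1, function(r) max(r) == min(r)))) {
    # every row fully tied: no evidence of any condition effect
    return(stat_result("friedman", 0, 1, nrow(y), df = ncol(y) - 1L,
                       exact = FALSE))
  }
  row_ties <- any(apply(y, 1, anyDuplicated) > 0)
  use_exact <- !row_ties && nrow(y) <= 10L && ncol(y) <= 3L
  if (use_exact) {
    ranks <- t(apply(y, 1, rank))
    res <- friedman_exact(ranks)
    stat_result("friedman", res$statistic, res$p, nrow(y),
                df = ncol(y) - 1L, exact = TRUE)
  } else {
    ft <- friedman.test(y)
    stat_result("friedman", ft$statistic, ft$p.value, nrow(y),
                df = unname(ft$parameter), exact = FALSE)
  }
}

# Exact permutation null of the Friedman statistic: dynamic programming over
# the joint distribution of the first k-1 column rank sums under independent
# uniform within-row rank permutations.
friedman_exact <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  perms <- if (k == 2L) {
    rbind(c(1, 2), c(2, 1))
  } else {
    rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  }
  stat_of <- function(s_free) {
    s_last <- n * k * (k + 1) / 2 - sum(s_free)
    12 / (n * k * (k + 1)) * (sum(s_free^2) + s_last^2) - 3 * n * (k + 1)
  }
  states <- setNames(1, paste(rep(0, k - 1), collapse = ","))
  inc <- perms[, seq_len(k - 1), drop = FALSE]
  for (row in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    prev_keys <- names(states)
    prev_vals <- unname(states)
    for (j in seq_along(prev_keys)) {
      s <- as.integer(strsplit(prev_keys[j], ",", fixed = TRUE)[[1]])
      for (pi in seq_len(nrow(inc))) {
        key <- paste(s + inc[pi, ], collapse = ",")
        nxt[[key]] <- (nxt[[key]] %||% 0) + prev_vals[j] / nrow(perms)
      }
    }
    keys <- ls(nxt)
    states <- setNames(vapply(keys, function(kk) nxt[[kk]], numeric(1)), keys)
  }
  stats_null <- vapply(names(states), function(kk) {
    stat_of(as.integer(strsplit(kk, ",", fixed = TRUE)[[1]]))
  }, numeric(1))
  obs <- stat_of(colSums(ranks[, seq_len(k - 1), drop = FALSE]))
  list(statistic = obs, p = sum(states[stats_null >= obs - 1e-9]))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum comparison of two independent samples. Small samples
#' (both sizes <= `exact_max`, no ties) use the exact null distribution;
#' otherwise the normal approximation with continuity and tie correction.
#' The unadjusted median difference `median(x) - median(y)` is reported
#' alongside.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact test (default 10).
#' @return A one-row stat-result tibble (with `median_diff`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 10) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  stat_result("wilcoxon_ranksum", wt$statistic, wt$p.value,
              length(x), length(y),
              median_diff = median(x) - median(y), exact = use_exact)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR control at rate `q` (the analysis default is q = 0.1):
#' adjusted p-values via the standard BH transformation; a hypothesis is
#' rejected when its adjusted p is <= q, equivalent to the step-up rule over
#' the thresholds `i q / m`.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q FDR level (default 0.1).
#' @return Tibble with `p_raw`, `p_adj`, `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    abort("p-values must be in [0, 1].")
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_raw = p_values, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m p)` with family size `m = length(p_values)`.
#'
#' @inheritParams bh_fdr
#' @return Vector of adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    abort("p-values must be in [0, 1].")
  pmin(1, length(p_values) * p_values)
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric samples, n >= 3; constant input is an error.
#' @return A one-row stat-result tibble (statistic = rho).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Constant input: Spearman correlation undefined.")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  stat_result("spearman", ct$estimate, ct$p.value, length(x))
}

#' Group-level median summary table
#'
#' Summarises an indexed, filtered per-point table into one row per
#' experimental group within each division x level-class stratum: neuron and
#' point counts, median normalised DEV/STD/CAS responses, median iMM/iRS/iPE,
#' and a per-index Friedman p (paired test of the two constituent responses)
#' BH-corrected within the stratum. Empty strata yield rows of `NA`.
#'
#' @param points Tibble with columns `unit_id`, `sex`, `age`, `exposure`,
#'   `division`, `level_class`, `dev_norm`, `std_norm`, `cas_norm`, `imm`,
#'   `irs`, `ipe`.
#' @param q FDR level for the within-stratum correction (default 0.1).
#' @return A tibble, one row per group x division x level_class.
#' @export
summarize_groups <- function(points, q = 0.1) {
  points <- as_tibble(points)
  need <- c("unit_id", "sex", "age", "exposure", "division", "level_class",
            "dev_norm", "std_norm", "cas_norm", "imm", "irs", "ipe")
  if (!all(need %in% names(points)))
    abort(paste("`points` must have columns:", paste(need, collapse = ", ")))

  tab <- points |>
    group_by(.data$sex, .data$age, .data$exposure, .data$division,
             .data$level_class) |>
    summarise(
      n_neurons = dplyr::n_distinct(.data$unit_id),
      n_points = n(),
      dev = median(.data$dev_norm), std = median(.data$std_norm),
      cas = median(.data$cas_norm),
      imm = median(.data$imm), irs = median(.data$irs), ipe = median(.data$ipe),
      p_imm = paired_index_p(.data$dev_norm, .data$std_norm),
      p_irs = paired_index_p(.data$cas_norm, .data$std_norm),
      p_ipe = paired_index_p(.data$dev_norm, .data$cas_norm),
      .groups = "drop"
    )
  tab <- tab |>
    group_by(.data$division, .data$level_class) |>
    mutate(across(c("p_imm", "p_irs", "p_ipe"),
                  ~ p.adjust(.x, method = "BH"),
                  .names = "{.col}_adj")) |>
    ungroup() |>
    mutate(fdr_q = q)
  # emit empty crossing cells as missing-value rows
  tab |>
    tidyr::complete(.data$sex, .data$age, .data$exposure, .data$division,
                    .data$level_class,
                    fill = list(n_neurons = 0L, n_points = 0L, fdr_q = q))
}

# Friedman (k = 2) test of the paired responses composing one index.
paired_index_p <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  tryCatch(friedman_test(x, y)$p_raw, error = function(e) NA_real_)
}

#' Pairwise group comparisons
#'
#' Wilcoxon rank-sum comparisons of per-point measures between all pairs of
#' experimental groups, run separately within each division x level-class
#' stratum, with multiplicity correction per stratum x measure family
#' (BH FDR at `q`, the group-level default, or Bonferroni for
#' population-level batteries).
#'
#' @inheritParams summarize_groups
#' @param measures Columns of `points` to compare (default the three
#'   indices).
#' @param correction `"bh_fdr"` or `"bonferroni"`.
#' @param q FDR level when `correction = "bh_fdr"`.
#' @return Comparison-matrix tibble: `group_a`, `group_b`, `measure`,
#'   `division`, `level_class`, `n_a`, `n_b`, `median_diff`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
compare_groups <- function(points, measures = c("imm", "irs", "ipe"),
                           correction = c("bh_fdr", "bonferroni"), q = 0.1) {
  correction <- match.arg(correction)
  points <- as_tibble(points)
  points$group <- paste(points$sex, points$age, points$exposure, sep = "_")

  strata <- points |>
    dplyr::distinct(.data$division, .data$level_class)
  rows <- list()
  for (si in seq_len(nrow(strata))) {
    stratum <- points |>
      filter(.data$division == strata$division[si],
             .data$level_class == strata$level_class[si])
    groups <- sort(unique(stratum$group), method = "radix")
    if (length(groups) < 2L) next
    pairs <- utils::combn(groups, 2)
    for (m in measures) {
      fam <- purrr::map(seq_len(ncol(pairs)), function(k) {
        xa <- stratum[[m]][stratum$group == pairs[1, k]]
        xb <- stratum[[m]][stratum$group == pairs[2, k]]
        w <- wilcoxon_ranksum(xa, xb)
        tibble(group_a = pairs[1, k], group_b = pairs[2, k], measure = m,
               division = strata$division[si],
               level_class = strata$level_class[si],
               n_a = length(xa), n_b = length(xb),
               median_diff = w$median_diff, p_raw = w$p_raw)
      }) |> bind_rows()
      if (correction == "bh_fdr") {
        adj <- bh_fdr(fam$p_raw, q = q)
        fam$p_adj <- adj$p_adj
        fam$significant <- adj$significant
      } else {
        fam$p_adj <- bonferroni(fam$p_raw)
        fam$significant <- fam$p_adj <= 0.05
      }
      rows[[length(rows) + 1L]] <- fam
    }
  }
  if (length(rows) == 0L)
    abort("Fewer than two groups in every stratum; nothing to compare.")
  bind_rows(rows)
}
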