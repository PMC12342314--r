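# Independent brute-force oracles, written from the definitions only.

# Benjamini-Hochberg step-up by direct threshold scan.
oracle_bh_decisions <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Exact two-sided rank-sum p by full enumeration of group assignments
# (no ties assumed). Statistic: Mann-Whitney U of the first sample.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  centre <- n1 * length(y) / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# Exact permutation null of the Friedman chi-square statistic for n rows,
# k = 3 conditions, no ties: enumerate all within-row rank orderings once.
oracle_friedman_null <- function(n) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- as.matrix(expand.grid(rep(list(1:6), n)))
  s1 <- rowSums(matrix(perms[idx, 1], nrow(idx)))
  s2 <- rowSums(matrix(perms[idx, 2], nrow(idx)))
  s3 <- rowSums(matrix(perms[idx, 3], nrow(idx)))
  12 / (n * 3 * 4) * (s1^2 + s2^2 + s3^2) - 3 * n * 4
}

oracle_friedman_stat <- function(y) {
  n <- nrow(y); k <- ncol(y)
  ranks <- t(apply(y, 1, rank))
  s <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(s^2) - 3 * n * (k + 1)
}

# Spearman rho from the classical rank-difference formula (no ties).
oracle_spearman_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
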