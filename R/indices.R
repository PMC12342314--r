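#' Euclidean normalisation of DEV/STD/CAS responses
#'
#' Places each unit-frequency combination's three baseline-corrected spike
#' counts on the unit sphere: components are the (rectified) counts divided
#' by their Euclidean norm `N = sqrt(DEV^2 + STD^2 + CAS^2)`, making
#' responses comparable across neurons. Negative corrected counts are
#' rectified to 0 before normalisation by default, which guarantees
#' components in \[0, 1\] and indices in \[−1, 1\]; set `rectify = FALSE`
#' for the signed variant (components may then leave \[0, 1\] and indices
#' \[−1, 1\]).
#'
#' All-zero triplets (after rectification) have no direction and are an
#' error — such combinations should already have been removed by the
#' significance filter.
#'
#' @param dev,std,cas Baseline-corrected spike counts (vectors of equal
#'   length).
#' @param rectify Rectify negative counts to 0 first (default `TRUE`).
#' @return A tibble with columns `dev_norm`, `std_norm`, `cas_norm`,
#'   `norm` (the Euclidean norm, in spikes).
#' @examples
#' normalize_triplet(3, 4, 0)
#' @export
normalize_triplet <- function(dev, std, cas, rectify = TRUE) {
  if (!(length(dev) == length(std) && length(std) == length(cas)))
    abort("`dev`, `std`, `cas` must have equal length.")
  if (rectify) {
    dev <- pmax(dev, 0); std <- pmax(std, 0); cas <- pmax(cas, 0)
  }
  n <- sqrt(dev^2 + std^2 + cas^2)
  if (any(n == 0))
    abort("All-zero triplet(s): normalisation undefined (filter these combinations first).")
  tibble(dev_norm = dev / n, std_norm = std / n, cas_norm = cas / n, norm = n)
}

#' Neuronal mismatch decomposition
#'
#' From normalised DEV/STD/CAS responses computes the neuronal mismatch
#' index and its two components:
#' * `imm = dev_norm − std_norm` (neuronal mismatch),
#' * `irs = cas_norm − std_norm` (repetition suppression),
#' * `ipe = dev_norm − cas_norm` (prediction error),
#'
#' so that `imm = irs + ipe` identically. With rectified normalised inputs
#' all three indices lie in \[−1, 1\].
#'
#' @param triplet A tibble from [normalize_triplet()] (columns `dev_norm`,
#'   `std_norm`, `cas_norm`; extra columns are passed through).
#' @return The input tibble with columns `imm`, `irs`, `ipe` added.
#' @examples
#' compute_indices(normalize_triplet(3, 4, 0))
#' @export
compute_indices <- function(triplet) {
  triplet <- as_tibble(triplet)
  need <- c("dev_norm", "std_norm", "cas_norm")
  if (!all(need %in% names(triplet)))
    abort("`triplet` must have columns dev_norm, std_norm, cas_norm.")
  mutate(triplet,
         imm = .data$dev_norm - .data$std_norm,
         irs = .data$cas_norm - .data$std_norm,
         ipe = .data$dev_norm - .data$cas_norm)
}

#' @rdname compute_indices
#' @inheritParams normalize_triplet
#' @details `mismatch_indices()` chains [normalize_triplet()] and
#'   [compute_indices()] for raw corrected counts.
#' @export
mismatch_indices <- function(dev, std, cas, rectify = TRUE) {
  compute_indices(normalize_triplet(dev, std, cas, rectify = rectify))
}
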