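# Internal helpers shared across modules.

# Evaluate `expr` under a local, seeded RNG without touching the caller's
# .Random.seed. All randomness in the package funnels through this.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic seed derivation: one master seed, distinct child streams per
# (stage, index). Adding units never perturbs the draws of existing ones
# because each child seed depends only on its own labels. Kept < 2^31 - 1.
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- as.double(master %% m)
  for (k in c(...)) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * 31^(seq_along(utf8ToInt(k)) %% 7)) else as.double(k)
    s <- (s * 48271 + kk + 1) %% m
  }
  as.integer(s)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
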