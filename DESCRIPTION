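Package: mismatchkit
Title: Single-Unit Auditory Predictive-Processing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying stimulus-specific adaptation and neuronal
    mismatch in auditory single-unit recordings. Generates oddball and
    cascade pure-tone stimulus sequences, simulates spike trains of tuned,
    adapting, deviance-sensitive neurons organised into experimental
    cohorts, extracts Gaussian-kernel spike-density functions and
    baseline-corrected spike counts, screens responses with a Monte-Carlo
    Poisson significance test, decomposes the neuronal mismatch index into
    repetition-suppression and prediction-error components, models
    adaptation time courses with bootstrapped power-law fits and
    half-adaptation times, and compares experimental groups with
    nonparametric tests under Benjamini-Hochberg or Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
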