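---
title: "Neuronal mismatch analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal mismatch analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(mismatchkit)
library(dplyr)
```

mismatchkit implements the single-unit analysis used to study predictive
processing in the auditory midbrain: the oddball paradigm with its cascade
control, spike-density-based response extraction, a Monte-Carlo screen for
evoked activity, the Euclidean-normalised mismatch decomposition
(iMM = iRS + iPE), power-law adaptation dynamics, and the nonparametric
group-comparison layer. Because no raw spike data are publicly deposited for
this paradigm, the package also ships a first-class synthetic-data generator
that emulates the recording design, so every stage can be exercised and
validated end to end against known ground truth.

This vignette is the package's own account of the underlying models, the
parameters that matter, and the places where the design was genuinely open.

## Stimulation model

An **oddball sequence** is 400 pure tones at 4 Hz (250 ms onset-to-onset;
75 ms tones with 5 ms ramps, kept as metadata only — no audio is
synthesised). A deviant frequency replaces the standard with 10%
probability: exactly 40 deviants, the first 10 tones always standards, and
at least 3 standards before every deviant. Only the last standard before
each deviant is analysed, so one sequence yields 40 deviant and 40 matched
standard trials.

Deviant placement is sampled *uniformly over all admissible position sets*
via a combinatorial bijection: choosing 40 of 273 free slots and re-inflating
the mandatory 3-standard gaps reproduces every admissible configuration
exactly once. Naive rejection sampling over positions 11–400 has an
acceptance probability of about $\binom{273}{40}/\binom{390}{40} \approx
10^{-7}$ per draw round and is not a practical option; the bijection is
exact, seeded and always terminates.

The **cascade control** presents the 10-tone, half-octave scale as 40
deterministic ascending (or descending) traversals. Each frequency thus
keeps the deviant's 10% presentation probability and the 4 Hz refractory
state, but no frequency ever repeats back-to-back, so no repetition-based
regularity forms. We implement the regular-scale reading (rather than
pseudorandom embedding) because the control's logic rests on the scale
regularity.

**Frequency selection** from a frequency response area (FRA) places the
half-octave scale so that the longest possible run of consecutive members
falls in the excitatory region, and returns all adjacent in-region pairs as
oddball candidates. The excitatory region is not quantitatively defined in
the field's descriptions; we use cells whose mean baseline-corrected
response exceeds `threshold_mult` (default 2) standard errors. With the 3–5
FRA repetitions typical of the protocol this criterion is noisy, so the
automatic level choice scans recorded levels in order of proximity to
threshold + offset (default 15 dB, within the conventional 10–20 dB) and
keeps the first level that supports a valid scale.

## Synthetic spike trains

`simulate_unit()` draws inhomogeneous-Poisson spike trains over
[−75, 250] ms per tone with rate

$$r(t) = r_{\text{spont}} + P\; g(f, L)\; s(f, n)\; d\; k(t),$$

with Gaussian log-frequency tuning $g$ (SD = `tuning_bandwidth` octaves,
saturating linear level term above threshold), a peak-normalised alpha
kernel $k$ (time constant 10 ms, latency 10 ms — spike-density functions in
this preparation show no specific kernel model, so a standard alpha response
is used), deviance gain $d$ on deviant tones, and the frequency-specific
adaptation state $s(f, n) = a\,n^b + c$ after the $n$-th presentation of
frequency $f$. Each frequency keeps its own presentation counter, which is
precisely why cascade tones adapt about ten times more slowly per channel
than an oddball standard — the design rationale of the control, reproduced
mechanistically. Negative states are clipped at zero and counted.

Defaults (`neuron_model()`): spontaneous 5 spikes/s, peak evoked
100 spikes/s, adaptation $(a, b, c) = (1, -0.6, 0.2)$, deviance gain 0.9.
No quantitative deviance-gain magnitude exists to copy; these values were
chosen once so that a default unit produces median normalised responses in
the empirically reported ranges (standards strongly adapted relative to
cascade, mismatch positive, prediction-error slightly negative) and were
not revisited. A deviance gain *below 1* is what reproduces the negative
prediction-error indices characteristic of the inferior colliculus.

`simulate_cohort()` arranges units into the study's design: eight groups
(sex × age × prenatal exposure), each with subjects and units, every unit
assigned a division (lemniscal / non-lemniscal) and a level class
(high ≥ 40 dB SPL / low). Per-subject spontaneous rates are gamma
distributed (shape 2 — positive and right-skewed, as reported for this
preparation) with a lognormal unit-level jitter. Non-lemniscal units get a
reduced steady-state adaptation floor (×0.3), which reproduces the much
lower standard responses (and hence larger mismatch) of that division.
Group rows carry multiplicative effects on spontaneous rate, adaptation
parameters and deviance gain; these are the knobs used to inject known
group differences for recovery tests.

What the generator does *not* emulate: burst/refractory spike statistics
(counts are exactly Poisson), level-dependent latency shifts, inhibitory
sidebands, slow drift, or anaesthesia-state fluctuations. Passing tests
therefore validate the analysis pipeline's arithmetic and statistical
behaviour on a faithful rendering of the design — not the biological
realism of any particular parameter value.

## Response extraction

The spike-density function is the trial-averaged Gaussian-kernel smoothed
histogram: kernel SD 6 ms (the density-estimation reading of a "6 ms
Gaussian kernel", configurable), 1-ms grid on [−75, 250] ms, in spikes/s.
Kernel mass outside the window is truncated, not renormalised, so the
spike-mass conservation property is asserted only for interior spikes
(≥ 4 SDs from the edges), where it holds to 1e−6.

The baseline is the mean rate over [−75, 0) ms; the baseline-corrected
spike count is the *signed* trapezoidal integral of (SDF − baseline) over
[0, 180] ms. The signed reading (rather than rectifying at baseline) keeps
the statistic distributionally comparable with its Monte-Carlo null, which
must be allowed to go negative; `rectify = TRUE` provides the other
variant. The count is linear in the SDF and decreases in the baseline at
exactly 0.18 spikes per (spike/s).

Internally, bulk counting uses the analytic identity that the integral of a
spike's Gaussian kernel over [0, 180] ms is a difference of normal CDFs.
This equals the grid trapezoid up to the Euler–Maclaurin boundary term
(< ~1e−3 spikes, only for spikes near the window edges); a test pins the
agreement of the two routes.

## Monte-Carlo significance screen

Each unit–frequency–condition trial set is tested for evoked activity:
`n_sim` (default 1,000) surrogate sets of the same trial count are drawn as
homogeneous Poisson processes, reduced through the identical
count path, and $p = (g + 1)/(N + 1)$ with $g$ the number of null counts at
or above the observed one. A combination is retained when any of DEV, STD,
CAS has $p < \alpha$ (default 0.05 — conventional, and conservative
relative to the ~0.001 attainable floor).

Two calibration-critical choices deserve emphasis:

* **every null replicate re-estimates its own baseline** from its own
  pre-stimulus window, exactly as the observed data do. Correcting the null
  with the observed baseline omits the baseline-estimation variance and
  inflates the false-positive rate to ~0.21 at nominal 0.05 (5 spikes/s,
  40 trials);
* **the null simulation rate is the constant-rate maximum-likelihood
  estimate under the null** — all spikes over the whole window — rather
  than the short pre-stimulus window alone. Under the null hypothesis the
  rate is constant, so the full window is the efficient estimate; using the
  75-ms baseline window leaves the empirical level at 0.07–0.08 across
  realistic rates, while the full-window estimate yields 0.047–0.05
  (measured at 5 and 20 spikes/s). Under genuine evoked activity the
  full-window rate is inflated, making the screen mildly conservative —
  the safe direction for an inclusion filter.

Only the excitatory direction is tested; suppressed responses are not
flagged.

## Mismatch decomposition

Retained DEV/STD/CAS counts are rectified at zero and divided by their
Euclidean norm, then

* iMM = DEV − STD (neuronal mismatch),
* iRS = CAS − STD (repetition suppression),
* iPE = DEV − CAS (prediction error),

so iMM = iRS + iPE identically and all indices lie in [−1, 1].
Rectification before normalisation is what guarantees those ranges; the
unrectified variant is available (`rectify = FALSE`) with the documented
caveat that components may leave [0, 1]. Where descriptions of iRS
conflict (one passage reverses the difference), the CAS − STD convention
is used: it is the one consistent with the published positive
repetition-suppression medians. All-zero triplets are an error by design —
they should never survive the significance filter.

## Adaptation dynamics

Average time courses are per-position means across units of the per-trial
baseline-corrected counts. The power law $y(t) = a\,t^b + c$ is fitted by
bounded Levenberg–Marquardt least squares ($b \le 0$, $c \ge 0$) from a
fixed multi-start grid ($a \in \{0.1, 0.5, 1\}$ plus a data-driven start,
$b \in \{-0.3, -0.8, -1.5\}$, $c \in \{0, \mathrm{median}(y)\}$), best
residual sum of squares winning — deterministic given the data. Trials are
indexed from 1 (the model is undefined at 0; no origin is conventionally
stated). Fits with $r^2 \ge 0.65$ are flagged high quality; constant series
(zero total variance) and all-start non-convergence are reported as failed
fits rather than numbers.

The bootstrap resamples *units* with replacement, averages, interpolates
the average onto the common trial grid, and refits, 1,000 times by default.
Descriptions of the original "interpolated iterations" are ambiguous about
what was resampled; unit-level resampling is the scheme under which
iteration-to-iteration variability has a defined meaning, and it is
documented as such. Failed iterations are dropped and counted.

Half-adaptation of the standard course uses the first 15 s (60 trials at
4 Hz): initial = value at trial 1, final = mean of the last five in-window
values (a plain noise-robust estimator; none is conventionally specified),
half level = their midpoint, crossing found by linear interpolation. A
course that does not decay has no half-adaptation time and is reported as
undefined rather than extrapolated.

## Group statistics

Comparisons operate on per-point values (unit × frequency pair) pooled
within groups — the "points" convention of the published summary tables;
neuron-level aggregation can be had by averaging first. The layer wraps the
classical nonparametric tests in tidy one-row results: Friedman across
matched conditions, two-sided Wilcoxon rank-sum between groups, Spearman
correlation, Benjamini–Hochberg FDR (q = 0.1) for group-level batteries and
Bonferroni for population-level ones. Exact small-sample behaviour:

* rank-sum p-values are exact for both groups ≤ 10 without ties, normal
  approximation with continuity and tie correction otherwise;
* Friedman p-values are exact for ≤ 10 complete tuples without ties,
  computed by dynamic programming over rank-sum states. This departs from
  the usual chi-square habit deliberately: at these sizes the chi-square
  approximation deviates from the exact permutation null by up to ~0.13,
  which is material when p-values sit near conventional thresholds.

Multiplicity families are one division × level panel per measure — family
definitions behind published corrected values are not recoverable, so the
panel convention is the documented default and is configurable. Median
differences are reported alongside every comparison. Empty strata appear
as missing-value rows rather than silently vanishing.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → extract → screen → index → summarise →
compare → adaptation fits under a single master seed. Per-stage,
per-unit seeds are derived arithmetically from labels, so adding units
never perturbs existing units' draws, and a rerun with the same
configuration reproduces every number; the JSON manifest echoes the seed,
parameters and per-stage counts needed to reproduce a run. The package's
functions (plus this vignette and the repository's `scripts/acceptance.R`)
are the intended interface; no separate command-line binary is shipped.

```{r pipeline, eval = FALSE}
cfg <- run_config(
  cohort = cohort_config(n_subjects = 2, n_units = 6, seed = 1),
  n_sim = 200, seed = 1
)
run <- run_pipeline(cfg, out_dir = "run1")
run$group_summary
```

The shipped examples and tests run at deliberately desk-scale sizes —
a few units per subject, Monte-Carlo nulls of 60–200, bootstraps of
50–200 — chosen so the full validation suite completes in minutes while
still exercising every code path; the analysis defaults
(`n_sim = 1000`, `n_iter = 1000`) match the published operating points and
are what production runs should use. Calibration and recovery checks run at
their published operating points: 2,000 repetitions for the Monte-Carlo
level, 500 seeds for the sequence contract, 100 noisy replicates for
power-law recovery, 1,000 random instances per statistical oracle.

## Known limitations

* The Poisson spiking model understates the overdispersion of real bursty
  units; Monte-Carlo calibration statements apply to Poisson-like activity.
* The excitatory-region rule (2 × SE) is a pragmatic stand-in for a
  quantity the experimental literature leaves undefined; FRA-based
  selection is correspondingly noisy at 3–5 repetitions.
* Table-level biological results from the original 903-neuron dataset
  cannot be reproduced without the raw recordings; the package validates
  the *method* via construction, calibration and ground-truth recovery
  instead, plus a qualitative end-to-end check that injected exposure
  effects propagate with the correct sign.
* Generalised linear mixed-effects modelling of group effects is out of
  scope by design; standard mixed-model packages operate directly on the
  per-point index tables this package emits.
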