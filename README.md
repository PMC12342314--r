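# mismatchkit

Single-unit auditory predictive-processing analysis in R: stimulus
generation for the oddball paradigm and its cascade control, spike-density
response extraction, Monte-Carlo significance screening, the neuronal
mismatch index decomposition, power-law adaptation dynamics, and
nonparametric group statistics — together with a synthetic spike-train
generator that emulates the full recording design so every stage can be
validated against known ground truth.

## The problem

Neurons in the auditory midbrain respond more strongly to a rare *deviant*
(DEV) tone than to a frequent *standard* (STD) — a single-neuron analogue
of mismatch negativity. That difference confounds two mechanisms:
adaptation to repetition, and genuine prediction-error signalling. The
*cascade* control (CAS) presents the deviant frequency at the same 10%
probability and 4 Hz rate, embedded in a regular ascending or descending
half-octave scale, so it shares the deviant's adaptation state without ever
establishing a repetition. Baseline-corrected spike counts for the three
conditions are projected onto the unit sphere,

    N = sqrt(DEV² + STD² + CAS²),   dev = DEV/N,  std = STD/N,  cas = CAS/N

and decomposed as

    iMM = dev − std   (neuronal mismatch)
    iRS = cas − std   (repetition suppression)
    iPE = dev − cas   (prediction error),     iMM = iRS + iPE

with all indices in [−1, 1]. The package implements this analysis end to
end for cohorts structured by sex × age × prenatal exposure, inferior
colliculus division and sound level, as used in studies of
autism-model (valproic-acid-exposed) rats.

Intended users: auditory electrophysiologists analysing oddball/cascade
recordings, and methodologists who need a fully seeded, testable reference
implementation of the paradigm's statistics.

## Worked example

Simulate a small cohort (8 groups × 2 subjects × 6 units), run the whole
pipeline at a Monte-Carlo depth of 200, and look at the group summary for
the non-lemniscal division at high sound level:

```r
library(mismatchkit)
library(dplyr)

cfg <- run_config(
  cohort = cohort_config(n_subjects = 2, n_units = 6, seed = 1),
  n_sim = 200, seed = 1
)
run <- run_pipeline(cfg)
run
#> <pipeline_run: 96 units, 173 points retained, seed 1>

run$group_summary |>
  filter(division == "non_lemniscal", level_class == "high") |>
  select(sex, age, exposure, n_points, dev, std, cas, imm, irs, ipe)
#> # A tibble: 8 × 10
#>   sex   age         exposure n_points   dev   std   cas   imm   irs     ipe
#>   <chr> <chr>       <chr>       <int> <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1 F     adult       control        10 0.587 0.211 0.709 0.355 0.485 -0.122
#> 2 F     adult       VPA             7 0.420 0.328 0.794 0.175 0.424 -0.375
#> 3 F     prepubertal control         7 0.655 0.114 0.729 0.429 0.625 -0.0659
#> 4 F     prepubertal VPA             5 0.598 0.265 0.798 0.288 0.515 -0.201
#> 5 M     adult       control         5 0.507 0.349 0.772 0.398 0.540 -0.339
#> 6 M     adult       VPA            10 0.659 0.199 0.713 0.439 0.406 -0.0743
#> 7 M     prepubertal control         4 0.662 0.358 0.631 0.308 0.268  0.0200
#> 8 M     prepubertal VPA            13 0.602 0.368 0.708 0.285 0.337 -0.106
```

Each row gives the median normalised DEV/STD/CAS responses of the retained
unit-frequency points of one group and the median indices they imply:
standards are strongly adapted relative to cascades (`std` well below
`cas`, hence positive `irs`), deviants sit slightly below cascades
(negative `ipe`), and the mismatch `imm` is their sum. `run$comparisons`
holds the pairwise Wilcoxon comparison matrix with Benjamini–Hochberg
correction at q = 0.1, and `run$adaptation` the power-law fits
(`y(t) = a·t^b + c`, r² ≥ 0.65 flagged high quality) with half-adaptation
times of the standard course.

The decomposition itself is a one-liner; for a single point with corrected
counts DEV = 1.41, STD = 0.62, CAS = 1.52:

```r
mismatch_indices(dev = 1.41, std = 0.62, cas = 1.52)
#>   dev_norm std_norm cas_norm  norm    imm    irs     ipe
#> 1   0.6516   0.2865   0.7024 2.164 0.3651 0.4159 -0.0508
```

`vignettes/mismatch-analysis.Rmd` documents the models, parameter choices
and numerical decisions in detail.

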