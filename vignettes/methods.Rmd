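---
title: "Methods: intrinsic timescale development along the cortical hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic timescale development along the cortical hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsdev)
library(dplyr)
```

## The measure

Intrinsic neural timescale summarizes how long a region's spontaneous
activity stays correlated with itself. Working from parcellated
resting-state BOLD series (one timepoints x regions matrix per subject,
with repetition time TR), the primary estimator is:

1. z-score each parcel's series and compute the biased (denominator-*n*)
   sample autocorrelation function (ACF); `sample_acf()` does this via FFT
   and matches `stats::acf()` to machine precision. Since the ACF is
   invariant to affine transforms of the signal, the z-scoring is cosmetic;
   it is kept because it is the convention in this literature.
2. find the first zero-crossing lag *z*: the smallest lag with ACF value
   at or below zero (`first_zero_crossing()`);
3. sum the positive ACF values at lags 0 .. *z* − 1 and multiply by TR
   (`timescale_from_acf(method = "acf_sum")`), giving a discrete area
   under the positive ACF lobe in seconds.

The lag-0 term (always 1) is included, so one TR is a hard lower bound on
the estimate; a configuration switch (`include_lag0 = FALSE`) drops it for
sensitivity work. For a stationary AR(1) process with coefficient φ the
population ACF is φ^k, every lag is positive, and the estimator's
population value is TR · Σ φ^k = TR / (1 − φ): the closed form that both
the test suite and the acceptance script verify by long-run simulation.

Two sensitivity estimators mirror common alternatives: `exp_decay` fits
A·exp(−lag·TR/τ) + B by nonlinear least squares (via `minpack.lm`) over
lags 1 .. min(*z* − 1, 50) — the window starts at lag 1 because lag 0
carries no information about the decay rate and ends before the crossing
where the exponential model stops being meaningful — and returns τ;
`zero_cross` returns *z* · TR directly.

Choices the literature leaves open, decided here:

* **max lag** defaults to min(n − 2, 200); at TR ≈ 0.8 s that is 160 s,
  far beyond any plausible BOLD zero-crossing, and bounds the FFT cost.
* **no zero-crossing** within the profile: the default `"truncate"`
  policy sums all positive values up to the max lag and flags the region;
  `"strict"` raises instead. Low-frequency-dominated parcels occasionally
  lack a crossing at short max lag, and silently dropping them would bias
  group maps.
* **degenerate regions** (constant signal) are flagged with a reason
  code, excluded from group means, GAMs and spin statistics, and counted
  in the run manifest — never silently dropped. A subject fails outright
  only when more than half of its regions are degenerate.

## The developmental model

Each region's timescale (and the cross-region mean, the "whole-brain"
analysis) is modelled over age with a Gaussian additive model:

    y ~ s(age, k = 3) + sex + mean_fd        (full model)
    y ~ sex + mean_fd                        (reduced model)

fitted by `mgcv::gam()` with REML smoothness selection — `mgcv` is the
canonical engine for penalized-spline GAMs and `fit_gam_pair()` wraps it
rather than re-deriving it. The smooth is a cubic regression spline with
basis dimension k = 3: deliberately small so developmental trajectories
can bend once but not overfit. The reduced model is ordinary least
squares on the same observations. eTIV can be appended to
`linear_covariates` for the volume-sensitivity variant.

The age effect size is a **signed partial R²**:

    |R²_partial| = (SSE_reduced − SSE_full) / SSE_reduced

with the sign of the mean first derivative of the fitted age smooth over
a dense grid (200 points by default), so a declining trajectory yields a
negative value even though the magnitude formula is nonnegative.
Significance uses a nested-model F construction from the same
ingredients: F = [(SSE_r − SSE_f)/(edf_f − df_r)] / [SSE_f/(n − edf_f)],
with the full model's total effective degrees of freedom in place of a
parametric count. Regional p-values are Benjamini–Hochberg corrected at
Q < 0.05 across regions; the single whole-brain p is reported
uncorrected. Two oracle properties pin the arithmetic down: with an
explicit unpenalized linear age column the signed partial R² equals the
classical nested-OLS quantity to 1e−10, and SSE nesting
(SSE_full ≤ SSE_reduced) holds on every fit because the spline's
unpenalized null space contains the linear trend.

Fitted trajectories are evaluated with covariates at reference values
(first factor level, numeric covariates at their sample mean — a plotting
convention, not a claim about the reference subject), differentiated by
central finite differences, and the **age of maximal change** is the grid
age with the largest absolute derivative — the decided reading of that
summary; an alternative would be the largest positive derivative, which
coincides for monotone-increasing fits.

## Spatial inference

Map-to-map comparisons use spin permutation tests that preserve spatial
autocorrelation. `spin_assignments()` draws Haar-uniform rotations
(normalized quaternions), applies each to the left hemisphere's
spherical parcel centroids and its x-mirror conjugate M·R·M (M =
diag(−1, 1, 1)) to the right hemisphere, and reassigns every parcel the
value of the nearest rotated centroid within its own hemisphere.
Duplicate sources are accepted, as is standard for centroid-level
spinning. Empirical p-values use the add-one convention
p = (1 + #extreme) / (1 + n_spins), with ties counted as extreme, so p
can never fall below 1/(1 + n_spins). Correlation and group-difference
tests are two-tailed by default; the Dice overlap test is one-tailed
greater, because overlap-above-chance is the scientific claim. Group
contrasts (association vs sensorimotor, from a median split of the axis
rank — the split quantile is configurable) use a Welch t statistic, with
null labels re-derived from the spun axis so the labels' spatial
structure is preserved under the null. Production analyses conventionally
use 10,000 spins; the test suite uses a few hundred for runtime, which
the spin p resolution (1/501) still supports at α = 0.05.

## What the synthetic generator emulates

The package ships a generator (`synth_config()`,
`make_axis_and_coords()`, `make_cohort()`, `simulate_cohort_series()`)
so the full pipeline is testable without access-controlled neuroimaging
data. It emulates exactly the statistical structure the analysis
assumes, and no more:

* **Geometry**: two mirror-image hemispheres of quasi-uniform centroids
  on the unit sphere (golden-angle lattice). The synthetic
  sensorimotor-association axis is the rank of a smooth scalar field —
  a latitude-like gradient plus low- and mid-frequency random components
  evaluated on mirror-symmetric coordinates — so it is spatially
  autocorrelated at neighbour scale, has the multiscale structure of a
  real cortical gradient (a field built only from hemisphere-scale
  components would make spun copies of itself implausibly self-similar),
  and is bilaterally symmetric, the map class hemisphere-mirrored
  spinning is designed for: spinning an asymmetric map produces nulls
  outside its own distribution and measurably miscalibrated tests.
* **Cohort**: ages uniform over 8–22 years; two-level sex; mean
  framewise displacement declining linearly with age (0.12 mm at age 8,
  −0.003 mm/year, SD 0.04 mm, truncated positive), matching the
  low-motion regime that survives a 0.2 mm QC cut; optional lognormal
  eTIV.
* **Signal**: each region of each subject is a stationary unit-variance
  AR(1) whose coefficient is chosen so the estimator's population value
  hits a target timescale τ = tau_base + tau_axis_gain·r̃ +
  tau_age_gain·r̃·ã + g_s + e_si (r̃: normalized axis rank; ã: normalized
  age; g_s: per-subject global offset; e_si: region-level noise), floored
  at one TR. Development is thus concentrated in high-axis regions, the
  pattern the pipeline is meant to detect. An optional
  `motion_tau_coupling` scales τ by (1 + coupling·FD) to test that the FD
  covariate absorbs a motion confound.

Defaults (150 subjects, 100 regions, 400 timepoints, TR 0.8 s,
tau_base 1.2 s, tau_axis_gain 2.0 s, tau_age_gain 1.2 s, subject_sd
0.5 s, subject_global_sd 0.45 s) were fixed once, against two
constraints: whole-brain age effects of the order seen in developmental
fMRI (partial R² of several percent, here ≈ 0.05–0.2 across seeds), and
reliable recovery of all three headline patterns at this desk-scale
cohort size, which is several-fold smaller than real developmental
samples and therefore needs somewhat larger per-region effects to reach
comparable power. The per-subject global offset `subject_global_sd`
deserves a note: purely region-level noise averages away in the
cross-region mean, which would make the whole-brain age effect
unrealistically clean; a shared between-individual component in global
dynamics keeps the whole-brain partial R² at a realistic size.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no haemodynamic response or band-pass
filtering (real BOLD ACFs are not exponential), no cross-regional
correlation (real parcels co-fluctuate), no scanner/site effects, no
non-uniform age sampling, no vertex-level structure within parcels.
Results on the generator demonstrate that the machinery is correct and
calibrated, not that any particular real cohort will show these effects.

## Numerical choices and degenerate inputs

* Biased (denominator-*n*) sample ACF: guarantees a valid
  autocorrelation sequence; computed by FFT for all regions at once.
* Per-subject sub-seeds are derived arithmetically from the master seed,
  so any subject can be regenerated independently and all generator
  functions restore the caller's RNG state.
* The AR(1) innovation variance is 1 − φ², giving unit marginal variance
  and hence comparable tSNR across regions.
* Exponential fits are initialized from a log-linear regression on the
  positive part of the profile and bounded (A, τ > 0); non-convergence
  raises a classed estimation failure carrying the optimizer message.
* Ties in the first zero-crossing rule: a value exactly 0 counts as
  crossed. Ties in spin p-values count as extreme. The median region in
  an odd axis split goes to the sensorimotor group.
* QC boundaries: strict `<` for mean FD (a "below 0.2 mm" criterion),
  inclusive for age bounds.
* Problem sizes in the shipped tests: cohorts of 150 subjects x 100
  regions x 400 timepoints for recovery/specificity (20 seeds each), 500
  spins for calibration, 100,000-step series for closed-form checks —
  chosen as the smallest sizes at which the statistical properties under
  test are stable.

## Known limitations

* Parcel-level (centroid) spinning only; no vertex-level nulls or
  variogram-matched surrogates.
* TSV is the only time-series ingestion format; CIFTI ptseries input is
  not supported.
* The F-test for the smooth term treats the REML-selected penalty as
  fixed, the standard approximation; its calibration is verified
  empirically in the suite rather than exact.
* Cross-sectional modelling only — no longitudinal or site-harmonization
  machinery.
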