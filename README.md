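# itsdev — development of fMRI intrinsic timescale along the cortical hierarchy

`itsdev` is an R package for researchers studying how the temporal
dynamics of spontaneous brain activity mature during childhood and
adolescence. It implements a complete, tested analysis pipeline for
parcellated resting-state BOLD data:

1. **Intrinsic timescale estimation.** For each cortical parcel the
   sample autocorrelation function (ACF) of the z-scored series is
   computed and the timescale is the TR-scaled sum of positive ACF
   values up to the first zero-crossing,

   τ = TR · Σₖ r(k) for k = 0 .. z−1, z = min{k ≥ 1 : r(k) ≤ 0},

   a discrete area under the positive ACF lobe, in seconds. Two
   sensitivity estimators are included (exponential-decay constant of a
   fit r(k) ≈ A·e^(−k·TR/τ) + B, and the zero-crossing time itself), plus
   temporal SNR.
2. **Developmental modelling.** Whole-brain and per-region generalized
   additive models `y ~ s(age, k = 3) + sex + mean_FD` (mgcv, REML), with
   the age effect summarized as a **signed partial R²**:
   (SSE_reduced − SSE_full)/SSE_reduced, signed by the mean derivative of
   the fitted age smooth; nested-model ANOVA p-values; BH-FDR across
   regions (Q < 0.05); fitted trajectories, derivatives and ages of
   maximal change.
3. **Spatial inference.** Spin permutation tests that preserve spatial
   autocorrelation: Haar-random rotations of spherical parcel centroids,
   mirrored across hemispheres, with nearest-centroid reassignment.
   Used for map–map Spearman correlations against a
   sensorimotor–association (S–A) axis, Welch-t contrasts of
   sensorimotor vs association parcels, and Dice overlap of significance
   masks across cohorts, all with empirical p = (1 + #extreme)/(1 + n).
4. **Synthetic cohorts.** A generator that emulates the statistical
   structure the analysis assumes — region-specific AR(1) dynamics whose
   timescale rises along a synthetic, bilaterally symmetric,
   spatially autocorrelated S–A axis and increases with age
   preferentially in high-axis regions, with realistic sex, motion, and
   (optional) eTIV covariates — so the entire pipeline is testable
   without access-controlled datasets.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` visualizations.

## Worked example

```r
library(itsdev)
library(dplyr)

cfg    <- synth_config(n_subjects = 60, n_regions = 60,
                       n_timepoints = 300, seed = 42)
geo    <- make_axis_and_coords(cfg$n_regions, seed = 42)
cohort <- make_cohort(cfg)
series <- simulate_cohort_series(cohort, geo$axis, cfg)

maps <- cohort_timescale_maps(series)   # per subject x region timescales
head(maps, 3)
#> # A tibble: 3 × 5
#>   subject_id region_id timescale flag  method
#>   <chr>      <chr>         <dbl> <chr> <chr>
#> 1 sub-0001   R001           2.56 <NA>  acf_sum
#> 2 sub-0001   R002           1.40 <NA>  acf_sum
#> 3 sub-0001   R003           2.02 <NA>  acf_sum

gams <- run_regional_gams(maps, cohort)
gams
#> <regional_gams> 60 regions; whole-brain signed partial R^2 = 0.1202 (p = 0.0239)
#>   FDR-significant regions: 0 (0.0%)

ens <- spin_assignments(geo$coords, n_spins = 1000, seed = 99)
hierarchy_summary(group_mean_map(maps), geo$axis, ens)
#> <hierarchy_summary> 60 regions; axis r_s = 0.98 (p_spin = 0.000999); assoc-vs-sens t = 12.9 (p_spin = 0.000999)
hierarchy_summary(select(gams$regional, region_id, partial_r2_signed),
                  geo$axis, ens)
#> <hierarchy_summary> 60 regions; axis r_s = 0.418 (p_spin = 0.004); assoc-vs-sens t = 2.83 (p_spin = 0.029)
```

Reading the output: the group-mean timescale map is almost perfectly
rank-correlated with the synthetic S–A axis (r_s = 0.98) and association
parcels have longer timescales than sensorimotor ones (t = 12.9), both
far beyond what spatially matched rotations produce (p_spin ≈ 0.001 at
1,000 spins). The whole-brain timescale increases with age (signed
partial R² = 0.12, p = 0.024), and the map of regional age effects
itself follows the axis (r_s = 0.42, p_spin = 0.004) — development
concentrated in association cortex. At this deliberately small cohort
(60 subjects) no single region survives FDR, while the map-level tests
are already decisive; the full-scale defaults (150 subjects, 100
regions, 400 timepoints) yield sizable FDR-significant fractions.

Real data enter through `load_timeseries()` (TSV, one column per
region, one row per timepoint), `load_cohort()`, `load_axis()` and
`load_coords()`, with `filter_cohort()` applying the conventional QC
(mean FD < 0.2 mm, ages 8–22). `run_pipeline()` chains all stages and
writes TSV/JSON outputs plus a run manifest; `exec/itsdev` exposes
`simulate`, `estimate`, `develop`, `nulls`, `compare` and `run`
subcommands for shell use.

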