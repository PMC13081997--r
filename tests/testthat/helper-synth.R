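# Shared fixtures, built in code at test time.

# A small but GAM-capable cohort configuration for fast tests.
small_config <- function(seed = 1L, ...) {
  synth_config(n_subjects = 40, n_regions = 20, n_timepoints = 120,
               seed = seed, ...)
}

# A deterministic cohort with known structure for GAM tests.
gam_test_cohort <- function(n = 200, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = runif(n, 8, 22),
    sex = factor(sample(c("F", "M"), n, replace = TRUE)),
    mean_fd = runif(n, 0.03, 0.19)
  )
}

# Stationary AR(1) sample of length n with coefficient phi.
ar1_sample <- function(n, phi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- rnorm(1)
  c(x1, stats::filter(rnorm(n - 1, sd = sqrt(1 - phi^2)), phi,
                      method = "recursive", init = x1))
}

# Pipeline run on one synthetic cohort; returns the pieces the
# multi-seed acceptance checks need.
run_synthetic_analysis <- function(seed, n_spins = 500, config = NULL,
                                   geometry_seed = NULL) {
  cfg <- config %||% synth_config(seed = seed)
  geo <- make_axis_and_coords(cfg$n_regions, geometry_seed %||% cfg$seed)
  cohort <- make_cohort(cfg)
  maps <- cohort_timescale_maps(simulate_cohort_series(cohort, geo$axis, cfg))
  gams <- run_regional_gams(maps, cohort)
  # ensemble seed decoupled from the generator seed stream
  ens <- spin_assignments(geo$coords, n_spins, seed = seed + 50000)
  mean_h <- hierarchy_summary(group_mean_map(maps), geo$axis, ens)
  effect_h <- hierarchy_summary(
    dplyr::select(gams$regional, "region_id", "partial_r2_signed"),
    geo$axis, ens)
  list(cfg = cfg, geo = geo, cohort = cohort, maps = maps, gams = gams,
       ensemble = ens, mean_h = mean_h, effect_h = effect_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
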