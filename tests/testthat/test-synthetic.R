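test_that("axis and coordinates satisfy their geometric invariants", {
  geo <- make_axis_and_coords(4, seed = 3)
  expect_equal(sort(geo$axis$rank), 1:4)
  expect_equal(sum(geo$coords$hemisphere == "left"), 2)
  expect_equal(sum(geo$coords$hemisphere == "right"), 2)

  geo100 <- make_axis_and_coords(100, seed = 5)
  norms <- with(geo100$coords, sqrt(x^2 + y^2 + z^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_true(all(geo100$coords$x[geo100$coords$hemisphere == "left"] < 0))
  expect_true(all(geo100$coords$x[geo100$coords$hemisphere == "right"] > 0))
  expect_equal(sort(geo100$axis$rank), 1:100)

  expect_error(make_axis_and_coords(5), class = "invalid_argument")
  expect_error(make_axis_and_coords(2), class = "invalid_argument")
})

test_that("generator outputs are deterministic given the seed", {
  expect_identical(make_axis_and_coords(20, seed = 9),
                   make_axis_and_coords(20, seed = 9))
  cfg <- small_config(seed = 11)
  expect_identical(make_cohort(cfg), make_cohort(cfg))
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  co <- make_cohort(cfg)
  s1 <- simulate_cohort_series(co, geo$axis, cfg)
  s2 <- simulate_cohort_series(co, geo$axis, cfg)
  expect_identical(s1[[5]]$data, s2[[5]]$data)
})

test_that("axis ranks are spatially autocorrelated on the lattice", {
  # nearest-neighbour rank correlation computed directly on the geometry
  for (seed in 1:3) {
    geo <- make_axis_and_coords(100, seed = seed)
    xyz <- as.matrix(geo$coords[c("x", "y", "z")])
    sim <- xyz %*% t(xyz)
    diag(sim) <- -2
    nn <- max.col(sim)
    expect_gt(spearman_r(geo$axis$rank, geo$axis$rank[nn]), 0)
  }
})

test_that("cohort respects its configured bounds and motion model", {
  cfg <- synth_config(n_subjects = 200, n_regions = 10, n_timepoints = 50,
                      age_range = c(8, 22), seed = 2)
  co <- make_cohort(cfg)
  expect_true(all(co$age >= 8 & co$age <= 22))
  expect_true(all(co$mean_fd > 0))
  expect_s3_class(co$sex, "factor")
  expect_length(levels(co$sex), 2)

  # zero noise + negative slope makes FD strictly decreasing in age
  cfg0 <- synth_config(n_subjects = 50, n_regions = 10, n_timepoints = 50,
                       motion_sd = 0, motion_age_slope = -0.003, seed = 4)
  co0 <- make_cohort(cfg0)
  ord <- order(co0$age)
  expect_true(all(diff(co0$mean_fd[ord]) < 0))

  expect_error(synth_config(n_subjects = 5), class = "invalid_argument")
  expect_error(synth_config(n_regions = 7), class = "invalid_argument")
  expect_error(synth_config(tau_base = 0.5, tr = 0.8),
               class = "invalid_argument")
})

test_that("phi_for_timescale inverts the AR(1) closed form", {
  expect_equal(phi_for_timescale(1.6, 0.8), 0.5)
  expect_equal(phi_for_timescale(0.8, 0.8), 0)  # white noise
  expect_equal(phi_for_timescale(8, 0.8), 0.9)
  expect_error(phi_for_timescale(0.5, 0.8), class = "invalid_argument")
})

test_that("long AR(1) simulation recovers the target timescale", {
  # independent oracle: simulate at phi = 0.9 and apply the estimator
  set.seed(42)
  x <- ar1_sample(1e5, phi_for_timescale(8, 0.8))
  est <- timescale_from_acf(sample_acf(x, max_lag = 400), tr = 0.8)
  expect_lt(abs(est$timescale - 8) / 8, 0.1)
})

test_that("generated series are stationary with unit variance", {
  cfg <- small_config(seed = 6)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  series <- simulate_cohort_series(make_cohort(cfg), geo$axis, cfg)
  v <- unlist(lapply(series[1:5], function(ts) apply(ts$data, 2, var)))
  # sample variance of AR(1) has inflated variance relative to iid; allow a
  # generous multiple of sqrt(2/N)
  expect_true(all(abs(v - 1) < 8 * sqrt(2 / cfg$n_timepoints)))
  expect_true(all(is.finite(series[[1]]$data)))
})

test_that("flat generator settings give flat timescale profiles", {
  cfg <- synth_config(n_subjects = 12, n_regions = 10, n_timepoints = 60,
                      tau_axis_gain = 0, tau_age_gain = 0, subject_sd = 0,
                      subject_global_sd = 0, seed = 8)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  series <- simulate_cohort_series(make_cohort(cfg), geo$axis, cfg)
  tau <- attr(series, "tau_target")
  expect_true(all(abs(tau - cfg$tau_base) < 1e-12))
})

test_that("group-mean map tracks the axis when age effects are off", {
  cfg <- synth_config(n_subjects = 12, n_regions = 100, n_timepoints = 4000,
                      tau_age_gain = 0, subject_sd = 0, subject_global_sd = 0,
                      seed = 10)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  series <- simulate_cohort_series(make_cohort(cfg), geo$axis, cfg)
  gm <- group_mean_map(cohort_timescale_maps(series))
  joined <- dplyr::inner_join(gm, geo$axis, by = "region_id")
  expect_gt(spearman_r(joined$timescale, joined$rank), 0.9)
})

test_that("development shows up in the top axis quartile, not the bottom", {
  cfg <- synth_config(seed = 12)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  cohort <- make_cohort(cfg)
  maps <- cohort_timescale_maps(simulate_cohort_series(cohort, geo$axis, cfg))
  joined <- dplyr::inner_join(maps, geo$axis, by = "region_id") |>
    dplyr::inner_join(cohort, by = "subject_id")
  age_cut <- quantile(cohort$age, c(1 / 3, 2 / 3))
  strat <- joined |>
    dplyr::filter(.data$age <= age_cut[1] | .data$age >= age_cut[2]) |>
    dplyr::mutate(
      old = .data$age >= age_cut[2],
      top = .data$rank > quantile(geo$axis$rank, 0.75),
      bottom = .data$rank <= quantile(geo$axis$rank, 0.25)
    )
  gap <- function(d) mean(d$timescale[d$old]) - mean(d$timescale[!d$old])
  top_gap <- gap(dplyr::filter(strat, .data$top))
  bottom_gap <- gap(dplyr::filter(strat, .data$bottom))
  expect_gt(top_gap, 0)
  expect_lt(bottom_gap, top_gap)
})
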