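test_that("sample ACF matches the textbook estimator and stats::acf", {
  set.seed(1)
  x <- rnorm(60)
  prof <- sample_acf(x, max_lag = 15)
  expect_equal(prof$acf[1], 1)
  expect_true(all(abs(prof$acf) <= 1 + 1e-9))
  # brute-force biased sample ACF
  xc <- x - mean(x)
  brute <- vapply(0:15, function(k) {
    sum(xc[1:(60 - k)] * xc[(1 + k):60]) / sum(xc^2)
  }, numeric(1))
  expect_equal(prof$acf, brute, tolerance = 1e-12)
  # independent implementation in stats
  ref <- drop(acf(x, lag.max = 15, plot = FALSE, demean = TRUE)$acf)
  expect_equal(prof$acf, ref, tolerance = 1e-12)
})

test_that("ACF is affine-invariant and alternating series cross at lag 1", {
  set.seed(2)
  x <- cumsum(rnorm(100))
  expect_equal(sample_acf(x, 20)$acf, sample_acf(3.7 * x - 11, 20)$acf,
               tolerance = 1e-12)
  alt <- rep(c(1, -1), 50)
  prof <- sample_acf(alt, 10)
  expect_lt(prof$acf[2], 0)
  expect_equal(first_zero_crossing(prof), 1L)
  expect_error(sample_acf(rep(1, 30)), class = "degenerate_input")
})

test_that("AR(1) sample ACF approaches the population value phi^k", {
  x <- ar1_sample(1e5, 0.8, seed = 3)
  r1 <- sample_acf(x, 5)$acf[2]
  expect_gt(r1, 0.79)
  expect_lt(r1, 0.81)
})

test_that("first zero-crossing follows its definition", {
  mk <- function(v) tibble::tibble(lag = seq_along(v) - 1, acf = v)
  expect_equal(first_zero_crossing(mk(c(1, 0.4, -0.2))), 2L)
  expect_equal(first_zero_crossing(mk(c(1, -0.001))), 1L)
  expect_true(is.na(first_zero_crossing(mk(c(1, 0.5, 0.5)))))
})

test_that("timescale arithmetic on worked ACF profiles is exact", {
  prof <- tibble::tibble(lag = 0:3, acf = c(1, 0.5, 0.2, -0.1))
  expect_equal(timescale_from_acf(prof, 0.8, "acf_sum")$timescale,
               0.8 * (1 + 0.5 + 0.2))
  expect_equal(timescale_from_acf(prof, 0.8, "zero_cross")$timescale, 3 * 0.8)
  prof2 <- tibble::tibble(lag = 0:2, acf = c(1, 0.4, -0.2))
  expect_equal(timescale_from_acf(prof2, 0.8, "zero_cross")$timescale, 1.6)
  # lag-0 exclusion switch
  expect_equal(
    timescale_from_acf(prof, 0.8, "acf_sum", include_lag0 = FALSE)$timescale,
    0.8 * (0.5 + 0.2))
})

test_that("exponential-decay fit recovers an exact exponential", {
  lags <- 0:40
  prof <- tibble::tibble(lag = lags, acf = exp(-lags * 0.8 / 4.0))
  est <- timescale_from_acf(prof, 0.8, "exp_decay")
  expect_equal(est$timescale, 4.0, tolerance = 1e-6)
})

test_that("no-crossing policy truncates with a flag or raises when strict", {
  prof <- tibble::tibble(lag = 0:3, acf = c(1, 0.6, 0.4, 0.3))
  res <- timescale_from_acf(prof, 0.8, "acf_sum")
  expect_equal(res$flag, "no_zero_crossing")
  expect_equal(res$timescale, 0.8 * (1 + 0.6 + 0.4 + 0.3))
  expect_error(
    timescale_from_acf(prof, 0.8, "acf_sum", on_no_crossing = "strict"),
    class = "no_zero_crossing")
})

test_that("subject maps flag degenerate regions without dropping others", {
  set.seed(4)
  dat <- matrix(rnorm(100 * 5), 100, 5)
  dat[, 3] <- 7  # constant region
  ts <- parcellated_ts(dat, tr = 0.8, subject_id = "s1")
  map <- subject_timescale_map(ts)
  expect_equal(map$flag[3], "constant")
  expect_true(is.na(map$timescale[3]))
  expect_true(all(is.na(map$flag[-3])))
  # acf_sum lower bound: lag-0 term alone contributes one TR
  expect_true(all(map$timescale[-3] >= 0.8))
})

test_that("vectorized per-subject path agrees with the per-region estimator", {
  set.seed(5)
  dat <- vapply(runif(6, 0, 0.9), function(p) ar1_sample(150, p),
                numeric(150))
  ts <- parcellated_ts(dat, tr = 0.8)
  for (method in c("acf_sum", "zero_cross")) {
    map <- subject_timescale_map(ts, method = method)
    ref <- vapply(seq_len(6), function(i) {
      timescale_from_acf(sample_acf(dat[, i]), 0.8, method)$timescale
    }, numeric(1))
    expect_equal(map$timescale, ref, tolerance = 1e-12)
  }
})

test_that("subject fails when most regions are degenerate", {
  dat <- matrix(1, 50, 4)
  dat[, 1] <- rnorm(50)
  expect_error(subject_timescale_map(parcellated_ts(dat, tr = 0.8)),
               class = "subject_failure")
})

test_that("estimates track targets within 10% on a long-series subject", {
  cfg <- synth_config(n_subjects = 10, n_regions = 10, n_timepoints = 1e5,
                      subject_sd = 0, subject_global_sd = 0, seed = 13)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  cohort <- make_cohort(cfg)
  series <- simulate_cohort_series(cohort, geo$axis, cfg)
  tau <- attr(series, "tau_target")
  map <- subject_timescale_map(series[[1]], max_lag = 1000)
  expect_true(all(abs(map$timescale - tau[1, map$region_id]) /
                    tau[1, map$region_id] < 0.1))
})

test_that("mean acf_sum timescale is monotone in AR(1) persistence", {
  set.seed(6)
  mean_est <- vapply(c(0.2, 0.5, 0.8), function(phi) {
    mean(vapply(1:60, function(i) {
      x <- ar1_sample(2000, phi)
      timescale_from_acf(sample_acf(x), tr = 0.8)$timescale
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_est) > 0))
})

test_that("group mean averages unflagged values and counts subjects", {
  m1 <- tibble::tibble(subject_id = "a", region_id = c("r1", "r2"),
                       timescale = c(1, 2), flag = NA_character_,
                       method = "acf_sum")
  m2 <- tibble::tibble(subject_id = "b", region_id = c("r1", "r2"),
                       timescale = c(3, 9), flag = c(NA, "constant"),
                       method = "acf_sum")
  gm <- group_mean_map(dplyr::bind_rows(m1, m2))
  expect_equal(gm$timescale[gm$region_id == "r1"], 2)
  expect_equal(gm$timescale[gm$region_id == "r2"], 2)  # flagged value excluded
  expect_equal(gm$n_subjects[gm$region_id == "r2"], 1)
  # two identical maps: mean equals either
  gm2 <- group_mean_map(dplyr::bind_rows(
    m1, dplyr::mutate(m1, subject_id = "c")))
  expect_equal(gm2$timescale, m1$timescale)
  expect_error(group_mean_map(m1[0, ]), class = "invalid_argument")
})

test_that("tSNR is mean over sd, scale-invariant, and flags zero variance", {
  set.seed(7)
  base <- rnorm(100)
  dat <- cbind(100 + 10 * scale(base)[, 1], rnorm(100), 5)
  ts <- parcellated_ts(dat, tr = 0.8)
  snr <- tsnr_map(ts)
  expect_equal(snr$tsnr[1], 10, tolerance = 1e-9)
  expect_lt(abs(snr$tsnr[2]), 0.5)  # near zero for zero-mean noise
  expect_equal(snr$flag[3], "zero_variance")
  ts2 <- parcellated_ts(2 * dat, tr = 0.8)
  expect_equal(tsnr_map(ts2)$tsnr[1:2], snr$tsnr[1:2], tolerance = 1e-12)
})

test_that("exp_decay and acf_sum maps agree in rank on a synthetic subject", {
  cfg <- synth_config(n_subjects = 10, n_regions = 30, n_timepoints = 4000,
                      subject_sd = 0.1, subject_global_sd = 0, seed = 14)
  geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
  series <- simulate_cohort_series(make_cohort(cfg), geo$axis, cfg)
  a <- subject_timescale_map(series[[1]], method = "acf_sum")
  b <- subject_timescale_map(series[[1]], method = "exp_decay")
  ok <- is.na(a$flag) & is.na(b$flag)
  expect_gt(spearman_r(a$timescale[ok], b$timescale[ok]), 0.8)
})
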