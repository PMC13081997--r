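test_that("gam_spec validates its arguments", {
  expect_error(gam_spec(basis_dim = 2), class = "invalid_argument")
  expect_error(gam_spec(linear_covariates = c("age", "sex")),
               class = "invalid_argument")
  expect_error(gam_spec(derivative_grid_size = 5), class = "invalid_argument")
  expect_equal(gam_spec()$basis_dim, 3L)
})

test_that("a noiseless linear age effect is reproduced exactly", {
  co <- gam_test_cohort(200, seed = 10)
  y <- 3 * co$age + 0.5 * as.numeric(co$sex == "M") + rnorm(200, sd = 1e-6)
  pair <- fit_gam_pair(co, y)
  expect_lt(pair$sse_full / pair$sse_reduced, 1e-6)
  traj <- smooth_trajectory(pair)
  expect_true(all(abs(traj$derivative - 3) < 0.05))
  expect_gt(signed_partial_r2(pair), 0.999)
})

test_that("pure-noise responses give small SSE gaps and near-minimal edf", {
  set.seed(11)
  co <- gam_test_cohort(500, seed = 11)
  gaps <- replicate(60, {
    pair <- fit_gam_pair(co, rnorm(500))
    (pair$sse_reduced - pair$sse_full) / pair$sse_reduced
  })
  expect_lt(mean(gaps), 0.02)
})

test_that("SSE nesting holds and edf stays within the basis budget", {
  set.seed(12)
  co <- gam_test_cohort(150, seed = 12)
  for (i in 1:20) {
    y <- rnorm(150) + runif(1, -2, 2) * co$age
    pair <- fit_gam_pair(co, y)
    expect_lte(pair$sse_full, pair$sse_reduced + 1e-9 * pair$sse_reduced)
    smooth_edf <- pair$edf_full - pair$df_reduced
    expect_gte(smooth_edf, 1 - 1e-6)
    expect_lte(smooth_edf, pair$spec$basis_dim + 1e-6)
  }
})

test_that("signed partial R2 equals the nested-OLS quantity with a linear age term", {
  set.seed(13)
  co <- gam_test_cohort(120, seed = 13)
  for (slope in c(-0.5, 0, 0.8)) {
    y <- slope * co$age + 2 * co$mean_fd + rnorm(120)
    pair <- fit_gam_pair(co, y, age_term = "linear")
    # independent oracle: classical nested OLS partial R2 with directional sign
    full <- lm(y ~ age + sex + mean_fd, data = co)
    red <- lm(y ~ sex + mean_fd, data = co)
    oracle <- (sum(residuals(red)^2) - sum(residuals(full)^2)) /
      sum(residuals(red)^2)
    oracle <- oracle * sign(coef(full)["age"])
    expect_equal(signed_partial_r2(pair), unname(oracle), tolerance = 1e-10)
  }
})

test_that("the large-penalty limit collapses to OLS with a linear age column", {
  set.seed(14)
  co <- gam_test_cohort(150, seed = 14)
  y <- 0.3 * co$age + rnorm(150)
  pen <- fit_gam_pair(co, y, sp = 1e9)
  ols <- fit_gam_pair(co, y, age_term = "linear")
  expect_equal(pen$sse_full, ols$sse_full, tolerance = 1e-6)
  expect_equal(unname(fitted(pen$full)), unname(fitted(ols$full)),
               tolerance = 1e-5)
})

test_that("the sign of partial R2 follows the mean derivative", {
  set.seed(15)
  co <- gam_test_cohort(200, seed = 15)
  up <- fit_gam_pair(co, 0.5 * co$age + rnorm(200, sd = 0.5))
  down <- fit_gam_pair(co, -0.5 * co$age + rnorm(200, sd = 0.5))
  expect_gt(signed_partial_r2(up), 0)
  expect_lt(signed_partial_r2(down), 0)
  expect_equal(abs(signed_partial_r2(down)),
               (down$sse_reduced - down$sse_full) / down$sse_reduced)
})

test_that("ANOVA p is tiny for strong effects and 1 for identical fits", {
  co <- gam_test_cohort(500, seed = 16)
  set.seed(16)
  y <- 5 * scale(co$age)[, 1] + rnorm(500)
  pair <- fit_gam_pair(co, y)
  expect_lt(gam_anova_p(pair), 1e-10)
  # degenerate: force the full model to match the reduced model
  fake <- pair
  fake$sse_full <- fake$sse_reduced
  expect_equal(gam_anova_p(fake), 1)
})

test_that("residuals are orthogonal to the linear covariate columns", {
  set.seed(17)
  co <- gam_test_cohort(100, seed = 17)
  pair <- fit_gam_pair(co, rnorm(100) + 0.1 * co$age)
  X <- model.matrix(~ sex + mean_fd, data = co)
  expect_true(all(abs(crossprod(X, residuals(pair$full))) < 1e-6))
})

test_that("BH-FDR matches the brute-force step-up procedure", {
  # independent oracle: literal step-up definition
  brute_bh <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    qv <- numeric(m)
    running <- 1
    for (i in m:1) {
      running <- min(running, m * p[ord[i]] / i)
      qv[ord[i]] <- running
    }
    list(q = qv, mask = qv <= q)
  }
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$significant, rep(TRUE, 4))
  expect_equal(fdr_bh(c(0.04, 0.5, 0.9))$significant, rep(FALSE, 3))
  expect_equal(fdr_bh(0)$q, 0)
  set.seed(18)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    res <- fdr_bh(p, 0.05)
    ref <- brute_bh(p, 0.05)
    expect_equal(res$q, ref$q, tolerance = 1e-12)
    expect_identical(res$significant, ref$mask)
  }
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
})

test_that("trajectory grid, derivative, and age of maximal change behave", {
  co <- gam_test_cohort(300, seed = 19)
  set.seed(19)
  # saturating growth: steep before the midpoint, flat after
  y <- pmin(co$age, 13) + rnorm(300, sd = 0.01)
  pair <- fit_gam_pair(co, y)
  traj <- smooth_trajectory(pair, grid_size = 100)
  expect_equal(nrow(traj), 100)
  expect_equal(range(traj$age), range(co$age))
  expect_lt(attr(traj, "age_max_change"), mean(range(co$age)))
  expect_error(smooth_trajectory(pair, grid_size = 5),
               class = "invalid_argument")
})

test_that("regional GAMs populate all fields and validate subjects", {
  res <- run_synthetic_analysis(21, n_spins = 10,
                                config = small_config(seed = 21))
  reg <- res$gams$regional
  expect_true(all(c("region_id", "partial_r2_signed", "p_anova", "q_fdr",
                    "significant", "edf", "age_max_change", "n_subjects")
                  %in% names(reg)))
  expect_true(all(abs(reg$partial_r2_signed) <= 1))
  expect_true(all(reg$q_fdr >= reg$p_anova - 1e-12))
  age_rng <- range(res$cohort$age)
  expect_true(all(reg$age_max_change >= age_rng[1] &
                    reg$age_max_change <= age_rng[2]))
  expect_error(run_regional_gams(res$maps, res$cohort[-1, ]),
               class = "invalid_argument")
})

test_that("whole-brain development is detected at generator settings", {
  res <- run_synthetic_analysis(22, n_spins = 10)
  wb <- res$gams$whole_brain
  expect_gt(wb$partial_r2_signed, 0)
  expect_lt(wb$p_anova, 0.05)
  # regional effects track the generator's true effect-size profile
  truth <- dplyr::inner_join(res$gams$regional, res$geo$axis,
                             by = "region_id")
  expect_gt(spearman_r(truth$partial_r2_signed, truth$rank), 0.5)
})

test_that("motion covariate absorbs a motion-timescale confound", {
  # with FD correlated with age and coupled to timescale, including mean_fd
  # shrinks the bias of the whole-brain effect relative to omitting it
  biases <- vapply(1:8, function(i) {
    cfg <- synth_config(n_subjects = 120, n_regions = 10, n_timepoints = 400,
                        tau_age_gain = 0, motion_tau_coupling = 8,
                        motion_sd = 0.01, subject_sd = 0.2,
                        subject_global_sd = 0, seed = 300 + i)
    geo <- make_axis_and_coords(cfg$n_regions, cfg$seed)
    cohort <- make_cohort(cfg)
    maps <- cohort_timescale_maps(
      simulate_cohort_series(cohort, geo$axis, cfg))
    wide <- tidyr::pivot_wider(maps[c("subject_id", "region_id", "timescale")],
                               names_from = "region_id",
                               values_from = "timescale")
    y <- rowMeans(as.matrix(wide[-1]))
    with_fd <- fit_gam_pair(cohort, y)
    no_fd <- fit_gam_pair(cohort, y,
                          spec = gam_spec(linear_covariates = "sex"))
    c(abs(signed_partial_r2(with_fd)), abs(signed_partial_r2(no_fd)))
  }, numeric(2))
  # true age effect is zero, so any detected effect is confound leakage
  expect_lt(mean(biases[1, ]), mean(biases[2, ]))
})
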