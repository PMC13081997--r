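#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic resting-state cohort: cohort size and
#' acquisition geometry, the target-timescale model (a base timescale that
#' rises along a synthetic sensorimotor-association axis and, preferentially
#' in high-axis regions, with age), between-subject noise, and a simple
#' head-motion model. Defaults produce a desk-scale cohort whose age effects
#' are of the same order as those seen in developmental fMRI samples
#' (whole-brain partial R-squared of a few percent).
#'
#' @param n_subjects Number of subjects (>= 10; downstream GAMs need degrees
#'   of freedom).
#' @param n_regions Number of cortical regions; must be even (two mirrored
#'   hemispheres) and >= 4.
#' @param n_timepoints Number of volumes per subject (>= 20).
#' @param tr Repetition time in seconds.
#' @param age_range Length-2 numeric, youngest and oldest age in years.
#' @param tau_base Timescale in seconds at axis rank 1 for the youngest age.
#' @param tau_axis_gain Seconds of timescale added per unit of normalized
#'   axis rank.
#' @param tau_age_gain Seconds added per unit normalized rank per unit
#'   normalized age: development concentrated in high-axis regions.
#' @param subject_sd SD (seconds) of independent per-subject, per-region
#'   timescale noise.
#' @param subject_global_sd SD (seconds) of a per-subject timescale offset
#'   shared across all regions (between-individual differences in global
#'   dynamics; this is what keeps whole-brain age effects at a realistic
#'   size rather than averaging the noise away over regions).
#' @param motion_intercept,motion_age_slope,motion_sd Mean framewise
#'   displacement model (mm): intercept at the youngest age, linear change
#'   per year, and residual SD. FD is truncated to be positive.
#' @param motion_tau_coupling Optional confound: per-subject timescales are
#'   scaled by `1 + motion_tau_coupling * mean_fd`. Default 0 (off).
#' @param include_etiv Add a lognormal estimated total intracranial volume
#'   column (mm^3) to the cohort table.
#' @param seed Integer seed; every generator draw derives from it.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 20, n_regions = 10, n_timepoints = 100)
#' cfg$tr
synth_config <- function(n_subjects = 150,
                         n_regions = 100,
                         n_timepoints = 400,
                         tr = 0.8,
                         age_range = c(8, 22),
                         tau_base = 1.2,
                         tau_axis_gain = 2.0,
                         tau_age_gain = 1.2,
                         subject_sd = 0.5,
                         subject_global_sd = 0.45,
                         motion_intercept = 0.12,
                         motion_age_slope = -0.003,
                         motion_sd = 0.04,
                         motion_tau_coupling = 0,
                         include_etiv = FALSE,
                         seed = 1L) {
  assert_scalar_number(n_subjects, "n_subjects", 10)
  assert_scalar_number(n_regions, "n_regions", 4)
  if (n_regions %% 2 != 0) {
    its_abort("`n_regions` must be even (two mirrored hemispheres)",
              "invalid_argument")
  }
  assert_scalar_number(n_timepoints, "n_timepoints", 20)
  assert_scalar_number(tr, "tr", 0, strict = TRUE)
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    its_abort("`age_range` must be (min, max) with max > min", "invalid_argument")
  }
  assert_scalar_number(tau_base, "tau_base", tr)
  assert_scalar_number(subject_sd, "subject_sd", 0)
  assert_scalar_number(subject_global_sd, "subject_global_sd", 0)
  assert_scalar_number(motion_sd, "motion_sd", 0)
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
      n_timepoints = as.integer(n_timepoints), tr = tr,
      age_range = as.numeric(age_range), tau_base = tau_base,
      tau_axis_gain = tau_axis_gain, tau_age_gain = tau_age_gain,
      subject_sd = subject_sd, subject_global_sd = subject_global_sd,
      motion_intercept = motion_intercept,
      motion_age_slope = motion_age_slope, motion_sd = motion_sd,
      motion_tau_coupling = motion_tau_coupling,
      include_etiv = isTRUE(include_etiv), seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

region_labels <- function(n_regions) {
  sprintf("R%0*d", max(3L, nchar(n_regions)), seq_len(n_regions))
}

# Reproducible per-subject sub-seed: subjects can be regenerated independently.
subject_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 7919 + as.double(idx) * 104729) %% 2147483587)
}

#' Generate a synthetic cortical axis and spherical parcel centroids
#'
#' Places `n_regions / 2` quasi-uniform centroids on the right-facing
#' hemisphere of the unit sphere (golden-angle lattice) and mirrors them in
#' the x-axis to form the left hemisphere. A sensorimotor-association-like
#' axis is then built from a smooth scalar field on the sphere (a
#' latitude-like gradient plus low-frequency random components) and ranked
#' 1..n_regions, so the axis is spatially autocorrelated like a real
#' cortical gradient.
#'
#' @param n_regions Even count >= 4.
#' @param seed Integer seed for the random field.
#' @return A list with `axis` (tibble: region_id, rank) and `coords`
#'   (tibble: region_id, x, y, z, hemisphere).
#' @export
#' @examples
#' geo <- make_axis_and_coords(20, seed = 1)
#' head(geo$axis)
make_axis_and_coords <- function(n_regions, seed = 1L) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 4 ||
      n_regions %% 2 != 0) {
    its_abort("`n_regions` must be an even count >= 4", "invalid_argument")
  }
  n_regions <- as.integer(n_regions)
  m <- n_regions %/% 2L
  # Golden-angle lattice on the x > 0 half-sphere (polar axis = +x).
  k <- seq_len(m)
  cos_theta <- (k - 0.5) / m           # in (0, 1): stays on x > 0 side
  sin_theta <- sqrt(1 - cos_theta^2)
  golden <- pi * (3 - sqrt(5))
  az <- golden * k
  right <- cbind(x = cos_theta, y = sin_theta * cos(az), z = sin_theta * sin(az))
  left <- right
  left[, "x"] <- -left[, "x"]
  xyz <- rbind(left, right)
  hemisphere <- rep(c("left", "right"), each = m)
  ids <- region_labels(n_regions)

  coords <- tibble::tibble(
    region_id = ids,
    x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
    hemisphere = hemisphere
  )

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  unit <- function() { a <- rnorm(3); a / sqrt(sum(a^2)) }
  u <- unit(); v <- unit(); w <- unit(); w2 <- unit()
  # Latitude-like gradient plus low- and mid-frequency components: smooth at
  # neighbour scale but with multiscale structure, like a real cortical
  # gradient (a field from only hemisphere-scale components would make spun
  # copies of itself implausibly self-similar). Built on mirror-symmetric
  # coordinates (|x|, y, z) so the axis is bilaterally symmetric, the
  # property hemisphere-mirrored spinning relies on.
  sym <- cbind(abs(xyz[, "x"]), xyz[, "y"], xyz[, "z"])
  field <- 0.6 * xyz[, "z"] + 0.4 * drop(sym %*% u) +
    0.3 * drop(sym %*% v)^2 + 0.5 * sin(3 * pi * drop(sym %*% w)) +
    0.25 * cos(5 * pi * drop(sym %*% w2)) + rnorm(n_regions, sd = 0.01)
  axis <- tibble::tibble(
    region_id = ids,
    rank = as.integer(rank(field, ties.method = "first"))
  )
  list(axis = axis, coords = coords)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate a synthetic cohort table
#'
#' Draws subject ages uniformly over the configured range, a two-level sex
#' variable, a mean framewise displacement that declines linearly with age
#' plus Gaussian noise (truncated to positive values), and optionally a
#' lognormal estimated total intracranial volume.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns subject_id, age, sex, mean_fd (and etiv when
#'   configured).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(subject_seed(config$seed, 0L))
  n <- config$n_subjects
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "M", "F"), levels = c("F", "M"))
  mu_fd <- config$motion_intercept +
    config$motion_age_slope * (age - config$age_range[1])
  mean_fd <- mu_fd + rnorm(n, sd = config$motion_sd)
  # truncate to (0, Inf) by redrawing the noise for offending subjects
  bad <- which(mean_fd <= 0)
  while (length(bad) > 0) {
    mean_fd[bad] <- mu_fd[bad] + rnorm(length(bad), sd = config$motion_sd)
    if (config$motion_sd == 0) mean_fd[bad] <- pmax(mu_fd[bad], 1e-6)
    bad <- which(mean_fd <= 0)
  }
  out <- tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = age, sex = sex, mean_fd = mean_fd
  )
  if (config$include_etiv) {
    out$etiv <- rlnorm(n, meanlog = log(1.5e6), sdlog = 0.06)
  }
  out
}

#' AR(1) coefficient matching a target intrinsic timescale
#'
#' Inverts the closed form of the positive-ACF-sum estimator for a
#' stationary AR(1) process: the population ACF is `phi^k`, all lags are
#' positive, and the sum over lags 0, 1, 2, ... times TR equals
#' `tr / (1 - phi)`. Solving for the coefficient gives
#' `phi = 1 - tr / tau`.
#'
#' @param tau Target timescale in seconds (`tau >= tr`). Vectorized.
#' @param tr Repetition time in seconds.
#' @return AR(1) coefficient(s) in `[0, 1)`.
#' @export
#' @examples
#' phi_for_timescale(1.6, 0.8)  # 0.5
phi_for_timescale <- function(tau, tr) {
  assert_scalar_number(tr, "tr", 0, strict = TRUE)
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < tr)) {
    its_abort("`tau` must be finite and >= `tr`", "invalid_argument")
  }
  1 - tr / tau
}

# Stationary AR(1) with unit marginal variance.
ar1_series <- function(n, phi) {
  x1 <- rnorm(1)
  if (n == 1L) return(x1)
  eps <- rnorm(n - 1L, sd = sqrt(1 - phi^2))
  c(x1, stats::filter(eps, phi, method = "recursive", init = x1))
}

# All regions of a subject at once: row-wise AR recursion over a matrix of
# innovations. Column j follows AR(1) with coefficient phi[j].
ar1_matrix <- function(n, phi) {
  r <- length(phi)
  x <- matrix(NA_real_, n, r)
  x[1, ] <- rnorm(r)
  eps <- matrix(rnorm((n - 1L) * r), n - 1L, r, byrow = TRUE) *
    rep(sqrt(1 - phi^2), each = n - 1L)
  for (t in 2:n) x[t, ] <- phi * x[t - 1L, ] + eps[t - 1L, ]
  x
}

#' Simulate parcellated time series for a whole cohort
#'
#' For subject s and region i the target timescale is
#' `tau_base + tau_axis_gain * r + tau_age_gain * r * a + g_s + e_si`,
#' where `r` is the region's axis rank normalized to `[0, 1]`, `a` the
#' subject's age normalized to `[0, 1]`, `g_s ~ N(0, subject_global_sd)` a
#' shared per-subject offset and `e_si ~ N(0, subject_sd)` region-level
#' noise; the result is optionally scaled by
#' `1 + motion_tau_coupling * mean_fd` and floored at TR. Each region's
#' series is a stationary unit-variance AR(1) with coefficient
#' [phi_for_timescale()] applied to its target. Subjects use independent
#' sub-seeds derived from `config$seed`, so any subject can be regenerated
#' alone.
#'
#' @param cohort Cohort tibble from [make_cohort()] (or same columns).
#' @param axis Axis tibble (region_id, rank) from [make_axis_and_coords()].
#' @param config A [synth_config()] consistent with both.
#' @return Named list of `parcellated_ts` objects, one per subject, with a
#'   `tau_target` attribute (subjects x regions matrix of target timescales).
#' @export
simulate_cohort_series <- function(cohort, axis, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(axis) != config$n_regions) {
    its_abort("axis map and config disagree on the number of regions",
              "invalid_argument")
  }
  if (nrow(cohort) != config$n_subjects) {
    its_abort("cohort and config disagree on the number of subjects",
              "invalid_argument")
  }
  axis <- dplyr::arrange(axis, .data$region_id)
  r_norm <- (axis$rank - 1) / (config$n_regions - 1)
  a_norm <- (cohort$age - config$age_range[1]) / diff(config$age_range)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  tau_target <- matrix(NA_real_, config$n_subjects, config$n_regions,
                       dimnames = list(cohort$subject_id, axis$region_id))
  out <- vector("list", config$n_subjects)
  names(out) <- cohort$subject_id
  for (s in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, s))
    g_s <- rnorm(1, sd = config$subject_global_sd)
    tau <- config$tau_base + config$tau_axis_gain * r_norm +
      config$tau_age_gain * r_norm * a_norm[s] + g_s +
      rnorm(config$n_regions, sd = config$subject_sd)
    if (config$motion_tau_coupling != 0) {
      tau <- tau * (1 + config$motion_tau_coupling * cohort$mean_fd[s])
    }
    tau <- pmax(tau, config$tr)
    tau_target[s, ] <- tau
    phi <- phi_for_timescale(tau, config$tr)
    dat <- ar1_matrix(config$n_timepoints, phi)
    out[[s]] <- parcellated_ts(dat, tr = config$tr,
                               subject_id = cohort$subject_id[s],
                               region_ids = axis$region_id)
  }
  attr(out, "tau_target") <- tau_target
  out
}
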