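#' Specification of the developmental GAM
#'
#' Describes the model fitted to every region (and to the whole-brain mean):
#' a Gaussian additive model with a penalized cubic regression spline of
#' age (small basis, k = 3, to avoid overfitting developmental
#' trajectories), linear covariates for sex and in-scanner motion
#' (optionally estimated total intracranial volume), and smoothing
#' parameters chosen by REML.
#'
#' @param smooth_term Name of the smooth covariate. Default "age".
#' @param basis_dim Maximum basis complexity k of the smooth (>= 3).
#' @param smoothing_selection "REML" (default) or "GCV" (mgcv's GCV.Cp).
#' @param linear_covariates Character vector of linear covariate names.
#' @param derivative_grid_size Grid points for trajectories/derivatives.
#' @return List of class `gam_spec`.
#' @export
gam_spec <- function(smooth_term = "age",
                     basis_dim = 3,
                     smoothing_selection = c("REML", "GCV"),
                     linear_covariates = c("sex", "mean_fd"),
                     derivative_grid_size = 200) {
  smoothing_selection <- match.arg(smoothing_selection)
  if (basis_dim < 3) its_abort("`basis_dim` must be >= 3", "invalid_argument")
  if (smooth_term %in% linear_covariates) {
    its_abort("smooth term cannot also be a linear covariate",
              "invalid_argument")
  }
  if (derivative_grid_size < 10) {
    its_abort("`derivative_grid_size` must be >= 10", "invalid_argument")
  }
  structure(
    list(smooth_term = smooth_term, basis_dim = as.integer(basis_dim),
         smoothing_selection = smoothing_selection,
         linear_covariates = linear_covariates,
         derivative_grid_size = as.integer(derivative_grid_size)),
    class = "gam_spec"
  )
}

#' Fit the full (smooth age) and reduced (covariates only) models
#'
#' The full model is `y ~ s(age, k = k, bs = "cr") + covariates` fitted by
#' [mgcv::gam()] with the spec's smoothness-selection criterion; the
#' reduced model drops the age term entirely and is ordinary least
#' squares on the same observations. `age_term = "linear"` replaces the
#' penalized smooth by an explicit unpenalized linear age column (OLS),
#' which makes the signed partial R-squared coincide with the classical
#' nested-OLS quantity -- used as an oracle in the test suite and for the
#' large-lambda limit.
#'
#' @param cohort Cohort tibble carrying the smooth term and covariates.
#' @param y Response vector, one value per cohort row (regional or
#'   whole-brain timescale in seconds).
#' @param spec A [gam_spec()].
#' @param age_term `"smooth"` (default) or `"linear"`.
#' @param sp Optional fixed smoothing parameter passed to [mgcv::gam()]
#'   (e.g. a very large value for the maximally-penalized limit).
#' @return Object of class `gam_pair`: list with elements `full`,
#'   `reduced` (fitted models), `sse_full`, `sse_reduced`, `edf_full`,
#'   `df_reduced`, `n`, `spec`, `data`.
#' @export
fit_gam_pair <- function(cohort, y, spec = gam_spec(),
                         age_term = c("smooth", "linear"), sp = NULL) {
  age_term <- match.arg(age_term)
  stopifnot(inherits(spec, "gam_spec"))
  if (!is.numeric(y) || length(y) != nrow(cohort) || any(!is.finite(y))) {
    its_abort("`y` must be finite numeric, one value per cohort row",
              "invalid_argument")
  }
  needed <- c(spec$smooth_term, spec$linear_covariates)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    its_abort(paste0("cohort lacks columns: ",
                     paste(missing_cols, collapse = ", ")),
              "invalid_argument")
  }
  min_n <- 10  # GAM needs residual degrees of freedom
  if (nrow(cohort) < min_n) {
    its_abort(sprintf("need at least %d subjects", min_n), "invalid_argument")
  }
  dat <- dplyr::mutate(cohort[needed], .y = y)

  cov_rhs <- paste(spec$linear_covariates, collapse = " + ")
  reduced_formula <- stats::as.formula(paste(".y ~", cov_rhs))
  reduced <- lm(reduced_formula, data = dat)
  if (reduced$rank < ncol(model.matrix(reduced))) {
    its_abort("rank-deficient linear covariates", "invalid_argument")
  }

  if (age_term == "smooth") {
    full_formula <- stats::as.formula(sprintf(
      ".y ~ s(%s, k = %d, bs = \"cr\") + %s", spec$smooth_term,
      spec$basis_dim, cov_rhs))
    method <- if (spec$smoothing_selection == "REML") "REML" else "GCV.Cp"
    full <- mgcv::gam(full_formula, data = dat, method = method, sp = sp)
    if (!full$converged) {
      its_abort("smoothing-parameter search did not converge",
                "estimation_failure")
    }
    edf_full <- sum(full$edf)
  } else {
    full_formula <- stats::as.formula(paste(".y ~", spec$smooth_term, "+",
                                            cov_rhs))
    full <- lm(full_formula, data = dat)
    edf_full <- full$rank
  }

  sse_full <- sum(residuals(full)^2)
  sse_reduced <- sum(residuals(reduced)^2)
  if (sse_full > sse_reduced + 1e-9 * max(1, sse_reduced)) {
    warn("full-model SSE exceeds reduced-model SSE (nesting violated)")
  }
  structure(
    list(full = full, reduced = reduced, sse_full = sse_full,
         sse_reduced = sse_reduced, edf_full = edf_full,
         df_reduced = reduced$rank, n = nrow(dat), spec = spec,
         data = dat, age_term = age_term),
    class = "gam_pair"
  )
}

#' @export
print.gam_pair <- function(x, ...) {
  cat(sprintf(
    "<gam_pair> n = %d; SSE full %.4g (edf %.2f) vs reduced %.4g (df %d)\n",
    x$n, x$sse_full, x$edf_full, x$sse_reduced, x$df_reduced))
  cat(sprintf("  signed partial R^2 = %.4g, p_anova = %.3g\n",
              signed_partial_r2(x), gam_anova_p(x)))
  invisible(x)
}

#' Signed partial R-squared of the age term
#'
#' Magnitude is the relative SSE drop from adding the age term,
#' `(SSE_reduced - SSE_full) / SSE_reduced`; the sign is the sign of the
#' mean first derivative of the fitted age smooth over a dense grid, so a
#' region whose timescale declines with age gets a negative value even
#' though the magnitude is nonnegative.
#'
#' @param pair A [fit_gam_pair()] result.
#' @param trajectory Optional precomputed [smooth_trajectory()] output
#'   (avoids re-evaluating the fit when the caller already has it).
#' @return Signed partial R-squared in `[-1, 1]`.
#' @export
signed_partial_r2 <- function(pair, trajectory = NULL) {
  stopifnot(inherits(pair, "gam_pair"))
  if (pair$sse_reduced <= 0) {
    its_abort("reduced-model SSE is zero: partial R^2 undefined",
              "degenerate_input")
  }
  magnitude <- max(pair$sse_reduced - pair$sse_full, 0) / pair$sse_reduced
  if (is.null(trajectory)) {
    trajectory <- smooth_trajectory(pair,
                                    grid_size = pair$spec$derivative_grid_size)
  }
  s <- if (mean(trajectory$derivative) >= 0) 1 else -1
  s * magnitude
}

#' Approximate ANOVA p-value for the smooth age effect
#'
#' Nested-model F test built from the two models' SSEs and effective
#' degrees of freedom:
#' `F = [(SSE_r - SSE_f) / (edf_f - df_r)] / [SSE_f / (n - edf_f)]`,
#' referred to an F distribution on `(edf_f - df_r, n - edf_f)` degrees of
#' freedom (degrees of freedom counted including the intercept).
#'
#' @param pair A [fit_gam_pair()] result.
#' @return p-value in (0, 1].
#' @export
gam_anova_p <- function(pair) {
  stopifnot(inherits(pair, "gam_pair"))
  df1 <- pair$edf_full - pair$df_reduced
  df2 <- pair$n - pair$edf_full
  if (df1 <= 1e-8) {
    warn("no effective age degrees of freedom; returning p = 1")
    return(1)
  }
  delta <- max(pair$sse_reduced - pair$sse_full, 0)
  if (delta == 0) return(1)
  f_stat <- (delta / df1) / (pair$sse_full / df2)
  max(pf(f_stat, df1, df2, lower.tail = FALSE), .Machine$double.xmin)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up q-values and a rejection mask at the given level.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q_level FDR level (default 0.05, the conventional Q < 0.05).
#' @return Tibble with columns `p`, `q`, `significant`, in input order.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))$significant
fdr_bh <- function(pvals, q_level = 0.05) {
  if (length(pvals) == 0) {
    return(tibble::tibble(p = numeric(), q = numeric(),
                          significant = logical()))
  }
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    its_abort("p-values must lie in [0, 1]", "invalid_argument")
  }
  if (q_level <= 0 || q_level >= 1) {
    its_abort("`q_level` must be in (0, 1)", "invalid_argument")
  }
  q <- p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, q = q, significant = q <= q_level)
}

#' Fitted developmental trajectory and its derivative
#'
#' Evaluates the fitted model on a uniform age grid spanning the observed
#' range, with covariates fixed at reference values (first factor level;
#' sample mean for numeric covariates), and differentiates by central
#' finite differences. The age of maximal developmental change is the grid
#' age with the largest absolute derivative.
#'
#' @param pair A [fit_gam_pair()] result.
#' @param grid_size Number of grid points (>= 10).
#' @return Tibble with columns `age`, `fitted` (seconds), `derivative`
#'   (seconds / year) and attribute `age_max_change`.
#' @export
smooth_trajectory <- function(pair, grid_size = 200) {
  stopifnot(inherits(pair, "gam_pair"))
  if (grid_size < 10) its_abort("`grid_size` must be >= 10", "invalid_argument")
  spec <- pair$spec
  ages <- pair$data[[spec$smooth_term]]
  grid <- seq(min(ages), max(ages), length.out = grid_size)
  newdata <- tibble::tibble(!!spec$smooth_term := grid)
  for (cv in spec$linear_covariates) {
    col <- pair$data[[cv]]
    newdata[[cv]] <- if (is.numeric(col)) mean(col) else factor(
      levels(factor(col))[1], levels = levels(factor(col)))
  }
  fit <- as.numeric(predict(pair$full, newdata = newdata))
  h <- grid[2] - grid[1]
  deriv <- numeric(grid_size)
  deriv[2:(grid_size - 1)] <- (fit[3:grid_size] - fit[1:(grid_size - 2)]) /
    (2 * h)
  deriv[1] <- (fit[2] - fit[1]) / h
  deriv[grid_size] <- (fit[grid_size] - fit[grid_size - 1]) / h
  out <- tibble::tibble(age = grid, fitted = fit, derivative = deriv)
  attr(out, "age_max_change") <- grid[which.max(abs(deriv))]
  out
}

#' Whole-brain and regional developmental GAMs
#'
#' Reproduces the two-level analysis: (1) a whole-brain GAM on each
#' subject's mean timescale over unflagged regions, reported with an
#' uncorrected p-value; (2) one GAM per unflagged region, with
#' Benjamini-Hochberg FDR control across regions at `fdr_q`.
#'
#' @param maps Long per-subject timescale-map tibble
#'   (see [cohort_timescale_maps()]).
#' @param cohort Cohort tibble; subjects must match the maps exactly.
#' @param spec A [gam_spec()].
#' @param fdr_q FDR level across regions.
#' @return List of class `regional_gams` with `regional` (tibble: region_id,
#'   partial_r2_signed, p_anova, q_fdr, significant, edf, age_max_change,
#'   n_subjects), `whole_brain` (one-row tibble), `trajectories` (long
#'   tibble: region_id, age, fitted, derivative), `spec`.
#' @export
run_regional_gams <- function(maps, cohort, spec = gam_spec(), fdr_q = 0.05) {
  map_subjects <- unique(maps$subject_id)
  if (!setequal(map_subjects, cohort$subject_id) ||
      length(map_subjects) != nrow(cohort)) {
    off <- c(setdiff(map_subjects, cohort$subject_id),
             setdiff(cohort$subject_id, map_subjects))
    its_abort(paste0("maps and cohort subjects differ: ",
                     paste(head(off, 5), collapse = ", ")),
              "invalid_argument")
  }

  wide <- maps |>
    dplyr::mutate(
      value = ifelse(is.na(.data$flag), .data$timescale, NA_real_)) |>
    dplyr::select("subject_id", "region_id", "value") |>
    tidyr::pivot_wider(names_from = "region_id", values_from = "value") |>
    dplyr::arrange(match(.data$subject_id, cohort$subject_id))
  stopifnot(identical(wide$subject_id, cohort$subject_id))
  ymat <- as.matrix(wide[-1])

  whole_y <- rowMeans(ymat, na.rm = TRUE)
  wb_pair <- fit_gam_pair(cohort, whole_y, spec)
  wb_traj <- smooth_trajectory(wb_pair, spec$derivative_grid_size)
  whole_brain <- tibble::tibble(
    region_id = "whole_brain",
    partial_r2_signed = signed_partial_r2(wb_pair, wb_traj),
    p_anova = gam_anova_p(wb_pair),
    edf = wb_pair$edf_full,
    age_max_change = attr(wb_traj, "age_max_change"),
    n_subjects = wb_pair$n
  )

  usable <- colnames(ymat)[colSums(is.na(ymat)) == 0]
  fits <- lapply(usable, function(rid) {
    pair <- fit_gam_pair(cohort, ymat[, rid], spec)
    traj <- smooth_trajectory(pair, spec$derivative_grid_size)
    list(
      row = tibble::tibble(
        region_id = rid,
        partial_r2_signed = signed_partial_r2(pair, traj),
        p_anova = gam_anova_p(pair),
        edf = pair$edf_full,
        age_max_change = attr(traj, "age_max_change"),
        n_subjects = pair$n
      ),
      traj = dplyr::mutate(traj, region_id = rid, .before = 1)
    )
  })
  regional <- dplyr::bind_rows(lapply(fits, `[[`, "row"))
  adj <- fdr_bh(regional$p_anova, fdr_q)
  regional$q_fdr <- adj$q
  regional$significant <- adj$significant
  regional <- dplyr::relocate(regional, "q_fdr", "significant",
                              .after = "p_anova")
  structure(
    list(regional = regional, whole_brain = whole_brain,
         trajectories = dplyr::bind_rows(lapply(fits, `[[`, "traj")),
         spec = spec, wb_trajectory = wb_traj),
    class = "regional_gams"
  )
}

#' @export
print.regional_gams <- function(x, ...) {
  cat(sprintf(
    "<regional_gams> %d regions; whole-brain signed partial R^2 = %.4g (p = %.3g)\n",
    nrow(x$regional), x$whole_brain$partial_r2_signed,
    x$whole_brain$p_anova))
  cat(sprintf("  FDR-significant regions: %d (%.1f%%)\n",
              sum(x$regional$significant),
              100 * mean(x$regional$significant)))
  invisible(x)
}

#' @rdname fit_gam_pair
#' @param x A `gam_pair` object.
#' @param ... Unused.
#' @export
glance.gam_pair <- function(x, ...) {
  tibble::tibble(
    partial_r2_signed = signed_partial_r2(x),
    p_anova = gam_anova_p(x),
    sse_full = x$sse_full,
    sse_reduced = x$sse_reduced,
    edf = x$edf_full,
    df_reduced = x$df_reduced,
    n = x$n
  )
}

#' @rdname fit_gam_pair
#' @export
tidy.gam_pair <- function(x, ...) {
  co <- coef(x$full)
  tibble::tibble(term = names(co), estimate = unname(co))
}

#' @rdname run_regional_gams
#' @param x A `regional_gams` object.
#' @param ... Unused.
#' @export
tidy.regional_gams <- function(x, ...) x$regional

#' @rdname run_regional_gams
#' @export
glance.regional_gams <- function(x, ...) {
  dplyr::mutate(x$whole_brain,
                frac_significant = mean(x$regional$significant),
                n_regions = nrow(x$regional))
}
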