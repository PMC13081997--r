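#' Parcellated BOLD time series for one subject
#'
#' Light container for a timepoints x regions matrix with its repetition
#' time. Rows are volumes, columns are cortical parcels.
#'
#' @param data Numeric matrix, timepoints x regions, all finite, >= 20 rows.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject label.
#' @param region_ids Unique region labels, one per column.
#' @return Object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, tr, subject_id = "subject",
                           region_ids = colnames(data)) {
  if (!is.matrix(data) || !is.numeric(data)) {
    its_abort("`data` must be a numeric matrix (timepoints x regions)",
              "invalid_argument")
  }
  if (nrow(data) < 20) {
    its_abort("need at least 20 timepoints", "invalid_argument")
  }
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    its_abort(sprintf("non-finite value at timepoint %d, region column %d",
                      bad[1], bad[2]), "format_error")
  }
  assert_scalar_number(tr, "tr", 0, strict = TRUE)
  if (is.null(region_ids)) region_ids <- region_labels(ncol(data))
  region_ids <- as.character(region_ids)
  if (length(region_ids) != ncol(data) || anyDuplicated(region_ids)) {
    its_abort("`region_ids` must be unique, one per column", "invalid_argument")
  }
  colnames(data) <- region_ids
  structure(
    list(subject_id = as.character(subject_id), data = data, tr = tr,
         region_ids = region_ids),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("<parcellated_ts> %s: %d timepoints x %d regions, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Sample autocorrelation function of a time series
#'
#' Biased (denominator n) sample ACF of the demeaned series, the standard
#' estimator guaranteeing a valid autocorrelation sequence. The series is
#' z-scored first for fidelity with common practice; the ACF is invariant
#' to affine transforms so this does not change the estimate.
#'
#' @param series Numeric vector, length >= 20, not constant.
#' @param max_lag Largest lag to compute; default `min(n - 2, 200)`.
#' @return Tibble of class `acf_profile` with columns `lag` (0..max_lag)
#'   and `acf`, and attribute `n` (series length).
#' @export
#' @examples
#' p <- sample_acf(sin(1:100 / 5) + rnorm(100, sd = 0.1))
#' p$acf[1]  # always 1 at lag 0
sample_acf <- function(series, max_lag = NULL) {
  if (!is.numeric(series) || length(series) < 20 || any(!is.finite(series))) {
    its_abort("`series` must be finite numeric with length >= 20",
              "invalid_argument")
  }
  n <- length(series)
  if (is.null(max_lag)) max_lag <- min(n - 2L, 200L)
  if (max_lag > n - 2L || max_lag < 1L) {
    its_abort("`max_lag` must be in [1, n - 2]", "invalid_argument")
  }
  if (sd(series) == 0) {
    its_abort("constant series: autocorrelation undefined", "degenerate_input")
  }
  vals <- drop(acf_matrix(matrix(series, ncol = 1), max_lag))
  out <- tibble::tibble(lag = 0:max_lag, acf = vals)
  attr(out, "n") <- n
  class(out) <- c("acf_profile", class(out))
  out
}

# Column-wise acf_sum / zero_cross estimates straight from the ACF matrix;
# same semantics as timescale_from_acf() (verified against it in tests) but
# without per-region data-frame overhead.
acf_timescales_vec <- function(vals, tr, method, include_lag0 = TRUE,
                               on_no_crossing = c("truncate", "strict")) {
  on_no_crossing <- match.arg(on_no_crossing)
  n_regions <- ncol(vals)
  timescale <- rep(NA_real_, n_regions)
  flag <- rep(NA_character_, n_regions)
  for (i in seq_len(n_regions)) {
    v <- vals[, i]
    if (anyNA(v)) {
      flag[i] <- "constant"
      next
    }
    zi <- which(v[-1] <= 0)
    if (length(zi) == 0) {
      if (on_no_crossing == "strict") {
        its_abort("ACF has no zero-crossing within the profile",
                  "no_zero_crossing")
      }
      flag[i] <- "no_zero_crossing"
      z <- NA_integer_
    } else {
      z <- zi[1]
    }
    if (method == "acf_sum") {
      w <- v[seq_len(if (is.na(z)) length(v) else z)]
      if (!include_lag0) w <- w[-1]
      timescale[i] <- tr * sum(w[w > 0])
    } else {
      timescale[i] <- if (is.na(z)) NA_real_ else z * tr
    }
  }
  list(timescale = timescale, flag = flag)
}

# Biased sample ACF of every column at once via FFT (Wiener-Khinchin).
# Matches stats::acf(demean = TRUE) to numerical precision; columns with
# zero variance come back as NA.
acf_matrix <- function(x, max_lag) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x), check.margin = FALSE)
  npad <- stats::nextn(2L * n, 2)
  pad <- rbind(xc, matrix(0, npad - n, ncol(x)))
  f <- stats::mvfft(pad)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L), ,
                                                      drop = FALSE]
  denom <- rep(ac[1L, ], each = max_lag + 1L)
  out <- ac / matrix(denom, max_lag + 1L, ncol(x))
  out[, ac[1L, ] <= 0] <- NA_real_
  out
}

#' First zero-crossing lag of an ACF profile
#'
#' @param acf_profile Output of [sample_acf()] (or any tibble with `lag`
#'   and `acf` columns, lag 0 first).
#' @return Smallest lag k >= 1 with `acf[k] <= 0`, or `NA_integer_` if the
#'   ACF stays positive over the whole profile.
#' @export
#' @examples
#' first_zero_crossing(tibble::tibble(lag = 0:2, acf = c(1, 0.4, -0.2)))  # 2
first_zero_crossing <- function(acf_profile) {
  vals <- acf_profile$acf
  idx <- which(vals[-1] <= 0)
  if (length(idx) == 0) NA_integer_ else acf_profile$lag[idx[1] + 1L]
}

#' Intrinsic timescale from an ACF profile
#'
#' The primary estimator (`acf_sum`) multiplies the repetition time by the
#' sum of positive ACF values up to (excluding) the first zero-crossing --
#' a discrete area under the positive part of the ACF, including the lag-0
#' value of 1. Sensitivity variants: `zero_cross` returns the crossing lag
#' times TR; `exp_decay` fits `A * exp(-lag * tr / tau) + B` by nonlinear
#' least squares over lags 1..`min(z - 1, 50)` and returns the decay
#' constant tau.
#'
#' @param acf_profile Output of [sample_acf()].
#' @param tr Repetition time in seconds.
#' @param method One of `"acf_sum"`, `"exp_decay"`, `"zero_cross"`.
#' @param include_lag0 Include the lag-0 term (value 1) in the positive
#'   sum. Default TRUE.
#' @param on_no_crossing Policy when the ACF never crosses zero within the
#'   profile: `"truncate"` (default) sums all positive values up to the
#'   last lag and flags the estimate; `"strict"` raises an error. For
#'   `zero_cross` there is no estimate without a crossing and the value is
#'   flagged `NA` under `"truncate"`.
#' @return One-row tibble with `timescale` (seconds) and `flag`
#'   (`NA_character_` or a reason code).
#' @export
#' @examples
#' p <- tibble::tibble(lag = 0:3, acf = c(1, 0.5, 0.2, -0.1))
#' timescale_from_acf(p, tr = 0.8)$timescale  # 1.36
timescale_from_acf <- function(acf_profile, tr,
                               method = c("acf_sum", "exp_decay", "zero_cross"),
                               include_lag0 = TRUE,
                               on_no_crossing = c("truncate", "strict")) {
  method <- match.arg(method)
  on_no_crossing <- match.arg(on_no_crossing)
  assert_scalar_number(tr, "tr", 0, strict = TRUE)
  vals <- acf_profile$acf
  if (any(is.na(vals))) {
    return(tibble::tibble(timescale = NA_real_, flag = "constant"))
  }
  z <- first_zero_crossing(acf_profile)
  flag <- NA_character_
  if (is.na(z)) {
    if (on_no_crossing == "strict") {
      its_abort("ACF has no zero-crossing within the profile",
                "no_zero_crossing")
    }
    flag <- "no_zero_crossing"
  }

  if (method == "acf_sum") {
    upto <- if (is.na(z)) length(vals) else z  # positions 1..z are lags 0..z-1
    w <- vals[seq_len(upto)]
    if (!include_lag0) w <- w[-1]
    ts <- tr * sum(w[w > 0])
    return(tibble::tibble(timescale = ts, flag = flag))
  }

  if (method == "zero_cross") {
    ts <- if (is.na(z)) NA_real_ else z * tr
    return(tibble::tibble(timescale = ts, flag = flag))
  }

  # exp_decay: fit over lags 1..min(z - 1 if crossing exists else 50, 50)
  last <- min(if (is.na(z)) 50L else z - 1L, 50L, max(acf_profile$lag))
  if (last < 3L) {
    return(tibble::tibble(timescale = NA_real_, flag = "exp_fit_window"))
  }
  lags <- 1:last
  y <- vals[lags + 1L]
  # log-linear initialisation on the positive part
  init_fit <- lm(log(pmax(y, 1e-6)) ~ lags)
  rate0 <- max(-coef(init_fit)[2], 1e-4)
  start <- c(A = max(exp(coef(init_fit)[[1]]), 1e-3), tau = tr / rate0, B = 0)
  resid_fn <- function(par) y - (par[1] * exp(-lags * tr / par[2]) + par[3])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(A = 1e-8, tau = 1e-8, B = -1),
      upper = c(A = Inf, tau = Inf, B = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error") || !(fit$info %in% 1:4)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    its_abort(paste0("exponential-decay fit failed: ", msg),
              "estimation_failure")
  }
  tibble::tibble(timescale = unname(fit$par[["tau"]]), flag = flag)
}

#' Per-region intrinsic timescale map for one subject
#'
#' Applies [sample_acf()] and [timescale_from_acf()] to every region of a
#' parcellated time series. Degenerate regions (constant signal, or no
#' zero-crossing under the truncate policy) are flagged, never silently
#' dropped; flagged regions carry `NA` or truncated estimates depending on
#' the method and are excluded from downstream models via the flag.
#'
#' @param ts A [parcellated_ts()].
#' @param method Estimator, as in [timescale_from_acf()].
#' @param max_lag Largest ACF lag; default `min(n - 2, 200)`.
#' @param ... Passed to [timescale_from_acf()].
#' @return Tibble of class `timescale_map` with columns subject_id,
#'   region_id, timescale (seconds), flag, method.
#' @export
subject_timescale_map <- function(ts, method = "acf_sum", max_lag = NULL, ...) {
  stopifnot(inherits(ts, "parcellated_ts"))
  n <- nrow(ts$data)
  if (is.null(max_lag)) max_lag <- min(n - 2L, 200L)
  vals <- acf_matrix(ts$data, max_lag)
  if (method %in% c("acf_sum", "zero_cross")) {
    est <- acf_timescales_vec(vals, ts$tr, method, ...)
  } else {
    rows <- lapply(seq_along(ts$region_ids), function(i) {
      prof <- tibble::tibble(lag = 0:max_lag, acf = vals[, i])
      timescale_from_acf(prof, tr = ts$tr, method = method, ...)
    })
    est <- dplyr::bind_rows(rows)
  }
  out <- tibble::tibble(
    subject_id = ts$subject_id,
    region_id = ts$region_ids,
    timescale = est$timescale,
    flag = est$flag,
    method = method
  )
  n_degenerate <- sum(out$flag %in% "constant")
  if (n_degenerate > 0.5 * nrow(out)) {
    its_abort(sprintf("subject %s: %d of %d regions degenerate",
                      ts$subject_id, n_degenerate, nrow(out)),
              "subject_failure")
  }
  class(out) <- c("timescale_map", class(out))
  out
}

#' Timescale maps for a whole cohort
#'
#' @param series_list List of [parcellated_ts()] objects.
#' @param ... Passed to [subject_timescale_map()].
#' @return Long tibble (one row per subject x region) of class
#'   `timescale_map`.
#' @export
cohort_timescale_maps <- function(series_list, ...) {
  out <- dplyr::bind_rows(lapply(series_list, subject_timescale_map, ...))
  class(out) <- c("timescale_map", class(out))
  out
}

#' Group-mean timescale map
#'
#' Arithmetic mean per region across subjects, using only unflagged values;
#' the number of contributing subjects is recorded per region.
#'
#' @param maps Long timescale-map tibble (multiple subjects).
#' @return Tibble with subject_id = "group_mean", region_id, timescale,
#'   flag, method, n_subjects.
#' @export
group_mean_map <- function(maps) {
  if (nrow(maps) == 0) its_abort("no maps supplied", "invalid_argument")
  if (length(unique(maps$method)) != 1) {
    its_abort("maps mix estimation methods", "invalid_argument")
  }
  per_subject <- dplyr::summarise(dplyr::group_by(maps, .data$subject_id),
                                  k = dplyr::n(), .groups = "drop")
  if (length(unique(per_subject$k)) != 1) {
    its_abort("subjects have different region sets", "invalid_argument")
  }
  out <- maps |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      n_subjects = sum(is.na(.data$flag) & !is.na(.data$timescale)),
      timescale = mean(.data$timescale[is.na(.data$flag)], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      subject_id = "group_mean",
      flag = ifelse(.data$n_subjects == 0, "all_flagged", NA_character_),
      timescale = ifelse(.data$n_subjects == 0, NA_real_, .data$timescale),
      method = maps$method[1]
    ) |>
    dplyr::select("subject_id", "region_id", "timescale", "flag", "method",
                  "n_subjects")
  class(out) <- c("timescale_map", class(out))
  out
}

#' Temporal signal-to-noise ratio per region
#'
#' Mean over standard deviation of each region's series, computed on the
#' series as supplied (tSNR is meaningless after z-scoring).
#'
#' @param ts A [parcellated_ts()] with raw (non-normalized) signal.
#' @return Tibble: subject_id, region_id, tsnr, flag.
#' @export
tsnr_map <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  m <- unname(colMeans(ts$data))
  s <- unname(apply(ts$data, 2, sd))
  tibble::tibble(
    subject_id = ts$subject_id,
    region_id = ts$region_ids,
    tsnr = ifelse(s > 0, m / s, NA_real_),
    flag = ifelse(s > 0, NA_character_, "zero_variance")
  )
}
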