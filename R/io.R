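#' Read a parcellated time-series TSV
#'
#' Expected dialect: tab-separated, first row = region ids, one subsequent
#' row per timepoint (rows are time). A transposed file is only accepted
#' when `n_regions_hint` is supplied and matches after transposition;
#' otherwise orientation ambiguity is an error, not a guess.
#'
#' @param path File path.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject label; default the file name without
#'   extension.
#' @param n_regions_hint Optional expected region count enabling
#'   transposition detection.
#' @return A [parcellated_ts()].
#' @export
load_timeseries <- function(path, tr, subject_id = NULL,
                            n_regions_hint = NULL) {
  if (!file.exists(path)) {
    its_abort(paste0("time-series file not found: ", path), "format_error")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) its_abort(
      paste0("cannot parse ", path, ": ", conditionMessage(e)),
      "format_error")
  )
  if (nrow(df) == 0) {
    its_abort(paste0(path, ": header-only file (no timepoints)"),
              "format_error")
  }
  if (anyDuplicated(names(df))) {
    its_abort(paste0(path, ": duplicate region ids in header"),
              "format_error")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))][1]
    its_abort(paste0(path, ": non-numeric values in region column ", bad),
              "format_error")
  }
  mat <- as.matrix(df)
  if (!is.null(n_regions_hint) && ncol(mat) != n_regions_hint &&
      nrow(mat) == n_regions_hint) {
    mat <- t(mat)
    colnames(mat) <- region_labels(ncol(mat))
  }
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    its_abort(sprintf("%s: non-finite value at row %d, column %s", path,
                      bad[1], colnames(mat)[bad[2]]), "format_error")
  }
  if (nrow(mat) < 20) {
    its_abort(paste0(path, ": fewer than 20 timepoints"), "format_error")
  }
  parcellated_ts(mat, tr = tr, subject_id = subject_id)
}

#' Write a parcellated time series to TSV
#'
#' @param ts A [parcellated_ts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcellated_ts"))
  df <- tibble::as_tibble(ts$data)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write the small tabular inputs
#'
#' Cohort CSV (subject_id, age, sex, mean_fd, optional etiv), axis CSV
#' (region_id, rank), coords CSV (region_id, x, y, z, hemisphere), and
#' timescale-map TSV (region_id, timescale_s, flag, method).
#'
#' @param path File path.
#' @return A tibble of the corresponding shape.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
load_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "age", "sex", "mean_fd")
  if (!all(required %in% names(df))) {
    its_abort(paste0("cohort file lacks columns: ",
                     paste(setdiff(required, names(df)), collapse = ", ")),
              "format_error")
  }
  if (anyNA(df[required])) {
    its_abort("cohort has missing values in required columns", "format_error")
  }
  df$sex <- factor(df$sex)
  df
}

#' @rdname tabular_io
#' @param cohort,axis,coords Tibbles to write.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
load_axis <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("region_id", "rank") %in% names(df))) {
    its_abort("axis file needs columns region_id, rank", "format_error")
  }
  if (!setequal(df$rank, seq_len(nrow(df)))) {
    its_abort("axis ranks must be a permutation of 1..n_regions",
              "format_error")
  }
  df$rank <- as.integer(df$rank)
  df
}

#' @rdname tabular_io
#' @export
write_axis <- function(axis, path) {
  readr::write_csv(axis, path, progress = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
load_coords <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("region_id", "x", "y", "z", "hemisphere")
  if (!all(required %in% names(df))) {
    its_abort("coords file needs columns region_id, x, y, z, hemisphere",
              "format_error")
  }
  df
}

#' @rdname tabular_io
#' @export
write_coords <- function(coords, path) {
  readr::write_csv(coords, path, progress = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @param map A timescale-map tibble.
#' @export
write_timescale_map <- function(map, path) {
  out <- tibble::tibble(
    region_id = map$region_id, timescale_s = map$timescale,
    flag = map$flag, method = map$method
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
load_timescale_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    subject_id = sub("\\.[^.]*$", "", basename(path)),
    region_id = df$region_id, timescale = df$timescale_s,
    flag = as.character(df$flag), method = df$method
  )
}

#' Cohort quality-control filter
#'
#' Retains subjects with mean framewise displacement strictly below
#' `max_fd` (the conventional low-motion cut of 0.2 mm) and age inside the
#' closed interval `age_range`; logs how many rows each criterion removed.
#'
#' @param cohort Cohort tibble.
#' @param max_fd Motion threshold in mm (strict `<`).
#' @param age_range Inclusive age bounds in years.
#' @return Filtered cohort tibble.
#' @export
filter_cohort <- function(cohort, max_fd = 0.2, age_range = c(8, 22)) {
  fd_fail <- !(cohort$mean_fd < max_fd)
  age_fail <- cohort$age < age_range[1] | cohort$age > age_range[2]
  message(sprintf("cohort QC: %d removed for motion, %d for age (of %d)",
                  sum(fd_fail), sum(age_fail & !fd_fail), nrow(cohort)))
  out <- cohort[!fd_fail & !age_fail, ]
  if (nrow(out) == 0) {
    its_abort("no subjects survive QC: nothing to analyze", "invalid_argument")
  }
  out
}

#' Write a full synthetic dataset in the pipeline's ingestion formats
#'
#' Emits cohort.csv, axis.csv, coords.csv and one
#' `timeseries/<subject_id>.tsv` per subject, exactly the formats the
#' readers consume, so synthetic fixtures double as format tests.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated cohort, axis, coords and
#'   the directory.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  geo <- make_axis_and_coords(config$n_regions, config$seed)
  cohort <- make_cohort(config)
  series <- simulate_cohort_series(cohort, geo$axis, config)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  write_axis(geo$axis, file.path(dir, "axis.csv"))
  write_coords(geo$coords, file.path(dir, "coords.csv"))
  for (ts in series) {
    write_timeseries(ts, file.path(dir, "timeseries",
                                   paste0(ts$subject_id, ".tsv")))
  }
  invisible(list(cohort = cohort, axis = geo$axis, coords = geo$coords,
                 dir = dir))
}
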