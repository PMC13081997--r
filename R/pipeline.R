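#' Pipeline configuration
#'
#' Collects paths and analysis settings for [run_pipeline()]. Any field
#' can be overridden by CLI flags; the config itself can come from a flat
#' YAML-like `key: value` file via [load_pipeline_config()].
#'
#' @param timeseries_dir Directory of per-subject time-series TSVs.
#' @param cohort_path,axis_path,coords_path Input table paths.
#' @param output_dir Output directory.
#' @param tr Repetition time in seconds.
#' @param method Timescale estimator.
#' @param max_lag ACF lag cap (NULL = `min(n - 2, 200)`).
#' @param basis_dim,fdr_q GAM settings.
#' @param n_spins Spin count for null models.
#' @param seed Seed for the spin ensemble.
#' @param qc_max_fd,qc_age_range Cohort QC settings ([filter_cohort()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(timeseries_dir, cohort_path, axis_path,
                            coords_path, output_dir,
                            tr = 0.8,
                            method = c("acf_sum", "exp_decay", "zero_cross"),
                            max_lag = NULL,
                            basis_dim = 3, fdr_q = 0.05,
                            n_spins = 10000, seed = 1L,
                            qc_max_fd = 0.2, qc_age_range = c(8, 22)) {
  method <- match.arg(method)
  assert_scalar_number(tr, "tr", 0, strict = TRUE)
  assert_scalar_number(qc_max_fd, "qc_max_fd", 0, strict = TRUE)
  structure(
    list(timeseries_dir = timeseries_dir, cohort_path = cohort_path,
         axis_path = axis_path, coords_path = coords_path,
         output_dir = output_dir, tr = tr, method = method,
         max_lag = max_lag, basis_dim = basis_dim, fdr_q = fdr_q,
         n_spins = as.integer(n_spins), seed = as.integer(seed),
         qc_max_fd = qc_max_fd, qc_age_range = qc_age_range),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Flat `key: value` config file; vector-valued keys
#'   comma-separated.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    its_abort(paste0("config file not found: ", path), "format_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1))
  conf <- setNames(as.list(trimws(vals)), trimws(keys))
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  pipeline_config(
    timeseries_dir = conf$timeseries_dir, cohort_path = conf$cohort_path,
    axis_path = conf$axis_path, coords_path = conf$coords_path,
    output_dir = conf$output_dir,
    tr = num(conf$tr) %||% 0.8,
    method = conf$method %||% "acf_sum",
    max_lag = num(conf$max_lag),
    basis_dim = num(conf$basis_dim) %||% 3,
    fdr_q = num(conf$fdr_q) %||% 0.05,
    n_spins = num(conf$n_spins) %||% 10000,
    seed = num(conf$seed) %||% 1,
    qc_max_fd = num(conf$qc_max_fd) %||% 0.2,
    qc_age_range = num(conf$qc_age_range) %||% c(8, 22)
  )
}

#' Run the full analysis pipeline
#'
#' Estimate per-subject timescale maps, average them, fit whole-brain and
#' regional developmental GAMs, and test hierarchy alignment and axis
#' contrasts with spin permutations. Every stage's outputs are written
#' before the next begins and a JSON run manifest (config echo, seed,
#' flag counts, failure point on error) is always written.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the pipeline results (`maps`,
#'   `group_mean`, `gams`, `mean_hierarchy`, `effect_hierarchy`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("itsdev")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stage = "init", ok = FALSE
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  on.exit(write_manifest(), add = TRUE)

  for (p in c(config$cohort_path, config$axis_path, config$coords_path)) {
    if (!file.exists(p)) {
      its_abort(paste0("input file missing: ", p), "format_error")
    }
  }
  if (!dir.exists(config$timeseries_dir)) {
    its_abort(paste0("time-series directory missing: ", config$timeseries_dir),
              "format_error")
  }

  manifest$stage <- "load"
  cohort <- load_cohort(config$cohort_path)
  axis <- load_axis(config$axis_path)
  coords <- load_coords(config$coords_path)
  cohort <- filter_cohort(cohort, config$qc_max_fd, config$qc_age_range)
  manifest$n_subjects_post_qc <- nrow(cohort)

  manifest$stage <- "estimate"
  ts_files <- file.path(config$timeseries_dir,
                        paste0(cohort$subject_id, ".tsv"))
  maps <- dplyr::bind_rows(lapply(seq_along(ts_files), function(i) {
    ts <- load_timeseries(ts_files[i], tr = config$tr,
                          subject_id = cohort$subject_id[i])
    subject_timescale_map(ts, method = config$method,
                          max_lag = config$max_lag)
  }))
  class(maps) <- c("timescale_map", class(maps))
  manifest$n_flagged_region_estimates <- sum(!is.na(maps$flag))
  readr::write_tsv(maps, file.path(out_dir, "timescale_maps.tsv"),
                   progress = FALSE)

  manifest$stage <- "group_mean"
  gmean <- group_mean_map(maps)
  write_timescale_map(gmean, file.path(out_dir, "group_mean_map.tsv"))

  manifest$stage <- "gam"
  spec <- gam_spec(basis_dim = config$basis_dim)
  gams <- run_regional_gams(maps, cohort, spec, fdr_q = config$fdr_q)
  readr::write_tsv(
    dplyr::select(gams$regional, "region_id", "partial_r2_signed",
                  "p_anova", "q_fdr", "significant", "edf",
                  "age_max_change"),
    file.path(out_dir, "regional_gams.tsv"), progress = FALSE)
  readr::write_tsv(gams$trajectories,
                   file.path(out_dir, "trajectories.tsv"), progress = FALSE)
  readr::write_tsv(gams$whole_brain,
                   file.path(out_dir, "whole_brain_gam.tsv"),
                   progress = FALSE)

  manifest$stage <- "spin"
  ensemble <- spin_assignments(coords, config$n_spins, config$seed)
  mean_h <- hierarchy_summary(gmean, axis, ensemble)
  effect_h <- hierarchy_summary(
    dplyr::select(gams$regional, "region_id", "partial_r2_signed"),
    axis, ensemble)
  report <- list(
    mean_map = as.list(tidy(mean_h)),
    effect_map = as.list(tidy(effect_h)),
    whole_brain = as.list(gams$whole_brain),
    frac_significant = mean(gams$regional$significant)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest$stage <- "done"
  manifest$ok <- TRUE
  invisible(list(maps = maps, group_mean = gmean, gams = gams,
                 mean_hierarchy = mean_h, effect_hierarchy = effect_h,
                 manifest = manifest))
}
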