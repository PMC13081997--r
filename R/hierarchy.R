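#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; errors on constant input
#' rather than returning NA.
#'
#' @param map_a,map_b Numeric vectors with >= 3 paired finite values.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' spearman_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
spearman_r <- function(map_a, map_b) {
  ok <- is.finite(map_a) & is.finite(map_b)
  if (sum(ok) < 3) {
    its_abort("need >= 3 paired finite values", "invalid_argument")
  }
  a <- map_a[ok]; b <- map_b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    its_abort("constant input: rank correlation undefined",
              "undefined_statistic")
  }
  cor(a, b, method = "spearman")
}

#' Split regions into sensorimotor vs association groups along the axis
#'
#' Regions at or below the chosen quantile of the axis rank are labelled
#' sensorimotor; the rest association. The median split (default) is the
#' conventional dichotomy for boxplot-style contrasts along the axis.
#'
#' @param axis Axis tibble (region_id, rank).
#' @param split_quantile Quantile of the rank distribution (default 0.5).
#' @return Tibble: region_id, group (factor sensorimotor/association).
#' @export
#' @examples
#' axis_median_split(tibble::tibble(region_id = letters[1:4], rank = 1:4))
axis_median_split <- function(axis, split_quantile = 0.5) {
  cut <- quantile(axis$rank, split_quantile, names = FALSE)
  tibble::tibble(
    region_id = axis$region_id,
    group = factor(ifelse(axis$rank <= cut, "sensorimotor", "association"),
                   levels = c("sensorimotor", "association"))
  )
}

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param mask_a,mask_b Equal-length logical vectors, not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
#' @examples
#' dice_score(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))  # 0.5
dice_score <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) {
    its_abort("masks must have equal length", "invalid_argument")
  }
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    its_abort("both masks empty: Dice undefined", "degenerate_input")
  }
  2 * sum(a & b) / denom
}

#' Hierarchical-organization summary of a cortical map
#'
#' Bundles the two axis analyses applied to mean-timescale or
#' developmental-effect maps: (1) a spin-tested Spearman correlation of
#' the map with the axis rank; (2) a spin-tested Welch t contrast of the
#' map between association and sensorimotor regions (labels from a
#' quantile split of the axis, re-derived from the spun axis under the
#' null).
#'
#' @param map Numeric map (vector or tibble) aligned to the ensemble.
#' @param axis Axis tibble (region_id, rank).
#' @param ensemble A [spin_assignments()] ensemble.
#' @param split_quantile Sensorimotor/association split quantile.
#' @return List of class `hierarchy_summary` with `axis_correlation` and
#'   `group_difference` (`spin_test` objects), `groups`, `n_regions_used`.
#' @export
hierarchy_summary <- function(map, axis, ensemble, split_quantile = 0.5) {
  ranks <- align_values(axis, ensemble, value_col = "rank")
  vals <- align_values(map, ensemble)
  corr <- spin_correlation_test(vals, ranks, ensemble,
                                correlation = "spearman")
  groups <- axis_median_split(axis, split_quantile)
  diff <- spin_group_diff_test(vals, groups, ensemble, axis,
                               split_quantile = split_quantile)
  structure(
    list(axis_correlation = corr, group_difference = diff, groups = groups,
         n_regions_used = sum(is.finite(vals))),
    class = "hierarchy_summary"
  )
}

#' @export
print.hierarchy_summary <- function(x, ...) {
  cat(sprintf(
    "<hierarchy_summary> %d regions; axis r_s = %.3g (p_spin = %.3g); assoc-vs-sens t = %.3g (p_spin = %.3g)\n",
    x$n_regions_used, x$axis_correlation$statistic,
    x$axis_correlation$p_spin, x$group_difference$statistic,
    x$group_difference$p_spin))
  invisible(x)
}

#' @rdname hierarchy_summary
#' @param x A `hierarchy_summary` object.
#' @param ... Unused.
#' @export
tidy.hierarchy_summary <- function(x, ...) {
  tibble::tibble(
    axis_rs = x$axis_correlation$statistic,
    axis_p_spin = x$axis_correlation$p_spin,
    group_t = x$group_difference$statistic,
    group_p_spin = x$group_difference$p_spin,
    n_regions_used = x$n_regions_used
  )
}

#' Compare developmental results across two cohorts
#'
#' Replication machinery: spin-tested Spearman correlation of the two
#' regional signed-partial-R-squared maps, each cohort's fraction of
#' FDR-significant regions, and a spin-tested Dice overlap of the two
#' significance masks (dataset A's mask is the spun member by default).
#'
#' @param results_a,results_b `regional_gams` results (or their `regional`
#'   tibbles) on identical region sets.
#' @param ensemble A [spin_assignments()] ensemble.
#' @return List of class `cross_dataset_summary` with
#'   `effect_map_correlation`, `dice` (`spin_test` objects or NULL when a
#'   mask is empty), `significant_fraction_a`, `significant_fraction_b`.
#' @export
compare_datasets <- function(results_a, results_b, ensemble) {
  ra <- if (inherits(results_a, "regional_gams")) results_a$regional else results_a
  rb <- if (inherits(results_b, "regional_gams")) results_b$regional else results_b
  if (!setequal(ra$region_id, rb$region_id)) {
    its_abort("results cover different region sets", "invalid_argument")
  }
  corr <- spin_correlation_test(
    dplyr::select(ra, "region_id", "partial_r2_signed"),
    dplyr::select(rb, "region_id", "partial_r2_signed"),
    ensemble, correlation = "spearman"
  )
  frac_a <- mean(ra$significant)
  frac_b <- mean(rb$significant)
  dice <- tryCatch(
    spin_dice_test(
      dplyr::select(ra, "region_id", "significant"),
      dplyr::select(rb, "region_id", "significant"),
      ensemble
    ),
    itsdev_error = function(e) NULL
  )
  structure(
    list(effect_map_correlation = corr, dice = dice,
         significant_fraction_a = frac_a, significant_fraction_b = frac_b),
    class = "cross_dataset_summary"
  )
}

#' @export
print.cross_dataset_summary <- function(x, ...) {
  cat(sprintf(
    "<cross_dataset_summary> effect-map r_s = %.3g (p_spin = %.3g); significant fractions %.3f / %.3f\n",
    x$effect_map_correlation$statistic, x$effect_map_correlation$p_spin,
    x$significant_fraction_a, x$significant_fraction_b))
  if (!is.null(x$dice)) {
    cat(sprintf("  Dice = %.3g (p_spin = %.3g)\n", x$dice$statistic,
                x$dice$p_spin))
  } else {
    cat("  Dice test unavailable (empty significance mask)\n")
  }
  invisible(x)
}

#' @rdname compare_datasets
#' @param x A `cross_dataset_summary` object.
#' @param ... Unused.
#' @export
tidy.cross_dataset_summary <- function(x, ...) {
  tibble::tibble(
    effect_rs = x$effect_map_correlation$statistic,
    effect_p_spin = x$effect_map_correlation$p_spin,
    significant_fraction_a = x$significant_fraction_a,
    significant_fraction_b = x$significant_fraction_b,
    dice = if (is.null(x$dice)) NA_real_ else x$dice$statistic,
    dice_p_spin = if (is.null(x$dice)) NA_real_ else x$dice$p_spin
  )
}

#' Association between parcel size and timescale
#'
#' Sensitivity check that parcel size does not drive timescale estimates:
#' per-subject Spearman correlation between parcel size and that
#' subject's timescale map, plus the across-subject mean.
#'
#' @param maps Long per-subject timescale-map tibble.
#' @param parcel_sizes Tibble (region_id, n_vertices) covering all
#'   unflagged regions.
#' @return List with `per_subject` (tibble: subject_id, r_s) and
#'   `mean_rs`.
#' @export
parcel_size_association <- function(maps, parcel_sizes) {
  per_subject <- maps |>
    dplyr::filter(is.na(.data$flag)) |>
    dplyr::inner_join(parcel_sizes, by = "region_id") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      r_s = spearman_r(.data$n_vertices, .data$timescale),
      .groups = "drop"
    )
  list(per_subject = per_subject, mean_rs = mean(per_subject$r_s))
}
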