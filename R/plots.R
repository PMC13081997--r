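#' Plot an autocorrelation profile
#'
#' Stem plot of the sample ACF with the positive area up to the first
#' zero-crossing shaded -- the quantity the acf_sum timescale integrates.
#'
#' @param object An `acf_profile` from [sample_acf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acf_profile <- function(object, ...) {
  z <- first_zero_crossing(object)
  shade <- object[object$lag < ifelse(is.na(z), max(object$lag) + 1, z) &
                    object$acf > 0, ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_area(data = shade, fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "lag", y = "autocorrelation") +
    ggplot2::theme_minimal()
}

#' Scatter of a regional map against the cortical axis
#'
#' @param map Tibble with `region_id` and one numeric value column.
#' @param axis Axis tibble (region_id, rank).
#' @param value_col Value column name; default the first numeric column.
#' @return A ggplot object.
#' @export
plot_map_vs_axis <- function(map, axis, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- names(map)[vapply(map, is.numeric, logical(1))][1]
  }
  df <- dplyr::inner_join(map, axis, by = "region_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data[[value_col]],
                                   colour = .data$rank)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(option = "plasma", guide = "none") +
    ggplot2::labs(x = "sensorimotor-association axis rank", y = value_col) +
    ggplot2::theme_minimal()
}

#' Developmental trajectories coloured by axis rank
#'
#' One fitted line per region, the visual signature of hierarchical
#' development: flat low-rank (sensorimotor) trajectories, rising
#' high-rank (association) ones.
#'
#' @param object A `regional_gams` result.
#' @param axis Optional axis tibble to colour lines by rank.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_gams <- function(object, axis = NULL, ...) {
  traj <- object$trajectories
  if (!is.null(axis)) {
    traj <- dplyr::inner_join(traj, axis, by = "region_id")
    p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$age, y = .data$fitted,
                                            group = .data$region_id,
                                            colour = .data$rank)) +
      ggplot2::scale_colour_viridis_c(option = "plasma",
                                      name = "axis rank")
  } else {
    p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$age, y = .data$fitted,
                                            group = .data$region_id))
  }
  p +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.4) +
    ggplot2::labs(x = "age (years)", y = "fitted intrinsic timescale (s)") +
    ggplot2::theme_minimal()
}

#' @rdname fit_gam_pair
#' @param object A `gam_pair` object.
#' @export
autoplot.gam_pair <- function(object, ...) {
  traj <- smooth_trajectory(object, object$spec$derivative_grid_size)
  obs <- tibble::tibble(age = object$data[[object$spec$smooth_term]],
                        y = object$data$.y)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$age, y = .data$fitted)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y),
                        alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(x = "age (years)", y = "intrinsic timescale (s)") +
    ggplot2::theme_minimal()
}
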