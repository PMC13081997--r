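#' Haar-uniform random rotation matrix
#'
#' Uniform random element of SO(3), drawn via a normalized quaternion.
#'
#' @param rng Ignored except for documentation symmetry; the draw consumes
#'   the current RNG stream.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(rng = NULL) {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Assignment for one rotation: each target parcel takes the value of the
# nearest rotated source centroid within its own hemisphere. Left
# hemisphere gets R, right gets the x-mirror conjugate M R M.
spin_assignment_for_rotation <- function(coords, rotation) {
  xyz <- as.matrix(coords[c("x", "y", "z")])
  assignment <- integer(nrow(coords))
  mirror <- diag(c(-1, 1, 1))
  for (hemi in c("left", "right")) {
    idx <- which(coords$hemisphere == hemi)
    rot <- if (hemi == "left") rotation else mirror %*% rotation %*% mirror
    rotated <- xyz[idx, , drop = FALSE] %*% t(rot)
    # nearest neighbour by max cosine = min great-circle distance
    sim <- xyz[idx, , drop = FALSE] %*% t(rotated)
    assignment[idx] <- idx[max.col(sim, ties.method = "first")]
  }
  assignment
}

#' Build a spin-permutation ensemble from spherical parcel centroids
#'
#' Draws `n_spins` Haar-uniform rotations; each is applied to the left
#' hemisphere's centroids and x-mirrored onto the right hemisphere, and
#' every target parcel is reassigned the index of the nearest rotated
#' source centroid within its own hemisphere (the standard parcel-level
#' adaptation of vertex spinning; duplicate sources are accepted). The
#' resulting index matrix permutes any region-aligned map while preserving
#' its spatial autocorrelation.
#'
#' @param coords Coords tibble (region_id, x, y, z, hemisphere); each
#'   coordinate triple must have unit norm and both hemispheres >= 2
#'   regions.
#' @param n_spins Number of rotations (>= 1). The production default in
#'   this line of work is 10,000; calibration tests use a few hundred.
#' @param seed Integer seed; the ensemble is a pure function of
#'   (coords, n_spins, seed).
#' @return Object of class `spin_ensemble`: list with `assignment`
#'   (n_spins x n_regions integer matrix), `region_id`, `n_spins`, `seed`,
#'   `coords_fingerprint`.
#' @export
spin_assignments <- function(coords, n_spins, seed = 1L) {
  required <- c("region_id", "x", "y", "z", "hemisphere")
  if (!all(required %in% names(coords))) {
    its_abort("coords need columns region_id, x, y, z, hemisphere",
              "invalid_argument")
  }
  norms <- sqrt(coords$x^2 + coords$y^2 + coords$z^2)
  if (any(abs(norms - 1) > 1e-6)) {
    its_abort("centroids must lie on the unit sphere", "invalid_argument")
  }
  counts <- table(coords$hemisphere)
  if (length(counts) != 2 || any(counts < 2)) {
    its_abort("need >= 2 regions in each of two hemispheres",
              "invalid_argument")
  }
  assert_scalar_number(n_spins, "n_spins", 1)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  assignment <- matrix(NA_integer_, n_spins, nrow(coords))
  for (i in seq_len(n_spins)) {
    assignment[i, ] <- spin_assignment_for_rotation(coords, random_rotation())
  }
  structure(
    list(assignment = assignment, region_id = coords$region_id,
         n_spins = as.integer(n_spins), seed = as.integer(seed),
         coords_fingerprint = coords_fingerprint(coords)),
    class = "spin_ensemble"
  )
}

# Cheap deterministic fingerprint of the coordinate table (no external
# hashing dependency): quantized coordinates folded into a 32-bit integer.
coords_fingerprint <- function(coords) {
  q <- round(c(coords$x, coords$y, coords$z) * 1e6) +
    rep(as.double(match(coords$hemisphere, c("left", "right"))), 3)
  h <- 0
  for (v in q) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  sprintf("%d-%d", nrow(coords), as.integer(h))
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d spins x %d regions (seed %d)\n",
              x$n_spins, length(x$region_id), x$seed))
  invisible(x)
}

#' Empirical spin p-value
#'
#' Permutation p with the add-one convention
#' `p = (1 + #extreme nulls) / (1 + n_nulls)`; ties count as extreme. The
#' two-tailed version compares absolute values.
#'
#' @param observed Observed statistic.
#' @param nulls Null statistics (non-finite entries dropped with warning).
#' @param tails "two" (default), "greater", or "less".
#' @return p-value in `(0, 1]`, never below `1 / (1 + n_nulls)`.
#' @export
spin_pvalue <- function(observed, nulls, tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  keep <- is.finite(nulls)
  if (!all(keep)) {
    warn(sprintf("dropping %d non-finite null values", sum(!keep)))
    nulls <- nulls[keep]
  }
  if (length(nulls) == 0) its_abort("no finite null values", "invalid_argument")
  extreme <- switch(tails,
    two = sum(abs(nulls) >= abs(observed)),
    greater = sum(nulls >= observed),
    less = sum(nulls <= observed)
  )
  (1 + extreme) / (1 + length(nulls))
}

new_spin_test <- function(statistic, nulls, p, tails, method) {
  structure(
    list(statistic = statistic, null_distribution = nulls, p_spin = p,
         tails = tails, method = method, n_spins = length(nulls)),
    class = "spin_test"
  )
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("<spin_test> %s: statistic = %.4g, p_spin = %.4g (%d spins, %s-tailed)\n",
              x$method, x$statistic, x$p_spin, x$n_spins, x$tails))
  invisible(x)
}

#' @rdname spin_correlation_test
#' @param x A `spin_test` object.
#' @param ... Unused.
#' @export
tidy.spin_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_spin = x$p_spin, n_spins = x$n_spins, tails = x$tails)
}

#' Spin test for the correlation between two cortical maps
#'
#' The observed statistic correlates the two maps; the null distribution
#' correlates `map_a` with spun versions of `map_b` (one per ensemble
#' row). Regions flagged `NA` in either map are excluded pairwise.
#'
#' @param map_a,map_b Numeric vectors aligned to the ensemble's regions,
#'   or tibbles with `region_id` plus a value column (the column named by
#'   `value_col`, default the first numeric column).
#' @param ensemble A [spin_assignments()] ensemble.
#' @param correlation "spearman" (default) or "pearson".
#' @param tails Tail convention for [spin_pvalue()].
#' @param value_col Optional value column name for tibble input.
#' @return A `spin_test` object.
#' @export
spin_correlation_test <- function(map_a, map_b, ensemble,
                                  correlation = c("spearman", "pearson"),
                                  tails = "two", value_col = NULL) {
  correlation <- match.arg(correlation)
  a <- align_values(map_a, ensemble, value_col)
  b <- align_values(map_b, ensemble, value_col)
  usable <- is.finite(a) & is.finite(b)
  if (sum(usable) < 10) {
    its_abort("fewer than 10 usable regions", "invalid_argument")
  }
  if (sd(a[usable]) == 0 || sd(b[usable]) == 0) {
    its_abort("constant map: correlation undefined", "degenerate_input")
  }
  observed <- cor(a[usable], b[usable], method = correlation)
  nulls <- vapply(seq_len(ensemble$n_spins), function(i) {
    bs <- b[ensemble$assignment[i, ]]
    ok <- usable & is.finite(bs)
    if (sum(ok) < 3 || sd(bs[ok]) == 0) return(NA_real_)
    cor(a[ok], bs[ok], method = correlation)
  }, numeric(1))
  new_spin_test(observed, nulls, spin_pvalue(observed, nulls, tails), tails,
                paste0("spin_", correlation))
}

align_values <- function(map, ensemble, value_col = NULL) {
  if (is.data.frame(map)) {
    if (is.null(value_col)) {
      num_cols <- names(map)[vapply(map, is.numeric, logical(1))]
      num_cols <- setdiff(num_cols, c("rank"))
      value_col <- if (length(num_cols) > 0) num_cols[1] else "rank"
    }
    idx <- match(ensemble$region_id, map$region_id)
    if (any(is.na(idx))) {
      its_abort("map does not cover the ensemble's regions",
                "invalid_argument")
    }
    vals <- map[[value_col]][idx]
    if ("flag" %in% names(map)) vals[!is.na(map$flag[idx])] <- NA_real_
    as.numeric(vals)
  } else {
    if (!is.null(names(map))) {
      idx <- match(ensemble$region_id, names(map))
      if (any(is.na(idx))) {
        its_abort("named map does not cover the ensemble's regions",
                  "invalid_argument")
      }
      as.numeric(map[idx])
    } else {
      if (length(map) != length(ensemble$region_id)) {
        its_abort("map length does not match ensemble regions",
                  "invalid_argument")
      }
      as.numeric(map)
    }
  }
}

# Welch two-sample t statistic (group 2 minus group 1 ordering handled by
# caller); returns NA when a group is too small.
welch_t <- function(x, g, min_group = 3L) {
  x1 <- x[!g]; x2 <- x[g]
  if (sum(is.finite(x1)) < min_group || sum(is.finite(x2)) < min_group) {
    return(NA_real_)
  }
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  (mean(x2) - mean(x1)) /
    sqrt(var(x2) / length(x2) + var(x1) / length(x1))
}

#' Spin test for a sensorimotor vs association group difference
#'
#' Observed statistic: Welch two-sample t of the values between the two
#' label groups (association minus sensorimotor). Null distribution: the
#' same t with labels recomputed from spun versions of the label-source
#' map (the axis), so the null preserves both the value map and the
#' labels' spatial structure.
#'
#' @param values_map Numeric map (vector or tibble) of regional values.
#' @param labels Logical/character map assigning each region to
#'   sensorimotor (FALSE / "sensorimotor") or association
#'   (TRUE / "association"), aligned like `values_map`; typically from
#'   [axis_median_split()].
#' @param ensemble A [spin_assignments()] ensemble.
#' @param label_source_map The continuous map the labels derive from
#'   (axis ranks); spun to generate null labelings.
#' @param split_quantile Quantile used to re-split the spun source map
#'   (default 0.5, median).
#' @param tails Tail convention (default two-tailed).
#' @return A `spin_test` object.
#' @export
spin_group_diff_test <- function(values_map, labels, ensemble,
                                 label_source_map, split_quantile = 0.5,
                                 tails = "two") {
  v <- align_values(values_map, ensemble)
  lab <- labels_to_logical(labels, ensemble)
  src <- align_values(label_source_map, ensemble)
  if (sum(lab, na.rm = TRUE) == 0 || sum(!lab, na.rm = TRUE) == 0) {
    its_abort("both label groups must be non-empty", "invalid_argument")
  }
  observed <- welch_t(v, lab, min_group = 1L)
  if (!is.finite(observed)) {
    its_abort("group difference undefined on observed data",
              "degenerate_input")
  }
  nulls <- vapply(seq_len(ensemble$n_spins), function(i) {
    src_spun <- src[ensemble$assignment[i, ]]
    cut <- quantile(src_spun, split_quantile, na.rm = TRUE, names = FALSE)
    welch_t(v, src_spun > cut)
  }, numeric(1))
  n_dropped <- sum(!is.finite(nulls))
  if (n_dropped > 0) {
    warn(sprintf("%d null spins dropped (group too small after spinning)",
                 n_dropped))
  }
  new_spin_test(observed, nulls[is.finite(nulls)],
                spin_pvalue(observed, nulls[is.finite(nulls)], tails),
                tails, "spin_group_diff")
}

labels_to_logical <- function(labels, ensemble) {
  if (is.data.frame(labels)) {
    idx <- match(ensemble$region_id, labels$region_id)
    lab <- labels$group[idx]
  } else if (!is.null(names(labels))) {
    lab <- labels[ensemble$region_id]
  } else {
    lab <- labels
  }
  if (is.character(lab) || is.factor(lab)) {
    as.character(lab) == "association"
  } else {
    as.logical(lab)
  }
}

#' Spin test for the Dice overlap of two binary region masks
#'
#' Observed statistic: [dice_score()] of the two masks. Null
#' distribution: Dice of spun `mask_a` against fixed `mask_b`. The default
#' tail is one-sided "greater" (overlap above chance).
#'
#' @param mask_a,mask_b Logical maps (vector or tibble with a logical
#'   column), each with at least one TRUE region.
#' @param ensemble A [spin_assignments()] ensemble.
#' @param tails Tail convention (default "greater").
#' @return A `spin_test` object.
#' @export
spin_dice_test <- function(mask_a, mask_b, ensemble, tails = "greater") {
  a <- mask_to_logical(mask_a, ensemble)
  b <- mask_to_logical(mask_b, ensemble)
  if (!any(a) || !any(b)) {
    its_abort("each mask needs at least one TRUE region", "degenerate_input")
  }
  observed <- dice_score(a, b)
  nulls <- vapply(seq_len(ensemble$n_spins), function(i) {
    dice_score(a[ensemble$assignment[i, ]], b)
  }, numeric(1))
  new_spin_test(observed, nulls, spin_pvalue(observed, nulls, tails), tails,
                "spin_dice")
}

mask_to_logical <- function(mask, ensemble) {
  if (is.data.frame(mask)) {
    idx <- match(ensemble$region_id, mask$region_id)
    if (any(is.na(idx))) {
      its_abort("mask does not cover the ensemble's regions",
                "invalid_argument")
    }
    lcol <- names(mask)[vapply(mask, is.logical, logical(1))][1]
    as.logical(mask[[lcol]][idx])
  } else if (!is.null(names(mask))) {
    as.logical(mask[ensemble$region_id])
  } else {
    if (length(mask) != length(ensemble$region_id)) {
      its_abort("mask length does not match ensemble regions",
                "invalid_argument")
    }
    as.logical(mask)
  }
}

#' @rdname spin_correlation_test
#' @export
autoplot.spin_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "null statistic (spun maps)", y = "count",
      title = sprintf("%s: statistic = %.3g, p_spin = %.3g",
                      object$method, object$statistic, object$p_spin)
    ) +
    ggplot2::theme_minimal()
}
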