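# Axonal line profiles: 30-um sampling lines perpendicular to the midline,
# averaged across lines, and the two-reference (cell body peak / axon shaft
# baseline) normalization.

#' Extract an averaged line profile from a density map
#'
#' Draws sampling lines perpendicular to the midline at 1-pixel spacing
#' within `band`, each starting on the midline and extending `length_um`
#' toward the ipsilateral side. Values are sampled by bilinear interpolation
#' at `step_um` spacing; lines with fewer than `min_defined_frac` defined
#' samples are dropped, and remaining lines are averaged at each distance
#' ignoring undefined samples. With the cell body adjacent to the midline,
#' profile distance 0 is the cell-body reference.
#'
#' @param map A [project_density()] map with a non-null `frame`.
#' @param band Interval of positions along the midline direction (um,
#'   relative to the map origin) within which lines are drawn; `NULL` spans
#'   the whole map.
#' @param length_um Profile length in microns (default 30).
#' @param step_um Sampling step along each line (default one pixel).
#' @param min_defined_frac Minimum fraction of defined samples for a line to
#'   be kept.
#' @return An object of class `line_profile`: `distances_um`, `values`,
#'   `n_lines_averaged`, plus the map's pixel and z-step sizes.
#' @export
extract_profile <- function(map, band = NULL, length_um = 30,
                            step_um = NULL, min_defined_frac = 0.5) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(map$frame)) abort("`map` must carry a midline frame.")
  check_number(length_um, "length_um", lower = 0, strict_lower = TRUE)
  if (is.null(step_um)) step_um <- map$pixel_um
  check_number(step_um, "step_um", lower = 0, strict_lower = TRUE)
  check_number(min_defined_frac, "min_defined_frac", lower = 0, upper = 1)
  fr <- map$frame
  nx <- nrow(map$values); ny <- ncol(map$values)

  if (is.null(band)) {
    # project the map corners onto the midline direction
    corners <- rbind(c(0, 0), c(nx, 0), c(0, ny), c(nx, ny)) * map$pixel_um
    t_rng <- range(sweep(corners, 2L, fr$midline_origin) %*% fr$midline_dir)
    band <- t_rng
  } else {
    check_window(band, "band")
  }
  t_pos <- seq(band[1], band[2], by = map$pixel_um)
  d_pos <- seq(0, length_um, by = step_um)

  samples <- vapply(t_pos, function(t) {
    pts_x <- fr$midline_origin[1] + t * fr$midline_dir[1] + d_pos * fr$lateral_axis[1]
    pts_y <- fr$midline_origin[2] + t * fr$midline_dir[2] + d_pos * fr$lateral_axis[2]
    bilinear_sample(map$values, pts_x / map$pixel_um + 0.5,
                    pts_y / map$pixel_um + 0.5)
  }, numeric(length(d_pos)))
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = length(d_pos))

  defined_frac <- colMeans(!is.na(samples))
  keep <- defined_frac >= min_defined_frac
  if (!any(keep)) {
    abort(sprintf("No sampling line has at least %.0f%% defined samples.",
                  100 * min_defined_frac))
  }
  values <- rowMeans(samples[, keep, drop = FALSE], na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  structure(
    list(distances_um = d_pos, values = values,
         n_lines_averaged = sum(keep),
         pixel_um = map$pixel_um, z_step_um = map$z_step_um),
    class = "line_profile"
  )
}

# Bilinear interpolation of a matrix at continuous 1-based pixel-center
# coordinates; returns NA where any contributing neighbor is NA or out of
# bounds.
bilinear_sample <- function(values, xi, yi) {
  nx <- nrow(values); ny <- ncol(values)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  out <- rep(NA_real_, length(xi))
  get <- function(i, j) {
    v <- rep(NA_real_, length(i))
    ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
    v[ok] <- values[cbind(i[ok], j[ok])]
    v
  }
  v00 <- get(x0, y0);     v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  # neighbors with zero weight may be undefined without harm
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  acc <- rep(0, length(xi)); bad <- rep(FALSE, length(xi))
  for (k in list(list(v00, w00), list(v10, w10), list(v01, w01), list(v11, w11))) {
    use <- k[[2]] > 1e-12
    bad <- bad | (use & is.na(k[[1]]))
    acc <- acc + ifelse(use, k[[2]] * ifelse(is.na(k[[1]]), 0, k[[1]]), 0)
  }
  out <- acc
  out[bad] <- NA_real_
  out
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.3g um, %d lines averaged\n",
              length(x$distances_um), max(x$distances_um), x$n_lines_averaged))
  invisible(x)
}

#' Tidy a line profile
#'
#' @param x A `line_profile` or `normalized_profile`.
#' @param ... Unused.
#' @return A tibble with `distance_um` and `value`.
#' @method tidy line_profile
#' @export
tidy.line_profile <- function(x, ...) {
  tibble(distance_um = x$distances_um, value = x$values)
}

#' @method tidy normalized_profile
#' @export
tidy.normalized_profile <- function(x, ...) {
  tibble(distance_um = x$distances_um, value = x$values)
}

#' Two-reference normalization of a line profile
#'
#' Anchors the profile to the mean value over the cell-body peak window
#' (mapped to 1) and the axon-shaft baseline window (mapped to 0):
#' `v' = (v - baseline_mean) / (peak_mean - baseline_mean)`. This removes
#' between-neuron differences in probe expression; the raw window means are
#' retained so scores can be re-expressed in raw ratio units.
#'
#' @param profile A [extract_profile()] result.
#' @param peak_window Interval (um) of the cell-body reference (default
#'   0-3 um from the cell body).
#' @param baseline_window Interval (um) of the axon-shaft reference (default
#'   20-25 um).
#' @param tol Degeneracy tolerance on `|peak_mean - baseline_mean|`.
#' @return An object of class `normalized_profile` with fields
#'   `distances_um`, `values`, `peak_value_raw`, `baseline_value_raw`.
#' @export
normalize_profile <- function(profile, peak_window = c(0, 3),
                              baseline_window = c(20, 25), tol = 1e-8) {
  stopifnot(inherits(profile, "line_profile"))
  dmax <- max(profile$distances_um)
  check_window(peak_window, "peak_window", lo = 0, hi = dmax)
  check_window(baseline_window, "baseline_window", lo = 0, hi = dmax)
  d <- profile$distances_um; v <- profile$values
  win_mean <- function(w) {
    sel <- d >= w[1] & d <= w[2] & !is.na(v)
    if (!any(sel)) abort("A reference window contains no defined samples.")
    mean(v[sel])
  }
  pm <- win_mean(peak_window)
  bm <- win_mean(baseline_window)
  if (abs(pm - bm) < tol) {
    abort("Degenerate profile: peak and baseline window means coincide (flat neuron).")
  }
  structure(
    list(distances_um = d, values = (v - bm) / (pm - bm),
         peak_value_raw = pm, baseline_value_raw = bm,
         peak_window = peak_window, baseline_window = baseline_window,
         pixel_um = profile$pixel_um, z_step_um = profile$z_step_um),
    class = "normalized_profile"
  )
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> peak %.4g, baseline %.4g (raw)\n",
              x$peak_value_raw, x$baseline_value_raw))
  invisible(x)
}
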