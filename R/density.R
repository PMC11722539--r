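# Depth-normalized 2D density maps: the per-column projection of masked
# per-voxel Y/C ratios used as the per-neuron activation image.

#' Project a masked ratio grid to a 2D density map
#'
#' For each (x, y) column, sums the masked, defined ratio values over z and
#' divides by the imaged object volume in that column (masked voxel count
#' times the z-step), i.e. the mean masked ratio per unit depth. Columns with
#' no masked defined voxel are undefined (`NA`). A whole-neuron divisor is
#' available behind `divisor = "neuron"`: each column sum is divided by the
#' total masked volume of the neuron instead, making the map depend on total
#' neuron size.
#'
#' @param ratio 3D ratio array (`NA` = undefined), as from [compute_ratio()].
#' @param mask Logical 3D object mask, congruent with `ratio`.
#' @param xy_pixel_um,z_step_um Voxel dimensions in microns.
#' @param frame Optional [midline_frame()] carried into the map.
#' @param divisor `"column"` (default, per-column depth) or `"neuron"`.
#' @return An object of class `density_map`: `values` (nx x ny matrix),
#'   `support_counts`, `frame`, `pixel_um`, `z_step_um`, `divisor`.
#' @export
project_density <- function(ratio, mask, xy_pixel_um, z_step_um,
                            frame = NULL, divisor = c("column", "neuron")) {
  divisor <- match.arg(divisor)
  if (!is.array(ratio) || length(dim(ratio)) != 3L ||
      !identical(dim(ratio), dim(mask))) {
    abort("`ratio` and `mask` must be congruent 3D arrays.")
  }
  check_number(xy_pixel_um, "xy_pixel_um", lower = 0, strict_lower = TRUE)
  check_number(z_step_um, "z_step_um", lower = 0, strict_lower = TRUE)
  ok <- mask & !is.na(ratio)
  contrib <- ratio
  contrib[!ok] <- 0
  total <- rowSums(contrib, dims = 2L)
  support <- rowSums(ok, dims = 2L)
  storage.mode(support) <- "integer"
  values <- switch(divisor,
    column = total / (support * z_step_um),
    neuron = total / (sum(support) * z_step_um)
  )
  values[support == 0L] <- NA_real_
  structure(
    list(values = values, support_counts = support, frame = frame,
         pixel_um = xy_pixel_um, z_step_um = z_step_um, divisor = divisor),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d cells (%.3g um px), %d defined\n",
              nrow(x$values), ncol(x$values), x$pixel_um,
              sum(!is.na(x$values))))
  invisible(x)
}

#' Tidy a density map into a long tibble
#'
#' @param x A `density_map`.
#' @param ... Unused.
#' @return A tibble with `x_um`, `y_um`, `density`, `support`.
#' @method tidy density_map
#' @export
tidy.density_map <- function(x, ...) {
  nx <- nrow(x$values); ny <- ncol(x$values)
  tibble(
    x_um = rep((seq_len(nx) - 0.5) * x$pixel_um, times = ny),
    y_um = rep((seq_len(ny) - 0.5) * x$pixel_um, each = nx),
    density = as.numeric(x$values),
    support = as.integer(x$support_counts)
  )
}
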