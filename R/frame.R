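# Midline reference frame for density maps and morphologies.
#
# All map/morphology coordinates live in a planar frame whose conventions
# follow the embryonic ventral nerve cord: the midline is an oriented line,
# the lateral axis is the perpendicular unit vector pointing toward the
# ipsilateral side (where the cell body sits), and distances are in microns.

#' Midline reference frame
#'
#' Builds the planar reference frame used to anchor line profiles and to
#' define laterality. The midline is the oriented line through
#' `midline_origin` along `midline_dir`; `lateral_axis` must be orthogonal to
#' it and points from the midline toward the ipsilateral side, where the cell
#' body lies.
#'
#' @param cellbody_position_um Numeric length-2, cell body (x, y) in microns.
#' @param midline_origin Numeric length-2, a point on the midline (microns).
#' @param midline_dir Numeric length-2 direction of the midline (normalized
#'   internally).
#' @param lateral_axis Numeric length-2 unit direction perpendicular to the
#'   midline, pointing toward the cell body side.
#' @return An object of class `midline_frame`.
#' @export
#' @examples
#' midline_frame(cellbody_position_um = c(3, 5))
midline_frame <- function(cellbody_position_um,
                          midline_origin = c(0, 0),
                          midline_dir = c(0, 1),
                          lateral_axis = c(1, 0)) {
  stopifnot(length(cellbody_position_um) == 2L, length(midline_origin) == 2L,
            length(midline_dir) == 2L, length(lateral_axis) == 2L)
  nrm <- function(v) v / sqrt(sum(v^2))
  midline_dir <- nrm(as.numeric(midline_dir))
  lateral_axis <- nrm(as.numeric(lateral_axis))
  if (abs(sum(midline_dir * lateral_axis)) > 1e-8) {
    abort("`lateral_axis` must be orthogonal to `midline_dir`.")
  }
  cb <- as.numeric(cellbody_position_um)
  if (sum((cb - as.numeric(midline_origin)) * lateral_axis) <= 0) {
    abort("`cellbody_position_um` must lie on the positive (ipsilateral) side of the midline.")
  }
  structure(
    list(midline_origin = as.numeric(midline_origin),
         midline_dir = midline_dir,
         lateral_axis = lateral_axis,
         cellbody_position_um = cb),
    class = "midline_frame"
  )
}

#' @export
print.midline_frame <- function(x, ...) {
  cat("<midline_frame>\n")
  cat(sprintf("  midline through (%.3g, %.3g) along (%.3g, %.3g)\n",
              x$midline_origin[1], x$midline_origin[2],
              x$midline_dir[1], x$midline_dir[2]))
  cat(sprintf("  lateral axis (%.3g, %.3g); cell body at (%.3g, %.3g) um\n",
              x$lateral_axis[1], x$lateral_axis[2],
              x$cellbody_position_um[1], x$cellbody_position_um[2]))
  invisible(x)
}

#' Signed lateral distance from the midline
#'
#' Positive on the ipsilateral (cell body) side.
#'
#' @param frame A [midline_frame()].
#' @param xy Numeric length-2 point, or an n x 2 matrix of points (microns).
#' @return Numeric vector of signed distances in microns.
#' @export
lateral_distance <- function(frame, xy) {
  stopifnot(inherits(frame, "midline_frame"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  sweep(xy, 2L, frame$midline_origin) %*% frame$lateral_axis |> as.numeric()
}

frame_to_list <- function(frame) {
  lapply(unclass(frame), as.numeric)
}

frame_from_list <- function(x) {
  midline_frame(cellbody_position_um = x$cellbody_position_um,
                midline_origin = x$midline_origin,
                midline_dir = x$midline_dir,
                lateral_axis = x$lateral_axis)
}
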