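# Two-channel ratiometric stack container and the per-voxel operations of the
# activation-quantification pipeline: background subtraction, Y/C ratio with a
# donor floor, and object/background threshold segmentation.

#' Two-channel ratiometric confocal stack
#'
#' Container for a donor (CFP) / acceptor (YFP) 3D voxel grid pair with voxel
#' dimensions. Array layout is `[x, y, z]` with the pixel center of index `i`
#' at `(i - 0.5) * xy_pixel_um` in map coordinates; x is the lateral (map)
#' axis, y runs along the midline, z is optical depth.
#'
#' @param donor,acceptor Non-negative 3D numeric arrays of identical shape.
#' @param xy_pixel_um In-plane pixel size in microns.
#' @param z_step_um Optical-section spacing in microns.
#' @param frame Optional [midline_frame()] locating the midline and cell body
#'   in map coordinates.
#' @return An object of class `ratiometric_stack`.
#' @export
ratiometric_stack <- function(donor, acceptor, xy_pixel_um, z_step_um,
                              frame = NULL) {
  if (!is.array(donor) || !is.array(acceptor) ||
      length(dim(donor)) != 3L || !identical(dim(donor), dim(acceptor))) {
    abort("`donor` and `acceptor` must be 3D arrays of identical shape.")
  }
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE)) {
    abort("Channel intensities must be non-negative.")
  }
  check_number(xy_pixel_um, "xy_pixel_um", lower = 0, strict_lower = TRUE)
  check_number(z_step_um, "z_step_um", lower = 0, strict_lower = TRUE)
  if (!is.null(frame)) stopifnot(inherits(frame, "midline_frame"))
  structure(
    list(donor = donor, acceptor = acceptor,
         xy_pixel_um = xy_pixel_um, z_step_um = z_step_um, frame = frame),
    class = "ratiometric_stack"
  )
}

#' @export
print.ratiometric_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("<ratiometric_stack> %d x %d x %d voxels (%.3g um px, %.3g um z-step)\n",
              d[1], d[2], d[3], x$xy_pixel_um, x$z_step_um))
  invisible(x)
}

#' @export
dim.ratiometric_stack <- function(x) dim(x$donor)

#' Subtract background fluorescence per channel
#'
#' Estimates a per-channel background level as the median intensity over a
#' background region and subtracts it, clamping at zero. Channels are
#' corrected independently, mirroring background correction against
#' non-labeled tissue.
#'
#' @param stack A [ratiometric_stack()].
#' @param background_roi Either `"auto"` (use a border band of the field,
#'   assumed cell-free) or a logical `nx x ny` matrix marking background
#'   pixels (applied at every z).
#' @return A background-corrected [ratiometric_stack()].
#' @export
subtract_background <- function(stack, background_roi = "auto") {
  stopifnot(inherits(stack, "ratiometric_stack"))
  d <- dim(stack$donor)
  if (identical(background_roi, "auto")) {
    band <- max(3L, ceiling(0.05 * min(d[1], d[2])))
    roi <- matrix(FALSE, d[1], d[2])
    roi[c(seq_len(band), d[1] - seq_len(band) + 1L), ] <- TRUE
    roi[, c(seq_len(band), d[2] - seq_len(band) + 1L)] <- TRUE
  } else {
    roi <- background_roi
    if (!is.matrix(roi) || !is.logical(roi) ||
        !identical(dim(roi), d[1:2])) {
      abort("`background_roi` must be \"auto\" or a logical nx x ny matrix.")
    }
  }
  if (!any(roi)) {
    abort("Background estimation failed: the background ROI is empty (mask covers the entire field).")
  }
  sel <- array(roi, dim = d)  # replicate the 2D roi over z
  out_d <- pmax(stack$donor - median(stack$donor[sel]), 0)
  out_a <- pmax(stack$acceptor - median(stack$acceptor[sel]), 0)
  ratiometric_stack(array(out_d, d), array(out_a, d),
                    stack$xy_pixel_um, stack$z_step_um, stack$frame)
}

#' Per-voxel acceptor/donor emission ratio
#'
#' Computes the yellow/cyan ratio on a background-corrected stack. Voxels
#' whose donor intensity falls below `donor_floor` are marked undefined
#' (`NA`) rather than producing unstable or non-finite ratios.
#'
#' @param stack A background-corrected [ratiometric_stack()].
#' @param donor_floor Minimum donor intensity for a defined ratio. Default:
#'   1% of the median donor intensity inside `mask` (or of positive donor
#'   voxels when no mask is supplied).
#' @param mask Optional logical 3D object mask used only to set the default
#'   floor.
#' @return 3D numeric array of ratios with `NA` at undefined voxels.
#' @export
compute_ratio <- function(stack, donor_floor = NULL, mask = NULL) {
  stopifnot(inherits(stack, "ratiometric_stack"))
  if (is.null(donor_floor)) {
    ref <- if (!is.null(mask)) stack$donor[mask] else stack$donor[stack$donor > 0]
    if (length(ref) == 0L) abort("Cannot derive a default `donor_floor`: no positive donor voxels.")
    donor_floor <- 0.01 * median(ref)
  }
  check_number(donor_floor, "donor_floor", lower = 0, strict_lower = TRUE)
  ratio <- stack$acceptor / stack$donor
  ratio[stack$donor < donor_floor] <- NA_real_
  ratio[!is.finite(ratio)] <- NA_real_
  ratio
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a binned histogram; returns a
#' threshold strictly between the two classes.
#'
#' @param x Numeric vector of intensities.
#' @param nbins Number of histogram bins.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("`x` has no finite values.")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins))
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(bcv)
  breaks[k + 1L]  # upper edge of the last class-1 bin
}

#' Object/background threshold segmentation
#'
#' Segments neuron ("object") voxels from background on the summed
#' donor+acceptor intensity, either with a fixed predefined threshold or with
#' an Otsu threshold computed from the whole-stack summed-intensity
#' histogram; the resulting threshold is applied voxelwise across all
#' z-planes.
#'
#' Because fluorescence fields are dominated by a large zero-mode background
#' and often contain a cell body much brighter than the neurites, the Otsu
#' threshold is computed on `log1p` summed intensities (a monotone transform,
#' so two-level images are still split exactly) and reported back in
#' intensity units.
#'
#' @param stack A [ratiometric_stack()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required intensity threshold when `method = "fixed"`.
#' @return Logical 3D mask, `TRUE` on object voxels (summed intensity >=
#'   threshold).
#' @export
segment_object <- function(stack, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(stack, "ratiometric_stack"))
  method <- match.arg(method)
  summed <- stack$donor + stack$acceptor
  thr <- switch(method,
    fixed = {
      if (is.null(threshold)) abort("`method = \"fixed\"` requires `threshold`.")
      check_number(threshold, "threshold")
      threshold
    },
    otsu = expm1(otsu_threshold(log1p(as.numeric(summed))))
  )
  mask <- summed >= thr
  if (!any(mask)) {
    abort(sprintf("Segmentation produced an empty mask (threshold %.4g above all intensities).", thr))
  }
  mask
}
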