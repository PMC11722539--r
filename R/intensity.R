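# Extracellular-stain intensity quantification: per-segment ROI means and
# the two-reference timecourse normalization (negative-control group -> 0,
# wild-type reference group -> 1).

#' Mean intensity over a region of interest
#'
#' @param image 2D or 3D numeric array.
#' @param roi Logical mask congruent with `image`.
#' @return Arithmetic mean intensity over the ROI.
#' @export
mean_roi_intensity <- function(image, roi) {
  if (!is.numeric(image) || is.null(dim(image))) {
    abort("`image` must be a 2D or 3D numeric array.")
  }
  if (!is.logical(roi) || !identical(dim(roi), dim(image))) {
    abort("`roi` must be a logical mask congruent with `image`.")
  }
  if (!any(roi)) abort("The ROI is empty.")
  mean(image[roi])
}

#' Two-reference normalization of intensity measurements
#'
#' Maps each measurement through
#' `v' = (v - mean(neg)) / (mean(pos) - mean(neg))`, so the negative-control
#' group mean lands exactly on 0 and the positive-reference group mean
#' exactly on 1. The convention follows normalizing a stain timecourse to
#' the null-mutant negative control (0) and the wild-type endpoint (1);
#' `flip_references` swaps the anchor assignment.
#'
#' @param measurements A data frame with at least `group` and `intensity`
#'   columns (for example from [generate_intensity_table()]).
#' @param neg_group,pos_group Group labels of the negative (-> 0) and
#'   positive (-> 1) references.
#' @param flip_references If `TRUE`, swap which reference maps to 0 and 1.
#' @return The input tibble with a `normalized_value` column appended.
#' @export
#' @examples
#' tab <- generate_intensity_table(1, c(mutant_15 = 10, wt_15 = 110), 0, 5)$table
#' normalize_two_reference(tab, "mutant_15", "wt_15")
normalize_two_reference <- function(measurements, neg_group, pos_group,
                                    flip_references = FALSE) {
  measurements <- as_tibble(measurements)
  if (!all(c("group", "intensity") %in% names(measurements))) {
    abort("`measurements` must have `group` and `intensity` columns.")
  }
  if (flip_references) {
    tmp <- neg_group; neg_group <- pos_group; pos_group <- tmp
  }
  for (g in c(neg_group, pos_group)) {
    if (!any(measurements$group == g)) {
      abort(sprintf("Reference group \"%s\" is absent from the table.", g))
    }
  }
  m_neg <- mean(measurements$intensity[measurements$group == neg_group])
  m_pos <- mean(measurements$intensity[measurements$group == pos_group])
  if (abs(m_pos - m_neg) < 1e-12 * max(1, abs(m_pos), abs(m_neg))) {
    abort("Degenerate references: the two reference group means coincide.")
  }
  dplyr::mutate(measurements,
                normalized_value = (.data$intensity - m_neg) / (m_pos - m_neg))
}

#' Per-group timecourse summary
#'
#' Summarizes normalized intensities per group as (mean, SEM, n), ordered by
#' the stated timepoint order.
#'
#' @param normalized Output of [normalize_two_reference()].
#' @param timepoint_order Optional character vector giving the timepoint
#'   display order.
#' @return A tibble with `group`, `timepoint`, `mean`, `sem`, `n`.
#' @export
timecourse_summary <- function(normalized, timepoint_order = NULL) {
  normalized <- as_tibble(normalized)
  if (!"normalized_value" %in% names(normalized)) {
    abort("`normalized` must contain a `normalized_value` column.")
  }
  if (!"timepoint" %in% names(normalized)) {
    normalized$timepoint <- sub("^.*_", "", normalized$group)
  }
  out <- normalized |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$normalized_value),
                     sem = sd(.data$normalized_value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  if (!is.null(timepoint_order)) {
    out <- dplyr::arrange(out, factor(.data$timepoint, levels = timepoint_order))
  }
  out
}
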