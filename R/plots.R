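# ggplot2 visualizations for each result type.

#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$density), ],
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Y/C density\n(ratio / um)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "Depth-normalized Y/C ratio density map")
}

#' @method autoplot line_profile
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$distance_um, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from cell body (um)",
                  y = "Y/C density (ratio / um)",
                  title = sprintf("Axonal line profile (%d lines averaged)",
                                  object$n_lines_averaged))
}

#' @method autoplot normalized_profile
#' @export
autoplot.normalized_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$distance_um, y = .data$value)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from cell body (um)",
                  y = "Normalized Y/C ratio",
                  title = "Normalized axonal profile (peak = 1, baseline = 0)")
}

#' @method autoplot gaussian_fit
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  d <- seq(min(object$data$distance_um), max(object$data$distance_um),
           length.out = 200)
  curve_df <- tibble(
    distance_um = d,
    value = object$amplitude *
      exp(-(d - object$center_um)^2 / (2 * object$sigma_um^2)) + object$offset
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance_um, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curve_df, color = "red") +
    ggplot2::labs(x = "Distance from cell body (um)", y = "Normalized Y/C",
                  title = sprintf("Gaussian fit: A = %.3g, mu = %.3g um, sigma = %.3g um",
                                  object$amplitude, object$center_um,
                                  object$sigma_um))
}

#' @method autoplot neuron_morphology
#' @export
autoplot.neuron_morphology <- function(object, ...) {
  nd <- object$nodes
  idx <- match(nd$parent, nd$id)
  seg <- tibble(x = nd$x_um, y = nd$y_um,
                xend = nd$x_um[idx], yend = nd$y_um[idx],
                kind = nd$kind)[!is.na(idx), ]
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend,
                                    color = .data$kind)) +
    ggplot2::geom_segment() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Lateral distance from midline (um)", y = "y (um)",
                  title = "Traced morphology (midline dashed)")
}

#' Bar plot of group activation with SEM error bars
#'
#' @param groups Output of [aggregate_group()].
#' @return A ggplot object.
#' @export
plot_group_activation <- function(groups) {
  ggplot2::ggplot(groups, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", color = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Activation score (AUC)",
                  title = "Group activation (mean +/- SEM)")
}

#' Timecourse plot of normalized intensity summaries
#'
#' @param summary Output of [timecourse_summary()].
#' @return A ggplot object.
#' @export
plot_intensity_timecourse <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                        group = 1)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "Timepoint (h AEL)", y = "Normalized intensity",
                  title = "Extracellular stain timecourse (references at 0 and 1)")
}
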