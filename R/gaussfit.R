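# Gaussian fitting of normalized axonal profiles and the area-under-curve
# activation score, plus group aggregation and fold changes.

#' Fit a Gaussian to a normalized line profile
#'
#' Least-squares fit of `f(d) = A * exp(-(d - mu)^2 / (2 sigma^2)) + c` to
#' the profile samples (undefined samples dropped). Initialization: `A =
#' max - min`, `mu = argmax`, `sigma = 3` um, `c` = baseline-window mean. A
#' Gauss-Newton (`nls`, port algorithm) fit is attempted first and refined by
#' bounded quasi-Newton minimization on failure; non-convergence is reported
#' through the `converged` flag, never as an error.
#'
#' @param profile A [normalize_profile()] result (or any object with
#'   `distances_um` and `values`).
#' @param init_sigma_um Initial sigma (um).
#' @return An object of class `gaussian_fit`: `amplitude`, `center_um`,
#'   `sigma_um`, `offset`, `residual_rmse`, `converged`, `n_points`, the data
#'   fitted, and (when available) the raw normalization span and z-step used
#'   for score rescaling.
#' @export
fit_gaussian <- function(profile, init_sigma_um = 3) {
  d <- profile$distances_um
  v <- profile$values
  if (length(d) != length(v)) {
    abort("`distances_um` and `values` must have equal length.")
  }
  ok <- !is.na(v) & !is.na(d)
  d <- d[ok]; v <- v[ok]
  if (length(d) < 8L) abort("Gaussian fitting needs at least 8 defined samples.")
  span_raw <- if (!is.null(profile$peak_value_raw)) {
    profile$peak_value_raw - profile$baseline_value_raw
  } else NA_real_
  bw <- if (!is.null(profile$baseline_window)) profile$baseline_window else NULL

  if (sd(v) < 1e-12) {
    # flat input: the zero-amplitude Gaussian is the exact least-squares fit
    return(new_gaussian_fit(0, mean(range(d)), init_sigma_um, mean(v),
                            0, TRUE, d, v, span_raw, profile$z_step_um))
  }
  c0 <- if (!is.null(bw)) {
    sel <- d >= bw[1] & d <= bw[2]
    if (any(sel)) mean(v[sel]) else median(v)
  } else median(v)  # most samples sit on the offset, not the bump
  # point the initial amplitude at whichever extremum departs more from the
  # offset estimate, so inverted bumps are inside the starting basin too
  if (max(v) - c0 >= c0 - min(v)) {
    start <- c(A = max(v) - min(v), mu = d[which.max(v)],
               sigma = init_sigma_um, c = c0)
  } else {
    start <- c(A = min(v) - max(v), mu = d[which.min(v)],
               sigma = init_sigma_um, c = c0)
  }
  lower <- c(A = -Inf, mu = -Inf, sigma = 1e-6, c = -Inf)

  model <- function(par) par[1] * exp(-(d - par[2])^2 / (2 * par[3]^2)) + par[4]
  sse <- function(par) sum((v - model(par))^2)

  est <- NULL; converged <- FALSE
  fit <- tryCatch(
    nls(v ~ A * exp(-(d - mu)^2 / (2 * sigma^2)) + c,
        data = list(d = d, v = v), start = as.list(start),
        lower = lower, algorithm = "port",
        control = nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    est <- coef(fit)[c("A", "mu", "sigma", "c")]
    converged <- isTRUE(fit$convInfo$isConv)
  }
  if (is.null(est) || !converged) {
    opt <- optim(if (is.null(est)) start else est, sse, method = "L-BFGS-B",
                 lower = lower, control = list(maxit = 1000))
    if (is.null(est) || opt$value <= sse(est)) {
      est <- opt$par
      converged <- opt$convergence == 0
    }
  }
  rmse <- sqrt(mean((v - model(est))^2))
  new_gaussian_fit(est[[1]], est[[2]], abs(est[[3]]), est[[4]],
                   rmse, converged, d, v, span_raw, profile$z_step_um)
}

new_gaussian_fit <- function(A, mu, sigma, c, rmse, converged, d, v,
                             span_raw, z_step_um) {
  structure(
    list(amplitude = A, center_um = mu, sigma_um = sigma, offset = c,
         residual_rmse = rmse, converged = converged,
         n_points = length(d),
         data = tibble(distance_um = d, value = v),
         norm_span_raw = span_raw,
         z_step_um = if (is.null(z_step_um)) NA_real_ else z_step_um),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> A = %.4g, mu = %.4g um, sigma = %.4g um, c = %.4g\n",
              x$amplitude, x$center_um, x$sigma_um, x$offset))
  cat(sprintf("  rmse %.3g over %d points; %s\n", x$residual_rmse, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("amplitude", "center_um", "sigma_um", "offset"),
         estimate = c(x$amplitude, x$center_um, x$sigma_um, x$offset))
}

#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(residual_rmse = x$residual_rmse, converged = x$converged,
         n_points = x$n_points)
}

#' Area under the fitted Gaussian component: the activation score
#'
#' Numerically integrates the Gaussian component
#' `A * exp(-(d - mu)^2 / (2 sigma^2))` (offset excluded, so the score
#' vanishes for flat profiles) over `domain`, to relative quadrature error
#' below 1e-8, and multiplies by `scale`.
#'
#' Fits on normalized profiles are dimensionless; `scale = "raw"` (the
#' default when the fit carries its normalization span) re-expresses the
#' score in raw ratio units per micron of depth times micron
#' (`(peak - baseline) * z_step`), which undoes both the peak/baseline
#' normalization and the depth-density division, making scores comparable
#' across neurons with different probe expression and acquisitions with
#' different z-steps. Use `scale = 1` for the dimensionless score.
#'
#' @param fit A [fit_gaussian()] result.
#' @param domain Integration interval in microns (default `c(0, 30)`).
#' @param scale `"raw"`, or a positive number multiplied into the score.
#' @param neuron_id,genotype Optional labels carried into the score row.
#' @param allow_unconverged Set `TRUE` to score a fit flagged as not
#'   converged.
#' @return A one-row tibble (class `activation_score`): `neuron_id`,
#'   `genotype`, `auc`, plus the fit parameters.
#' @export
compute_auc <- function(fit, domain = c(0, 30), scale = "raw",
                        neuron_id = NA_character_, genotype = NA_character_,
                        allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "gaussian_fit"))
  check_window(domain, "domain", lo = -Inf)
  if (!is.finite(fit$sigma_um) || fit$sigma_um <= 0) {
    abort("Fit has a non-finite or non-positive sigma; cannot integrate.")
  }
  if (!fit$converged && !allow_unconverged) {
    abort("Fit did not converge; pass `allow_unconverged = TRUE` to score it anyway.")
  }
  if (identical(scale, "raw")) {
    scale <- if (is.finite(fit$norm_span_raw) && is.finite(fit$z_step_um)) {
      fit$norm_span_raw * fit$z_step_um
    } else 1
  }
  check_number(scale, "scale")
  g <- function(x) fit$amplitude * exp(-(x - fit$center_um)^2 / (2 * fit$sigma_um^2))
  auc <- if (fit$amplitude == 0) 0 else {
    integrate(g, domain[1], domain[2], rel.tol = 1e-10, abs.tol = 0,
              subdivisions = 500L)$value
  }
  out <- tibble(neuron_id = neuron_id, genotype = genotype,
                auc = scale * auc,
                amplitude = fit$amplitude, center_um = fit$center_um,
                sigma_um = fit$sigma_um, offset = fit$offset,
                converged = fit$converged)
  class(out) <- c("activation_score", class(out))
  out
}

#' Quantify one stack end-to-end
#'
#' Runs the full activation-quantification chain on a two-channel stack:
#' background subtraction, segmentation, ratio, density projection, line
#' profile, two-reference normalization, Gaussian fit and AUC scoring.
#'
#' @param stack A [ratiometric_stack()] with a frame (or pass `frame`).
#' @param frame Optional [midline_frame()] overriding the stack's.
#' @param background_roi Passed to [subtract_background()].
#' @param method,threshold Passed to [segment_object()].
#' @param donor_floor Passed to [compute_ratio()].
#' @param peak_window,baseline_window Passed to [normalize_profile()].
#' @param domain,scale Passed to [compute_auc()].
#' @param length_um,band Passed to [extract_profile()].
#' @param neuron_id,genotype Labels carried into the score.
#' @return A one-row score tibble as from [compute_auc()], with the fit
#'   attached as attribute `"fit"`.
#' @export
quantify_stack <- function(stack, frame = NULL, background_roi = "auto",
                           method = "otsu", threshold = NULL,
                           donor_floor = NULL,
                           band = NULL, length_um = 30,
                           peak_window = c(0, 3), baseline_window = c(20, 25),
                           domain = c(0, 30), scale = "raw",
                           neuron_id = NA_character_, genotype = NA_character_) {
  stopifnot(inherits(stack, "ratiometric_stack"))
  if (is.null(frame)) frame <- stack$frame
  if (is.null(frame)) abort("A midline frame is required (in the stack or via `frame`).")
  corrected <- subtract_background(stack, background_roi)
  mask <- segment_object(corrected, method = method, threshold = threshold)
  ratio <- compute_ratio(corrected, donor_floor = donor_floor, mask = mask)
  dmap <- project_density(ratio, mask, corrected$xy_pixel_um,
                          corrected$z_step_um, frame = frame)
  prof <- extract_profile(dmap, band = band, length_um = length_um)
  nprof <- normalize_profile(prof, peak_window = peak_window,
                             baseline_window = baseline_window)
  fit <- fit_gaussian(nprof)
  score <- compute_auc(fit, domain = domain, scale = scale,
                       neuron_id = neuron_id, genotype = genotype,
                       allow_unconverged = TRUE)
  attr(score, "fit") <- fit
  score
}

#' Aggregate activation scores per group
#'
#' @param scores A tibble of per-neuron scores with an `auc` column; grouped
#'   by `genotype` unless a single `label` is supplied.
#' @param label Optional single group label overriding the `genotype` column.
#' @return A tibble with `label`, `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @export
aggregate_group <- function(scores, label = NULL) {
  scores <- as_tibble(scores)
  if (!"auc" %in% names(scores)) abort("`scores` must have an `auc` column.")
  if (!is.null(label)) scores$genotype <- label
  if (!"genotype" %in% names(scores)) scores$genotype <- "group"
  out <- scores |>
    dplyr::group_by(label = .data$genotype) |>
    dplyr::summarise(mean = mean(.data$auc),
                     sem = sd(.data$auc) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) {
    warn("Groups with n < 2 have undefined SEM.")
  }
  out
}

#' Fold change between two group means
#'
#' @param g1,g2 One-row group summaries from [aggregate_group()] (or numeric
#'   scalars); `g2` is the reference.
#' @return `mean(g1) / mean(g2)`.
#' @export
fold_change <- function(g1, g2) {
  m1 <- if (is.numeric(g1)) g1[[1]] else g1$mean[[1]]
  m2 <- if (is.numeric(g2)) g2[[1]] else g2$mean[[1]]
  if (!is.finite(m2) || m2 == 0) abort("Reference group mean is zero or not finite.")
  m1 / m2
}
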