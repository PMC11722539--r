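# Synthetic two-channel FRET z-stack generator.
#
# The scene is a stylized motoneuron: a spherical cell body touching the
# midline plus a straight cylindrical axon running perpendicular to the
# midline along the lateral (+x) axis. The planted acceptor/donor ratio along
# the axon axis is baseline + A * exp(-(d - center)^2 / (2 sigma^2)) with d
# the lateral distance from the midline (which, with the cell body adjacent
# to the midline, is also the distance from the cell-body reference). The
# acceptor channel is synthesized as donor signal times the target ratio, so
# the planted ratio is exact before noise; photon noise is independent
# Poisson per channel after brightness scaling.

#' Scene parameters for the synthetic stack generator
#'
#' Defaults state the imaging geometry the pipeline assumes: 0.5-um optical
#' sections spanning an 8-um z-depth, a >= 30 um axon so a 30-um line profile
#' is defined, and a localized activation bump in the proximal axon. The
#' brightness and background-offset defaults are placeholders for an
#' uncalibrated detector and are meant to be overridden per scene.
#'
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @param xy_pixel_um In-plane pixel size (um).
#' @param z_step_um Optical-section thickness (um).
#' @param z_depth_um Total imaged depth (um).
#' @param cellbody_radius_um Cell body radius (um).
#' @param axon_length_um Axon length from the midline (um, >= 30).
#' @param axon_width_um Axon diameter (um).
#' @param activation_amplitude True Gaussian peak height of the activation
#'   bump above baseline, in ratio units.
#' @param activation_center_um Bump center, distance from the cell body (um).
#' @param activation_sigma_um Bump width sigma (um).
#' @param baseline_ratio Baseline acceptor/donor ratio inside the neuron.
#' @param donor_brightness Mean donor signal photons per axon voxel; the cell
#'   body is rendered `cellbody_boost` times brighter.
#' @param cellbody_boost Brightness multiplier of the cell body over the axon.
#' @param background_offset Per-channel camera offset (counts), added
#'   everywhere.
#' @param noise_model `"none"` or `"poisson"`.
#' @param margin_um Blank margin around the neuron on each xy side (um).
#' @return A validated `scene_params` list.
#' @export
#' @examples
#' p <- scene_params(seed = 1, noise_model = "none")
scene_params <- function(seed = 1L,
                         xy_pixel_um = 0.1,
                         z_step_um = 0.5,
                         z_depth_um = 8,
                         cellbody_radius_um = 3,
                         axon_length_um = 30,
                         axon_width_um = 2,
                         activation_amplitude = 1.0,
                         activation_center_um = 8,
                         activation_sigma_um = 3,
                         baseline_ratio = 1.0,
                         donor_brightness = 200,
                         cellbody_boost = 3,
                         background_offset = 100,
                         noise_model = c("poisson", "none"),
                         margin_um = 2) {
  noise_model <- match.arg(noise_model)
  seed <- check_count(seed, "seed")
  for (nm in c("xy_pixel_um", "z_step_um", "z_depth_um", "cellbody_radius_um",
               "axon_length_um", "axon_width_um", "activation_sigma_um",
               "baseline_ratio")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_number(activation_amplitude, "activation_amplitude", lower = 0)
  check_number(activation_center_um, "activation_center_um",
               lower = 0, upper = axon_length_um)
  check_number(donor_brightness, "donor_brightness", lower = 0, strict_lower = TRUE)
  check_number(cellbody_boost, "cellbody_boost", lower = 1)
  check_number(background_offset, "background_offset", lower = 0)
  check_number(margin_um, "margin_um", lower = 0)
  structure(
    list(seed = seed, xy_pixel_um = xy_pixel_um, z_step_um = z_step_um,
         z_depth_um = z_depth_um, cellbody_radius_um = cellbody_radius_um,
         axon_length_um = axon_length_um, axon_width_um = axon_width_um,
         activation_amplitude = activation_amplitude,
         activation_center_um = activation_center_um,
         activation_sigma_um = activation_sigma_um,
         baseline_ratio = baseline_ratio,
         donor_brightness = donor_brightness, cellbody_boost = cellbody_boost,
         background_offset = background_offset, noise_model = noise_model,
         margin_um = margin_um),
    class = "scene_params"
  )
}

# Analytic integral of the planted Gaussian component over [0, L]
planted_auc <- function(amplitude, center, sigma, L) {
  amplitude * sigma * sqrt(2 * pi) *
    (pnorm((L - center) / sigma) - pnorm((0 - center) / sigma))
}

#' Generate a synthetic ratiometric stack with analytic ground truth
#'
#' Renders the stylized neuron described in [scene_params()] and returns the
#' two-channel stack together with the noise-free ratio profile along the
#' axon, the analytic area under the planted Gaussian component over the
#' profile domain `[0, axon_length_um]`, and the exact object mask.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `stack` (a [ratiometric_stack()] carrying the
#'   [midline_frame()]) and `truth` (class `ground_truth`: `true_profile`
#'   tibble, `true_auc`, `mask`, and the generating parameters).
#' @export
generate_ratiometric_stack <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  if (p$axon_length_um < 30) {
    abort("`axon_length_um` must be >= 30 um so that the 30-um line profile is defined.")
  }
  px <- p$xy_pixel_um
  nx <- ceiling((p$axon_length_um + 2 * p$margin_um) / px)
  ny <- ceiling((2 * p$cellbody_radius_um + 2 * p$margin_um) / px)
  nz <- max(1L, round(p$z_depth_um / p$z_step_um))

  # world coordinates: midline at x = margin, neuron axis at y-center, z-center
  x0 <- p$margin_um
  xc <- (seq_len(nx) - 0.5) * px - x0          # lateral distance from midline
  yc <- (seq_len(ny) - 0.5) * px
  zc <- (seq_len(nz) - 0.5) * p$z_step_um
  y_mid <- ny * px / 2
  z_mid <- nz * p$z_step_um / 2

  X <- array(rep(xc, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(yc, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), dim = c(nx, ny, nz))

  r2_yz <- (Y - y_mid)^2 + (Z - z_mid)^2
  soma <- (X - p$cellbody_radius_um)^2 + r2_yz <= p$cellbody_radius_um^2
  axon <- X >= 0 & X <= p$axon_length_um & r2_yz <= (p$axon_width_um / 2)^2
  mask <- soma | axon

  ratio <- p$baseline_ratio + p$activation_amplitude *
    exp(-(X - p$activation_center_um)^2 / (2 * p$activation_sigma_um^2))

  donor_sig <- array(0, dim = c(nx, ny, nz))
  donor_sig[axon] <- p$donor_brightness
  donor_sig[soma] <- p$donor_brightness * p$cellbody_boost
  donor <- p$background_offset + donor_sig
  acceptor <- p$background_offset + donor_sig * ratio

  if (p$noise_model == "poisson") {
    set.seed(p$seed)
    donor <- array(rpois(length(donor), lambda = donor), dim = dim(donor))
    acceptor <- array(rpois(length(acceptor), lambda = acceptor), dim = dim(acceptor))
    storage.mode(donor) <- "double"
    storage.mode(acceptor) <- "double"
  }

  frame <- midline_frame(
    cellbody_position_um = c(x0 + p$cellbody_radius_um, y_mid),
    midline_origin = c(x0, 0), midline_dir = c(0, 1), lateral_axis = c(1, 0)
  )
  stack <- ratiometric_stack(donor, acceptor, px, p$z_step_um, frame)

  d_grid <- seq(0, p$axon_length_um, by = px)
  truth <- structure(
    list(
      true_profile = tibble(
        distance_um = d_grid,
        ratio = p$baseline_ratio + p$activation_amplitude *
          exp(-(d_grid - p$activation_center_um)^2 / (2 * p$activation_sigma_um^2))
      ),
      true_auc = planted_auc(p$activation_amplitude, p$activation_center_um,
                             p$activation_sigma_um, p$axon_length_um),
      mask = mask,
      params = p
    ),
    class = "ground_truth"
  )
  list(stack = stack, truth = truth)
}
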