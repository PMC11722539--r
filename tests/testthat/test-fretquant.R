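# Activation quantification: each stage against its forced arithmetic or an
# independent oracle, plus the pipeline-level invariances.

test_that("background subtraction removes a constant per-channel offset", {
  d <- array(10, c(6, 6, 2)); a <- array(25, c(6, 6, 2))
  st <- ratiometric_stack(d, a, 0.5, 0.5)
  roi <- matrix(TRUE, 6, 6)
  corr <- subtract_background(st, roi)
  expect_true(all(corr$donor == 0) && all(corr$acceptor == 0))

  # zero background: identity
  st0 <- ratiometric_stack(array(c(0, 5), c(2, 2, 2)), array(1, c(2, 2, 2)), 1, 1)
  roi0 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  corr0 <- subtract_background(st0, roi0)
  expect_identical(corr0$donor, st0$donor)

  expect_error(subtract_background(st, matrix(FALSE, 6, 6)), "empty")
})

test_that("channel offsets (100, 150) are removed and the planted ratio recovered", {
  sim <- generate_ratiometric_stack(small_scene(seed = 11, background_offset = 100))
  # acceptor gets an extra +50 offset on top of the generator's 100
  st <- sim$stack
  st$acceptor <- st$acceptor + 50
  corr <- subtract_background(st)
  mask <- segment_object(corr)
  ratio <- compute_ratio(corr, mask = mask)
  m <- sim$truth$mask & mask & !is.na(ratio)
  p <- sim$truth$params
  x_lat <- (seq_len(dim(st$donor)[1]) - 0.5) * p$xy_pixel_um - p$margin_um
  planted <- p$baseline_ratio + p$activation_amplitude *
    exp(-(x_lat - p$activation_center_um)^2 / (2 * p$activation_sigma_um^2))
  idx <- which(m, arr.ind = TRUE)
  # median relative error under Poisson noise at default brightness
  rel <- abs(ratio[m] / planted[idx[, 1]] - 1)
  expect_lt(median(rel), 0.01 * 10)  # per-voxel noise
  expect_lt(abs(median(ratio[m] / planted[idx[, 1]]) - 1), 0.01)
})

test_that("ratio arithmetic and the donor floor guard", {
  d <- array(c(2, 1, 0.001, 4), c(2, 2, 1))
  a <- array(c(1, 1, 5, 2), c(2, 2, 1))
  st <- ratiometric_stack(d, a, 1, 1)
  r <- compute_ratio(st, donor_floor = 0.5)
  expect_equal(r[1, 1, 1], 0.5)
  expect_equal(r[2, 1, 1], 1)
  expect_true(is.na(r[1, 2, 1]))  # below floor: undefined, not Inf
  expect_equal(r[2, 2, 1], 0.5)
  expect_error(compute_ratio(st, donor_floor = 0), "donor_floor")

  st_eq <- ratiometric_stack(array(3, c(2, 2, 2)), array(3, c(2, 2, 2)), 1, 1)
  expect_true(all(compute_ratio(st_eq, donor_floor = 1) == 1))
})

test_that("segmentation recovers a two-level planted mask exactly", {
  sim <- generate_ratiometric_stack(small_scene(
    noise_model = "none", background_offset = 10, donor_brightness = 500,
    cellbody_boost = 1))
  mask <- segment_object(sim$stack)
  expect_identical(mask, sim$truth$mask)

  expect_error(segment_object(sim$stack, method = "fixed", threshold = 1e9),
               "empty mask")
  all_mask <- segment_object(sim$stack, method = "fixed", threshold = 0)
  expect_true(all(all_mask))
})

test_that("density projection matches its forced arithmetic and the naive loop", {
  # single plane: density = r / z_step
  r1 <- array(c(1.5, NA), c(1, 2, 1))
  m1 <- array(c(TRUE, FALSE), c(1, 2, 1))
  dm1 <- project_density(r1, m1, 1, 0.5)
  expect_equal(dm1$values[1, 1], 3)
  expect_true(is.na(dm1$values[1, 2]))
  expect_identical(dm1$support_counts, matrix(c(1L, 0L), 1, 2))

  # uniform ratio through k masked planes: r / z_step independent of k
  for (k in c(1, 3, 7)) {
    rk <- array(2, c(2, 2, k)); mk <- array(TRUE, c(2, 2, k))
    expect_equal(project_density(rk, mk, 1, 0.4)$values,
                 matrix(5, 2, 2))
  }

  # oracle equivalence on random stacks with undefined voxels
  set.seed(42)
  for (i in 1:5) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:5, 1))
    ratio <- array(runif(prod(d), 0.5, 3), d)
    ratio[runif(prod(d)) < 0.2] <- NA
    mask <- array(runif(prod(d)) < 0.6, d)
    dm <- project_density(ratio, mask, 0.2, 0.5)
    ref <- naive_density(ratio, mask, 0.5)
    expect_equal(dm$values, ref$values)
    expect_identical(dm$support_counts, ref$support)
  }
})

test_that("profile extraction averages lines perpendicular to the midline", {
  frame <- midline_frame(cellbody_position_um = c(4, 5),
                         midline_origin = c(2, 0))
  vals <- matrix(4.2, 40, 10)
  dm <- structure(list(values = vals, support_counts = matrix(1L, 40, 10),
                       frame = frame, pixel_um = 1, z_step_um = 0.5,
                       divisor = "column"),
                  class = "density_map")
  pr <- extract_profile(dm, length_um = 30)
  expect_equal(pr$values, rep(4.2, 31))
  expect_equal(pr$distances_um, 0:30)

  # argmax lands within one sampling step of the planted center
  sim <- generate_ratiometric_stack(small_scene(noise_model = "none"))
  sc <- quantify_stack(sim$stack)
  prof <- attr(sc, "fit")$data
  expect_lt(abs(prof$distance_um[which.max(prof$value)] -
                  sim$truth$params$activation_center_um), 0.25 + 1e-9)

  # a band holding a single line equals direct interpolation of that line
  one <- extract_profile(dm, band = c(5, 5.4), length_um = 20)
  expect_identical(one$n_lines_averaged, 1L)
  expect_equal(one$values, rep(4.2, 21))
})

test_that("profile normalization is anchored, affine-invariant, and guards flats", {
  d <- seq(0, 30, by = 0.5)
  mk_prof <- function(v) structure(list(distances_um = d, values = v,
                                        n_lines_averaged = 1L, pixel_um = 0.5,
                                        z_step_um = 0.5),
                                   class = "line_profile")
  base <- exp(-(d - 8)^2 / 18)
  np <- normalize_profile(mk_prof(base))
  pw <- d >= 0 & d <= 3; bw <- d >= 20 & d <= 25
  expect_equal(mean(np$values[bw]), 0, tolerance = 1e-12)
  expect_equal(mean(np$values[pw]), 1, tolerance = 1e-12)

  # already normalized input is unchanged
  np2 <- normalize_profile(mk_prof(np$values))
  expect_equal(np2$values, np$values, tolerance = 1e-12)

  # affine invariance: a * v + b maps to the same normalized profile
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    np_ab <- normalize_profile(mk_prof(a * base + b))
    expect_equal(np_ab$values, np$values, tolerance = 1e-9)
  }

  expect_error(normalize_profile(mk_prof(rep(2, length(d)))), "Degenerate")
})

test_that("gaussian fitting recovers exact-model samples to 1e-6", {
  d <- seq(0, 30, by = 0.25)
  mk <- function(v) list(distances_um = d, values = v, z_step_um = 0.5)
  v <- 1 * exp(-(d - 10)^2 / (2 * 9)) + 0
  fit <- fit_gaussian(mk(v))
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$center_um, 10, tolerance = 1e-5)
  expect_equal(fit$sigma_um, 3, tolerance = 1e-5)
  expect_equal(fit$offset, 0, tolerance = 1e-6)

  # offsets and negative amplitudes are inside the model class too
  v2 <- -0.4 * exp(-(d - 22)^2 / (2 * 4)) + 0.7
  fit2 <- fit_gaussian(mk(v2))
  expect_equal(fit2$amplitude, -0.4, tolerance = 1e-5)
  expect_equal(fit2$offset, 0.7, tolerance = 1e-6)

  flat <- fit_gaussian(mk(rep(0, length(d))))
  expect_true(flat$converged)
  expect_equal(flat$amplitude, 0)
  expect_equal(compute_auc(flat, scale = 1)$auc, 0)

  expect_error(fit_gaussian(list(distances_um = 0:4, values = v[1:5])),
               "at least 8")
})

test_that("AUC equals the error-function closed form", {
  mkfit <- function(A, mu, sigma, c = 0) {
    neurofret:::new_gaussian_fit(A, mu, sigma, c, 0, TRUE, 0:30, rep(0, 31),
                                 NA_real_, NA_real_)
  }
  f <- mkfit(1, 15, 3)
  expect_equal(compute_auc(f, c(0, 30), scale = 1)$auc,
               gauss_integral(1, 15, 3, 0, 30), tolerance = 1e-8)
  expect_equal(compute_auc(f, c(0, 30), scale = 1)$auc, 7.5199,
               tolerance = 1e-4)
  set.seed(3)
  for (i in 1:20) {
    A <- runif(1, -2, 5); mu <- runif(1, -5, 35); s <- runif(1, 0.5, 10)
    fi <- mkfit(A, mu, s)
    expect_equal(compute_auc(fi, c(0, 30), scale = 1)$auc,
                 gauss_integral(A, mu, s, 0, 30), tolerance = 1e-8)
  }
  expect_equal(compute_auc(mkfit(0, 10, 3), scale = 1)$auc, 0)
})

test_that("group aggregation and fold changes follow their definitions", {
  s1 <- tibble::tibble(auc = c(2, 2, 2), genotype = "a")
  s2 <- tibble::tibble(auc = c(1, 1, 1), genotype = "b")
  g <- aggregate_group(rbind(s1, s2))
  expect_equal(g$sem, c(0, 0))
  expect_equal(fold_change(g[g$label == "a", ], g[g$label == "b", ]), 2)
  expect_equal(fold_change(g[g$label == "a", ], g[g$label == "a", ]), 1)
  expect_error(fold_change(g[g$label == "a", ], tibble::tibble(mean = 0)), "zero")

  sem_ref <- sd(c(1, 2, 3)) / sqrt(3)
  g3 <- aggregate_group(tibble::tibble(auc = c(1, 2, 3), genotype = "x"))
  expect_equal(g3$sem, sem_ref)
})

test_that("scaling both channels by k leaves the whole pipeline invariant", {
  sim <- generate_ratiometric_stack(small_scene(seed = 5, noise_model = "none"))
  ref <- quantify_stack(sim$stack)
  for (k in c(0.5, 3)) {
    st <- sim$stack
    st$donor <- st$donor * k
    st$acceptor <- st$acceptor * k
    sc <- quantify_stack(st)
    expect_equal(sc$auc, ref$auc, tolerance = 1e-9)
    expect_equal(sc$center_um, ref$center_um, tolerance = 1e-9)
  }
})

test_that("noise-free pipeline recovers the analytic AUC over a parameter grid", {
  grid <- expand.grid(amp = c(0.3, 1.0), center = c(6, 10), sigma = c(2, 4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sim <- generate_ratiometric_stack(small_scene(
      seed = 20 + i, noise_model = "none", activation_amplitude = g$amp,
      activation_center_um = g$center, activation_sigma_um = g$sigma))
    sc <- quantify_stack(sim$stack)
    expect_lt(abs(sc$auc / sim$truth$true_auc - 1), 0.05)
  }
})
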