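# Shared fixture builders. All fixtures are generated in code; the "small"
# scene keeps unit tests fast while the acceptance tests use the default
# full-resolution scene.

small_scene <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, xy_pixel_um = 0.25, margin_um = 1.5)
  do.call(scene_params, utils::modifyList(defaults, args))
}

# independent per-column projection oracle: naive triple loop
naive_density <- function(ratio, mask, z_step_um) {
  d <- dim(ratio)
  out <- matrix(NA_real_, d[1], d[2])
  support <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      tot <- 0
      cnt <- 0L
      for (k in seq_len(d[3])) {
        if (mask[i, j, k] && !is.na(ratio[i, j, k])) {
          tot <- tot + ratio[i, j, k]
          cnt <- cnt + 1L
        }
      }
      support[i, j] <- cnt
      if (cnt > 0L) out[i, j] <- tot / (cnt * z_step_um)
    }
  }
  list(values = out, support = support)
}

# independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to the two groups and count x > y pairs directly (no ranks)
brute_mwu_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pool), n1)
  u_all <- apply(combs, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# closed-form Gaussian-component integral over [lo, hi]
gauss_integral <- function(A, mu, sigma, lo, hi) {
  A * sigma * sqrt(2 * pi) * (pnorm((hi - mu) / sigma) - pnorm((lo - mu) / sigma))
}

# a tiny hand-built morphology: straight shaft along +x with explicit
# protrusions given as (attach_x, dx, dy, dz) rows
toy_morphology <- function(protrusions = NULL, shaft_length = 10) {
  shaft_x <- seq(0, shaft_length, by = 1)
  n <- length(shaft_x)
  nodes <- tibble::tibble(
    id = seq_len(n), parent = c(-1L, seq_len(n - 1L)),
    x_um = shaft_x, y_um = 0, z_um = 0,
    kind = c("soma", rep("shaft", n - 1L)), radius_um = 0.3
  )
  if (!is.null(protrusions)) {
    for (r in seq_len(nrow(protrusions))) {
      p <- protrusions[r, ]
      att <- which(nodes$kind == "shaft" & nodes$x_um == p$attach_x)[1]
      nodes <- rbind(nodes, tibble::tibble(
        id = max(nodes$id) + 1L, parent = nodes$id[att],
        x_um = p$attach_x + p$dx, y_um = p$dy, z_um = p$dz,
        kind = "protrusion", radius_um = 0.1
      ))
    }
  }
  frame <- midline_frame(cellbody_position_um = c(1e-6, 0))
  neuron_morphology(nodes, frame)
}
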