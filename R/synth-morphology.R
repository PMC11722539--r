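# Synthetic traced-morphology generator: a straight axon shaft perpendicular
# to the midline with planted straight filopodia of known path length and
# laterality, so counting can be checked against exact ground truth.

#' Generate a synthetic neuron morphology with planted filopodia
#'
#' Builds a rooted tree with a soma at the midline, a straight shaft along
#' the lateral (+x) axis, and `n_filopodia` straight two-segment protrusions
#' at known attachment positions. Each protrusion's planted path length is
#' its Euclidean length; its side is the sign of its lateral tilt.
#'
#' @param seed Integer seed.
#' @param n_filopodia Number of protrusions to plant (>= 0).
#' @param length_range_um Interval from which planted lengths are drawn
#'   uniformly (um), or ignored when `lengths_um` is given.
#' @param shaft_length_um Shaft length along the lateral axis (um).
#' @param side `"ipsi"`, `"contra"`, or `"mixed"` laterality of the planted
#'   protrusions (mixed: each side with probability 1/2).
#' @param lengths_um Optional explicit planted lengths (overrides
#'   `length_range_um`; length must equal `n_filopodia`).
#' @param attach_positions_um Optional explicit attachment distances from the
#'   midline (um); default uniform on `[1, shaft_length_um - 1]`.
#' @return A list with `morphology` (a [neuron_morphology()]) and `truth`
#'   (class `ground_truth`): planted lengths, sides, attachment positions,
#'   `planted_filopodia_count` = number of planted protrusions that are
#'   ipsilateral and strictly longer than 1 um.
#' @export
generate_morphology <- function(seed = 1L, n_filopodia = 6L,
                                length_range_um = c(0.4, 3),
                                shaft_length_um = 30,
                                side = c("mixed", "ipsi", "contra"),
                                lengths_um = NULL,
                                attach_positions_um = NULL) {
  side <- match.arg(side)
  seed <- check_count(seed, "seed")
  n_filopodia <- check_count(n_filopodia, "n_filopodia")
  check_number(shaft_length_um, "shaft_length_um", lower = 0, strict_lower = TRUE)
  set.seed(seed)

  explicit_lengths <- !is.null(lengths_um)
  if (!explicit_lengths) {
    check_window(length_range_um, "length_range_um", lo = 0)
    lengths_um <- runif(n_filopodia, length_range_um[1], length_range_um[2])
  } else if (length(lengths_um) != n_filopodia) {
    abort("`lengths_um` must have length `n_filopodia`.")
  }
  if (is.null(attach_positions_um)) {
    attach_positions_um <- runif(n_filopodia, 1, max(1, shaft_length_um - 1))
  } else if (length(attach_positions_um) != n_filopodia) {
    abort("`attach_positions_um` must have length `n_filopodia`.")
  }
  if (n_filopodia > 0 && shaft_length_um < max(attach_positions_um)) {
    abort("`shaft_length_um` is smaller than the maximum attachment position.")
  }
  sides <- switch(side,
    ipsi = rep("ipsi", n_filopodia),
    contra = rep("contra", n_filopodia),
    mixed = sample(c("ipsi", "contra"), n_filopodia, replace = TRUE)
  )

  # shaft: soma root at the midline, shaft nodes every 1 um
  shaft_x <- seq(0, shaft_length_um, by = 1)
  n_shaft <- length(shaft_x)
  nodes <- tibble(
    id = seq_len(n_shaft),
    parent = c(-1L, seq_len(n_shaft - 1L)),
    x_um = shaft_x, y_um = 0, z_um = 0,
    kind = c("soma", rep("shaft", n_shaft - 1L)),
    radius_um = c(2, rep(0.3, n_shaft - 1L))
  )

  planted <- tibble(length_um = numeric(), side = character(),
                    attachment_um = numeric())
  next_id <- n_shaft
  for (i in seq_len(n_filopodia)) {
    att_x <- attach_positions_um[i]
    att_row <- which(nodes$kind == "shaft")[
      which.min(abs(nodes$x_um[nodes$kind == "shaft"] - att_x))]
    att_id <- nodes$id[att_row]
    s <- if (sides[i] == "ipsi") 1 else -1
    if (explicit_lengths) {
      # axis-aligned placement keeps planted path lengths exact in floating
      # point, so strict length-threshold boundaries behave deterministically
      dir <- c(s, 0, 0)
    } else {
      dir <- c(s * runif(1, 0.2, 1), runif(1, -1, 1), runif(1, -0.3, 0.3))
      dir <- dir / sqrt(sum(dir^2))
    }
    L <- lengths_um[i]
    p0 <- c(nodes$x_um[att_row], nodes$y_um[att_row], nodes$z_um[att_row])
    mid <- p0 + dir * L / 2
    tip <- p0 + dir * L
    nodes <- dplyr::bind_rows(nodes, tibble(
      id = next_id + 1:2,
      parent = c(att_id, next_id + 1L),
      x_um = c(mid[1], tip[1]), y_um = c(mid[2], tip[2]),
      z_um = c(mid[3], tip[3]),
      kind = "protrusion", radius_um = 0.1
    ))
    next_id <- next_id + 2L
    planted <- dplyr::bind_rows(planted, tibble(
      length_um = L, side = sides[i], attachment_um = nodes$x_um[att_row]
    ))
  }

  frame <- midline_frame(cellbody_position_um = c(1e-6, 0),
                         midline_origin = c(0, 0),
                         midline_dir = c(0, 1), lateral_axis = c(1, 0))
  truth <- structure(
    list(planted = planted,
         planted_filopodia_lengths = planted$length_um,
         planted_filopodia_count = sum(planted$side == "ipsi" &
                                         planted$length_um > 1),
         params = list(seed = seed, n_filopodia = n_filopodia,
                       shaft_length_um = shaft_length_um, side = side)),
    class = "ground_truth"
  )
  list(morphology = neuron_morphology(nodes, frame), truth = truth)
}
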