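# Filopodia morphometry: decomposition, the strict >1 um ipsilateral filter,
# region restriction, and geometric invariances.

test_that("protrusion decomposition measures path lengths and sides", {
  shaft_only <- toy_morphology()
  expect_identical(nrow(extract_protrusions(shaft_only)), 0L)

  one <- toy_morphology(data.frame(attach_x = 4, dx = 0, dy = 2, dz = 0))
  pr <- extract_protrusions(one)
  expect_identical(nrow(pr), 1L)
  expect_equal(pr$path_length_um, 2)
  expect_equal(pr$attachment_distance_um, 4)

  # multi-node protrusions accumulate parent-child distances
  gen <- generate_morphology(seed = 5, n_filopodia = 9)
  pr2 <- extract_protrusions(gen$morphology)
  expect_equal(sort(pr2$path_length_um),
               sort(gen$truth$planted$length_um), tolerance = 1e-9)
  expect_identical(sort(pr2$side), sort(gen$truth$planted$side))
})

test_that("the strict more-than-1-um ipsilateral filter counts correctly", {
  tri <- generate_morphology(seed = 2, n_filopodia = 3, side = "ipsi",
                             lengths_um = c(0.5, 1.0, 2.0))
  expect_identical(count_filopodia(tri$morphology), 1L)

  # mirror every protrusion about its attachment: ipsilateral count drops to 0
  m <- tri$morphology
  flip <- m
  shaft_anchor_x <- function(id) {
    while (m$nodes$kind[m$nodes$id == id] == "protrusion") {
      id <- m$nodes$parent[m$nodes$id == id]
    }
    m$nodes$x_um[m$nodes$id == id]
  }
  prot <- which(flip$nodes$kind == "protrusion")
  anchors <- vapply(flip$nodes$id[prot], shaft_anchor_x, 1)
  flip$nodes$x_um[prot] <- 2 * anchors - flip$nodes$x_um[prot]
  expect_identical(count_filopodia(flip), 0L)
  expect_identical(count_filopodia(flip, side = "contra"), 1L)
})

test_that("counts are conserved and monotone", {
  gen <- generate_morphology(seed = 9, n_filopodia = 15,
                             length_range_um = c(0.2, 4))
  m <- gen$morphology
  expect_identical(count_filopodia(m, min_length_um = 0, side = "any"), 15L)

  thresholds <- c(0, 0.5, 1, 2, 3, 5)
  counts <- vapply(thresholds, function(t) count_filopodia(m, t, side = "any"),
                   1L)
  expect_true(all(diff(counts) <= 0L))

  full <- count_filopodia(m, side = "any")
  restricted <- count_filopodia(m, side = "any", region = c(5, 30))
  expect_lte(restricted, full)
})

test_that("planted ipsilateral counts are recovered exactly over a seed grid", {
  for (seed in 1:30) {
    gen <- generate_morphology(seed = seed,
                               n_filopodia = sample.int(15, 1),
                               length_range_um = c(0.2, 3))
    expect_identical(count_filopodia(gen$morphology),
                     as.integer(gen$truth$planted_filopodia_count))
  }
})

test_that("region restriction keeps the right subtree", {
  prs <- data.frame(attach_x = c(4, 10, 28), dx = c(0.5, 0.5, 0.5),
                    dy = c(2, 2, 2), dz = 0)
  m <- toy_morphology(prs, shaft_length = 30)

  r <- restrict_region(m, 5, 30)
  lat <- r$nodes$x_um[r$nodes$kind == "shaft"]
  expect_true(all(lat >= 5 & lat <= 30))
  # the protrusion attached at 4 um is gone, the others remain
  expect_identical(sum(r$nodes$kind == "protrusion"), 2L)
  expect_identical(count_filopodia(r, min_length_um = 0, side = "any"), 2L)

  # shaft entirely inside the region: node set unchanged
  r2 <- restrict_region(m, 0.5, 40)
  expect_identical(sort(r2$nodes$id),
                   sort(m$nodes$id[m$nodes$kind != "soma"]))

  expect_error(restrict_region(m, 40, 50), "No shaft node")
  expect_error(restrict_region(m, 10, 5), "lo_um")

  # brute-force node filter oracle on generated trees
  for (seed in 1:10) {
    gen <- generate_morphology(seed = seed, n_filopodia = 8)
    mm <- gen$morphology
    rr <- restrict_region(mm, 5, 30)
    keep_shaft <- mm$nodes$id[mm$nodes$kind == "shaft" &
                                mm$nodes$x_um >= 5 & mm$nodes$x_um <= 30]
    # a protrusion node is kept iff its shaft attachment ancestor is kept
    att_of <- function(id) {
      while (mm$nodes$kind[mm$nodes$id == id] == "protrusion") {
        id <- mm$nodes$parent[mm$nodes$id == id]
      }
      id
    }
    prot_ids <- mm$nodes$id[mm$nodes$kind == "protrusion"]
    keep_prot <- prot_ids[vapply(prot_ids, att_of, 0) %in% keep_shaft]
    expect_setequal(rr$nodes$id, c(keep_shaft, keep_prot))
  }
})

test_that("rigid motions of morphology and frame leave counts unchanged", {
  gen <- generate_morphology(seed = 13, n_filopodia = 10)
  m <- gen$morphology
  ref_count <- count_filopodia(m)
  ref_lengths <- sort(extract_protrusions(m)$path_length_um)

  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(12, -5)
  rot <- m
  xy <- as.matrix(m$nodes[, c("x_um", "y_um")]) %*% t(R)
  rot$nodes$x_um <- xy[, 1] + shift[1]
  rot$nodes$y_um <- xy[, 2] + shift[2]
  fr <- m$frame
  rot$frame <- midline_frame(
    cellbody_position_um = as.numeric(R %*% fr$cellbody_position_um + shift),
    midline_origin = as.numeric(R %*% fr$midline_origin + shift),
    midline_dir = as.numeric(R %*% fr$midline_dir),
    lateral_axis = as.numeric(R %*% fr$lateral_axis)
  )
  expect_identical(count_filopodia(rot), ref_count)
  expect_equal(sort(extract_protrusions(rot)$path_length_um), ref_lengths,
               tolerance = 1e-9)
})

test_that("malformed trees are rejected with informative errors", {
  frame <- midline_frame(cellbody_position_um = c(1, 0))
  nodes <- tibble::tibble(id = 1:2, parent = c(-1L, 1L), x_um = c(0, 1),
                          y_um = 0, z_um = 0, kind = c("soma", "shaft"))
  expect_s3_class(neuron_morphology(nodes, frame), "neuron_morphology")

  dup <- nodes; dup$id <- c(1L, 1L)
  expect_error(neuron_morphology(dup, frame), "Duplicate")

  orphan <- nodes; orphan$parent <- c(-1L, 99L)
  expect_error(neuron_morphology(orphan, frame), "Orphaned")

  two_roots <- nodes; two_roots$parent <- c(-1L, -1L)
  expect_error(neuron_morphology(two_roots, frame), "exactly one root")

  cyc <- tibble::tibble(id = 1:3, parent = c(-1L, 3L, 2L), x_um = 0:2,
                        y_um = 0, z_um = 0,
                        kind = c("soma", "shaft", "shaft"))
  expect_error(neuron_morphology(cyc, frame), "Cycle")
})
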