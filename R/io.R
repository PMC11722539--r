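# File formats: two-channel stacks as interleaved multi-page TIFF with a
# JSON sidecar (voxel sizes + midline frame), morphologies as SWC, frames as
# JSON. All writers and readers round-trip losslessly for integer image data
# and to 1e-6 um for SWC coordinates.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a ratiometric stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are interleaved donor-then-acceptor per z-plane (an even page
#' count). Voxel sizes go into the TIFF resolution tags and, together with
#' the channel order and optional midline frame, into a JSON sidecar at
#' `<path>.json`. Integer-valued data in `[0, 65535]` are stored as 16-bit
#' unsigned; anything else as 32-bit float.
#'
#' @param stack A [ratiometric_stack()].
#' @param path Output TIFF path.
#' @param frame Optional [midline_frame()] (default: the stack's own).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, frame = NULL) {
  stopifnot(inherits(stack, "ratiometric_stack"))
  if (is.null(frame)) frame <- stack$frame
  nz <- dim(stack$donor)[3]
  pages <- vector("list", 2L * nz)
  for (k in seq_len(nz)) {
    pages[[2L * k - 1L]] <- stack$donor[, , k]
    pages[[2L * k]] <- stack$acceptor[, , k]
  }
  all_vals <- c(stack$donor, stack$acceptor)
  dtype <- if (all(all_vals == round(all_vals)) && max(all_vals) <= 65535) {
    "uint16"
  } else {
    "float32"
  }
  nf_write_tiff(path, pages, dtype = dtype, pixel_um = stack$xy_pixel_um)
  sidecar <- list(
    xy_pixel_um = stack$xy_pixel_um,
    z_step_um = stack$z_step_um,
    n_z = nz,
    channel_order = c("donor", "acceptor"),
    dtype = dtype,
    frame = if (!is.null(frame)) frame_to_list(frame) else NULL
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @return `read_stack()`: a [ratiometric_stack()] with the sidecar's frame
#'   attached.
#' @export
read_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("Missing JSON sidecar for %s: expected voxel sizes and frame at %s.",
                  path, sp))
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  tif <- nf_read_tiff(path)
  n_pages <- length(tif$pages)
  if (n_pages %% 2L != 0L) {
    abort(sprintf("Malformed stack TIFF %s: odd page count %d (channels must be interleaved).",
                  path, n_pages))
  }
  nz <- n_pages %/% 2L
  d <- dim(tif$pages[[1]])
  donor <- array(0, c(d, nz))
  acceptor <- array(0, c(d, nz))
  for (k in seq_len(nz)) {
    donor[, , k] <- tif$pages[[2L * k - 1L]]
    acceptor[, , k] <- tif$pages[[2L * k]]
  }
  frame <- if (!is.null(meta$frame)) frame_from_list(meta$frame) else NULL
  ratiometric_stack(donor, acceptor, meta$xy_pixel_um, meta$z_step_um, frame)
}

#' Write / read a midline frame as JSON
#'
#' @param frame A [midline_frame()].
#' @param path JSON path.
#' @return `path` (write) or a [midline_frame()] (read).
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "midline_frame"))
  jsonlite::write_json(frame_to_list(frame), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  frame_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

SWC_TYPE_FROM_KIND <- c(soma = 1L, shaft = 2L, protrusion = 7L)

#' Write / read a neuron morphology as SWC
#'
#' Standard whitespace-delimited SWC (`id type x y z radius parent`, `#`
#' comments, parent `-1` for the root) with coordinates in microns. Type
#' codes: 1 = soma, 2 = shaft/axon, 7 = protrusion.
#'
#' @param m A [neuron_morphology()].
#' @param path SWC path.
#' @param frame Optional [midline_frame()] written to `<path>.json`; by
#'   default the morphology's own frame is written.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path, frame = m$frame) {
  stopifnot(inherits(m, "neuron_morphology"))
  nd <- m$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nd$id, SWC_TYPE_FROM_KIND[nd$kind], nd$x_um, nd$y_um,
                   nd$z_um, nd$radius_um, nd$parent)
  writeLines(c("# SWC morphology (um); types: 1 soma, 2 shaft, 7 protrusion",
               lines), path)
  if (!is.null(frame)) write_frame(frame, sidecar_path(path))
  invisible(path)
}

#' @rdname write_swc
#' @param default_frame Frame to use when no `<path>.json` sidecar exists.
#' @return `read_swc()`: a [neuron_morphology()].
#' @export
read_swc <- function(path, default_frame = NULL) {
  txt <- readLines(path)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (length(txt) == 0L) abort(sprintf("SWC file %s has no data lines.", path))
  fields <- strsplit(txt, "\\s+")
  if (any(vapply(fields, length, 1L) != 7L)) {
    abort(sprintf("SWC file %s: every data line must have 7 fields.", path))
  }
  mat <- do.call(rbind, lapply(fields, as.numeric))
  type <- as.integer(mat[, 2])
  kind_map <- c(`1` = "soma", `2` = "shaft", `7` = "protrusion")
  unknown <- setdiff(unique(type), c(1L, 2L, 7L))
  if (length(unknown) > 0L) {
    abort(sprintf("SWC file %s: unsupported type code(s) %s (expected 1, 2, 7).",
                  path, paste(unknown, collapse = ", ")))
  }
  nodes <- tibble(
    id = as.integer(mat[, 1]), parent = as.integer(mat[, 7]),
    x_um = mat[, 3], y_um = mat[, 4], z_um = mat[, 5],
    kind = unname(kind_map[as.character(type)]), radius_um = mat[, 6]
  )
  sp <- sidecar_path(path)
  frame <- if (file.exists(sp)) {
    read_frame(sp)
  } else if (!is.null(default_frame)) {
    default_frame
  } else {
    midline_frame(cellbody_position_um = c(1e-6, 0))
  }
  neuron_morphology(nodes, frame)
}
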