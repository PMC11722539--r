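# Minimal baseline TIFF support, written against the TIFF 6.0 baseline:
# uncompressed single-sample grayscale multi-page files. A page is an
# nx x ny matrix (column index = image row). The writer emits little-endian
# uint8/16/32 or float32 with one strip per page; the reader additionally
# accepts big-endian files and multi-strip layouts. No R TIFF package is
# available in this stack, hence this self-contained implementation; tests
# cross-check it against an independent reader.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

nf_write_tiff <- function(path, pages, dtype = c("uint16", "float32",
                                                 "uint8", "uint32"),
                          pixel_um = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(is.list(pages), length(pages) > 0L)
  dims <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), dims), TRUE))) {
    abort("All TIFF pages must share the same dimensions.")
  }
  w <- dims[1]; h <- dims[2]
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, uint32 = 32L, float32 = 32L)
  fmt <- if (dtype == "float32") 3L else 1L
  bpp <- bits / 8L
  n_pages <- length(pages)
  page_bytes <- w * h * bpp

  # resolution: pixels per centimeter as a rational
  if (is.null(pixel_um)) pixel_um <- 1
  res_num <- round(1e6 / pixel_um)  # (1e4 um/cm) / pixel_um * 100
  res_den <- 100

  rat_off <- 8L
  data_off <- rat_off + 8L
  ifd0_off <- data_off + n_pages * page_bytes
  n_tags <- 13L
  ifd_size <- 2L + n_tags * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  writeBin(as.integer(c(res_num, res_den)), con, size = 4, endian = "little")

  for (p in pages) {
    v <- as.numeric(p)
    if (dtype == "float32") {
      writeBin(v, con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = bpp, endian = "little")
    }
  }

  write_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (k in seq_len(n_pages)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    strip_off <- data_off + (k - 1L) * page_bytes
    write_entry(256L, 4L, 1L, w)                    # ImageWidth
    write_entry(257L, 4L, 1L, h)                    # ImageLength
    write_entry(258L, 3L, 1L, bits)                 # BitsPerSample
    write_entry(259L, 3L, 1L, 1L)                   # Compression: none
    write_entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    write_entry(273L, 4L, 1L, strip_off)            # StripOffsets
    write_entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    write_entry(278L, 4L, 1L, h)                    # RowsPerStrip
    write_entry(279L, 4L, 1L, page_bytes)           # StripByteCounts
    write_entry(282L, 5L, 1L, rat_off)              # XResolution
    write_entry(283L, 5L, 1L, rat_off)              # YResolution
    write_entry(296L, 3L, 1L, 3L)                   # ResolutionUnit: cm
    write_entry(339L, 3L, 1L, fmt)                  # SampleFormat
    next_off <- if (k < n_pages) ifd0_off + k * ifd_size else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

nf_read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) abort(sprintf("Malformed TIFF: %s is too short.", path))
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   abort(sprintf("Malformed TIFF %s: bad byte-order mark.", path)))
  rd_int <- function(off, size, n = 1L, signed = FALSE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed || size == 4L, endian = endian)
  }
  if (rd_int(2L, 2L) != 42L) abort(sprintf("Malformed TIFF %s: bad magic.", path))

  pages <- list()
  pixel_um <- NA_real_
  ifd_off <- rd_int(4L, 4L)
  while (ifd_off != 0L) {
    n_tags <- rd_int(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_int(e, 2L)
      type <- rd_int(e + 2L, 2L)
      count <- rd_int(e + 4L, 4L)
      tsize <- TIFF_TYPE_SIZES[type]
      inline <- tsize * count <= 4L
      val_off <- if (inline) e + 8L else rd_int(e + 8L, 4L)
      value <- if (type %in% c(3L, 4L, 1L)) {
        rd_int(val_off, tsize, count)
      } else if (type == 5L) {  # RATIONAL
        nums <- rd_int(val_off, 4L, 2L * count)
        nums[seq(1, 2 * count, 2)] / nums[seq(2, 2 * count, 2)]
      } else {
        NULL
      }
      tags[[as.character(tag)]] <- value
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) {
          abort(sprintf("Malformed TIFF %s: missing required tag %d.", path, tag))
        }
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 1L)
    if (need(259L, 1L) != 1L) {
      abort(sprintf("Unsupported TIFF %s: only uncompressed data is handled.", path))
    }
    if (need(277L, 1L) != 1L) {
      abort(sprintf("Unsupported TIFF %s: only single-sample grayscale is handled.", path))
    }
    fmt <- need(339L, 1L)
    offs <- need(273L)
    counts <- need(279L)
    xres <- tags[["282"]]
    if (!is.null(xres) && is.finite(xres[1]) && xres[1] > 0 &&
        isTRUE(need(296L, 2L) == 3L)) {
      pixel_um <- 1e4 / xres[1]
    }
    bpp <- bits / 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nvals <- counts[s] / bpp
      seg <- raw[(offs[s] + 1L):(offs[s] + counts[s])]
      vals <- c(vals, if (fmt == 3L) {
        if (bits != 32L) abort(sprintf("Unsupported TIFF %s: float depth %d.", path, bits))
        readBin(seg, "double", n = nvals, size = 4L, endian = endian)
      } else {
        readBin(seg, "integer", n = nvals, size = bpp,
                signed = bpp == 4L, endian = endian)
      })
    }
    if (length(vals) != w * h) {
      abort(sprintf("Malformed TIFF %s: strip data does not match page size.", path))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = w, ncol = h)
    ifd_off <- rd_int(ifd_off + 2L + n_tags * 12L, 4L)
  }
  if (length(pages) == 0L) abort(sprintf("Malformed TIFF %s: no pages.", path))
  list(pages = pages, pixel_um = pixel_um)
}
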