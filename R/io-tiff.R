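# Minimal baseline TIFF codec for single-plane grayscale images
# (uncompressed, little-endian, 8- or 16-bit). Implemented here because the
# pipeline's imaging interface requires TIFF and no TIFF package is part of
# the supported dependency set; covers exactly the subset this package
# writes plus plain single-strip/multi-strip grayscale files.

#' Write a grayscale image as an uncompressed TIFF
#'
#' @param image numeric matrix; values are rounded and clamped to the
#'   integer range of `bits`.
#' @param path output path.
#' @param bits 8 or 16 bits per sample (default 16).
#' @return the path, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16) {
  if (!is.matrix(image) || !is.numeric(image))
    abort("`image` must be a numeric matrix", "synq_contract_error")
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16", "synq_parameter_error")
  h <- nrow(image); w <- ncol(image)
  maxval <- 2^bits - 1
  px <- as.integer(pmin(pmax(round(image), 0), maxval))
  bytes_pp <- bits %/% 8
  data_bytes <- h * w * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42)
  wr4(8 + data_bytes)                   # IFD sits after the pixel data
  # pixel data, row-major
  writeBin(as.integer(t(matrix(px, h, w))), con, size = bytes_pp,
           endian = "little")
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0) } else wr4(value)  # 3=SHORT, 4=LONG
  }
  wr2(9L)                               # entry count
  entry(256, 4, 1, w)                   # ImageWidth
  entry(257, 4, 1, h)                   # ImageLength
  entry(258, 3, 1, bits)                # BitsPerSample
  entry(259, 3, 1, 1)                   # Compression = none
  entry(262, 3, 1, 1)                   # Photometric = BlackIsZero
  entry(273, 4, 1, 8)                   # StripOffsets
  entry(277, 3, 1, 1)                   # SamplesPerPixel
  entry(278, 4, 1, h)                   # RowsPerStrip
  entry(279, 4, 1, data_bytes)          # StripByteCounts
  wr4(0)                                # no next IFD
  invisible(path)
}

#' Read a grayscale TIFF image
#'
#' Supports uncompressed single-sample (grayscale) baseline TIFF, 8 or 16
#' bits, either byte order, one or more strips.
#'
#' @param path file path.
#' @return numeric matrix (rows = image height).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path))
    abort(sprintf("TIFF file not found: %s", path), "synq_io_error")
  raw_all <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw_all[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    abort("not a TIFF file", "synq_io_error")
  rd <- function(offset, size, n = 1, signed = FALSE) {
    readBin(raw_all[(offset + 1):(offset + size * n)], "integer",
            n = n, size = size, signed = signed || size == 4, endian = endian)
  }
  if (rd(2, 2) != 42) abort("not a TIFF file", "synq_io_error")
  ifd <- rd(4, 4)
  n_entries <- rd(ifd, 2)
  tags <- list()
  type_size <- c(1, 1, 2, 4, 8)
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- rd(off, 2); type <- rd(off + 2, 2); count <- rd(off + 4, 4)
    sz <- type_size[type]
    vals <- if (sz * count <= 4) rd(off + 8, sz, count)
            else rd(rd(off + 8, 4), sz, count)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) abort(sprintf("TIFF tag %d missing", tag),
                                  "synq_io_error")
      default
    } else v
  }
  w <- need(256); h <- need(257); bits <- need(258, 8)
  if (length(bits) != 1) abort("only single-sample grayscale TIFF supported",
                               "synq_io_error")
  if (need(259, 1) != 1) abort("only uncompressed TIFF supported", "synq_io_error")
  if (need(277, 1) != 1) abort("only single-sample grayscale TIFF supported",
                               "synq_io_error")
  offs <- need(273); counts <- need(279, h * w * bits / 8)
  bpp <- bits %/% 8
  px <- unlist(lapply(seq_along(offs), function(i) {
    rd(offs[i], bpp, counts[i] %/% bpp)
  }))
  if (length(px) != h * w) abort("corrupt TIFF pixel data", "synq_io_error")
  matrix(as.numeric(px), nrow = h, ncol = w, byrow = TRUE)
}
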