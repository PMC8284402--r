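# Minimal baseline TIFF reader/writer, 32-bit float, single sample,
# uncompressed, little-endian. This covers the package's own dataset dialect
# (and reads simple uncompressed grayscale TIFFs of other provenance); it is
# hand-rolled because no TIFF package is available in the target library.

.tiff_tags <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                SamplesPerPixel = 277L, RowsPerStrip = 278L,
                StripByteCounts = 279L, SampleFormat = 339L)

#' Write a matrix as a 32-bit float TIFF
#'
#' Baseline, uncompressed, single-strip, little-endian grayscale TIFF with
#' IEEE floating-point samples. Values are stored in float32 precision.
#'
#' @param x Numeric matrix (row = y, column = x).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_float <- function(x, path) {
  x <- as.matrix(x)
  ny <- nrow(x); nx <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2,
                             endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4,
                             endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(8L)                       # IFD starts right after the header
  entries <- list(
    c(256L, 4L, 1L, nx),       # ImageWidth
    c(257L, 4L, 1L, ny),       # ImageLength
    c(258L, 3L, 1L, 32L),      # BitsPerSample
    c(259L, 3L, 1L, 1L),       # Compression: none
    c(262L, 3L, 1L, 1L),       # Photometric: BlackIsZero
    c(273L, 4L, 1L, NA),       # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),       # SamplesPerPixel
    c(278L, 4L, 1L, ny),       # RowsPerStrip
    c(279L, 4L, 1L, 4L * nx * ny),  # StripByteCounts
    c(339L, 3L, 1L, 3L)        # SampleFormat: IEEE float
  )
  n_entries <- length(entries)
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  w2(n_entries)
  for (e in entries) {
    w2(e[1]); w2(e[2]); w4(e[3])
    val <- if (e[1] == 273L) data_offset else e[4]
    if (e[2] == 3L) { w2(val); w2(0L) } else w4(val)
  }
  w4(0L)                       # no next IFD
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a grayscale TIFF into a matrix
#'
#' Supports the subset written by [write_tiff_float] plus uncompressed
#' 8/16-bit unsigned and 32/64-bit float grayscale baseline TIFFs (single
#' image, strip-based, either byte order).
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little"
            else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  ru <- function(off, size, n = 1)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, signed = size > 2, endian = endian)
  if (ru(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- ru(4, 4)
  n_entries <- ru(ifd, 2)
  tags <- list()
  for (i in seq_len(n_entries) - 1L) {
    off <- ifd + 2 + i * 12
    tag <- ru(off, 2); type <- ru(off + 2, 2); count <- ru(off + 4, 4)
    type_size <- c(1L, 1L, 2L, 4L, 8L)[min(type, 5L)]
    inline <- type_size * count <= 4
    voff <- if (inline) off + 8 else ru(off + 8, 4)
    vals <- if (type == 3L) ru(voff, 2, count)
            else if (type %in% c(1L, 4L)) ru(voff, if (type == 1L) 1 else 4,
                                             count)
            else NULL
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing")
      default
    } else v
  }
  nx <- need(256L); ny <- need(257L)
  bits <- need(258L, 1L)[1]
  if (need(259L, 1L)[1] != 1L) stop("compressed TIFF not supported")
  fmt <- need(339L, 1L)[1]
  offsets <- need(273L)
  counts <- need(279L, rep((bits / 8) * nx * ny, length(offsets)))
  rows_per_strip <- need(278L, ny)[1]
  vals <- numeric(0)
  for (k in seq_along(offsets)) {
    seg <- raw_all[(offsets[k] + 1):(offsets[k] + counts[k])]
    n <- counts[k] / (bits / 8)
    v <- if (fmt == 3L) {
      readBin(seg, "double", n = n, size = bits / 8, endian = endian)
    } else {
      readBin(seg, "integer", n = n, size = bits / 8,
              signed = bits > 16, endian = endian)
    }
    vals <- c(vals, v)
  }
  matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
}
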