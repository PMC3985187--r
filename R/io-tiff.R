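# Minimal baseline TIFF codec for single-plane grayscale images (8- or
# 16-bit, uncompressed, single strip, little-endian). No TIFF package is
# available in the supported R stack, so the few tags needed are read and
# written directly.

tiff_tag <- function(id, type, count, value) list(id = id, type = type,
                                                  count = count, value = value)

#' Write a grayscale matrix as an uncompressed TIFF
#'
#' @param image numeric matrix (row = y); values are clamped to the integer
#'   range of `bit_depth`.
#' @param path output file.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(image, path, bit_depth = 8L) {
  stopifnot(is.matrix(image), bit_depth %in% c(8L, 16L))
  h <- nrow(image); w <- ncol(image)
  maxv <- 2^bit_depth - 1
  px <- round(pmin(pmax(t(image), 0), maxv)) # row-major scanlines
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(0x49L, 0x49L, 0x2aL, 0x00L), con, size = 1L) # "II", 42
  data_offset <- 8L
  nbytes <- w * h * (bit_depth / 8L)
  ifd_offset <- data_offset + nbytes
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = "little")
  writeBin(as.integer(px), con, size = bit_depth / 8L, endian = "little")
  tags <- list(
    tiff_tag(256L, 3L, 1L, w),            # ImageWidth
    tiff_tag(257L, 3L, 1L, h),            # ImageLength
    tiff_tag(258L, 3L, 1L, bit_depth),    # BitsPerSample
    tiff_tag(259L, 3L, 1L, 1L),           # Compression = none
    tiff_tag(262L, 3L, 1L, 1L),           # Photometric = BlackIsZero
    tiff_tag(273L, 4L, 1L, data_offset),  # StripOffsets
    tiff_tag(277L, 3L, 1L, 1L),           # SamplesPerPixel
    tiff_tag(278L, 3L, 1L, h),            # RowsPerStrip
    tiff_tag(279L, 4L, 1L, nbytes))       # StripByteCounts
  writeBin(as.integer(length(tags)), con, size = 2L, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg$id), con, size = 2L, endian = "little")
    writeBin(as.integer(tg$type), con, size = 2L, endian = "little")
    writeBin(as.integer(tg$count), con, size = 4L, endian = "little")
    writeBin(as.integer(tg$value), con, size = 4L, endian = "little")
  }
  writeBin(0L, con, size = 4L, endian = "little") # no next IFD
  invisible(path)
}

read_u16 <- function(raw, off) as.integer(raw[off + 1L]) +
  256L * as.integer(raw[off + 2L])
read_u32 <- function(raw, off) as.integer(raw[off + 1L]) +
  256 * as.integer(raw[off + 2L]) + 65536 * as.integer(raw[off + 3L]) +
  16777216 * as.integer(raw[off + 4L])

#' Read an uncompressed grayscale TIFF
#'
#' Supports the subset written by [write_tiff_gray()]: little-endian,
#' single plane, 8/16-bit, compression = none, any strip layout.
#'
#' @param path TIFF file.
#' @return numeric matrix (row = y).
#' @export
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(raw[1L] == as.raw(0x49) && raw[2L] == as.raw(0x49)))
    stop("only little-endian TIFF is supported (byte offset 0)")
  if (read_u16(raw, 2L) != 42L) stop("not a TIFF file (byte offset 2)")
  ifd <- read_u32(raw, 4L)
  ntag <- read_u16(raw, ifd)
  tags <- list()
  for (k in seq_len(ntag)) {
    base <- ifd + 2L + 12L * (k - 1L)
    id <- read_u16(raw, base)
    type <- read_u16(raw, base + 2L)
    count <- read_u32(raw, base + 4L)
    val <- if (type == 3L && count == 1L) read_u16(raw, base + 8L)
    else read_u32(raw, base + 8L)
    tags[[as.character(id)]] <- list(type = type, count = count, value = val,
                                     base = base)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stop("missing TIFF tag ", id)
    t
  }
  w <- need(256L)$value; h <- need(257L)$value
  bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]]$value
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]$value
  if (comp != 1L) stop("compressed TIFF is not supported")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale is supported")
  so <- need(273L); sc <- need(279L)
  n_strips <- so$count
  offsets <- if (n_strips == 1L) so$value else
    vapply(seq_len(n_strips) - 1L,
           function(i) read_u32(raw, so$value + 4L * i), 0L)
  counts <- if (n_strips == 1L) sc$value else
    vapply(seq_len(n_strips) - 1L,
           function(i) read_u32(raw, sc$value + 4L * i), 0L)
  bytes <- unlist(lapply(seq_len(n_strips), function(i)
    raw[(offsets[i] + 1L):(offsets[i] + counts[i])]))
  vals <- if (bits == 8L) as.integer(bytes) else {
    ev <- as.integer(bytes[seq(1L, length(bytes), 2L)])
    od <- as.integer(bytes[seq(2L, length(bytes), 2L)])
    ev + 256L * od
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
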