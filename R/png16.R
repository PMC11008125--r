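#' Write a grayscale image as 16-bit PNG
#'
#' Writes a numeric matrix in `[0, 1]` as a single-channel 16-bit PNG, the
#' recording format of the sickling assay (installed R packages write 8-bit
#' PNG only, so the encoder is built in: IHDR/IDAT/IEND chunks, zlib stream
#' via [memCompress()], CRC-32 in compiled code).
#'
#' The matrix uses the package's image convention: `img[x + 1, y + 1]` is the
#' pixel at 0-based coordinates (x right, y down), i.e. `nrow(img)` is the
#' image width.
#'
#' @param img numeric matrix with values in `[0, 1]`; values outside are
#'   clipped.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_gray_png()]
#' @export
write_png16 <- function(img, path) {
  if (!is.matrix(img) || !is.numeric(img)) stopf("img must be a numeric matrix")
  w <- nrow(img); h <- ncol(img)
  u <- round(clamp(img, 0, 1) * 65535)
  # scanlines are rows of the displayed image (fixed y), big-endian 16-bit,
  # each preceded by filter byte 0
  hi <- as.raw(u %/% 256L); lo <- as.raw(u %% 256L)
  sl <- matrix(raw(1), nrow = 1L + 2L * w, ncol = h)
  sl[seq(2L, 2L * w, by = 2L), ] <- hi
  sl[seq(3L, 2L * w + 1L, by = 2L), ] <- lo
  idat <- memCompress(as.vector(sl), type = "gzip")
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  write_chunk(con, "IHDR", ihdr)
  write_chunk(con, "IDAT", idat)
  write_chunk(con, "IEND", raw(0))
  invisible(path)
}

int_be <- function(x) {
  x <- as.double(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

write_chunk <- function(con, type, data) {
  body <- c(charToRaw(type), data)
  crc <- as.raw(crc32_bytes(body))
  writeBin(int_be(length(data)), con)
  writeBin(body, con)
  writeBin(crc, con)
}

#' Read a grayscale PNG (8- or 16-bit)
#'
#' @param path PNG file path.
#' @return numeric matrix in `[0, 1]`, dimensions (width, height); pixel
#'   `[x + 1, y + 1]` is at 0-based image coordinates (x, y).
#' @export
read_gray_png <- function(path) {
  z <- png::readPNG(path)
  if (length(dim(z)) == 3L) z <- z[, , 1L]
  t(z)
}
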