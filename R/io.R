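#' One imaging round's co-acquired channels
#'
#' @param round_id integer round index
#' @param channels named list of 2D numeric matrices; must include the
#'   persistent fiducial channels `nuclear` and `actin` for registration,
#'   plus the round's probe channels named by marker
#' @param pixel_size optional pixel size in microns
#' @return a `round_stack` object
#' @export
round_stack <- function(round_id, channels, pixel_size = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop2("all channels of a round must share the same shape")
  structure(list(round_id = as.integer(round_id), channels = channels,
                 pixel_size = pixel_size),
            class = "round_stack")
}

#' @export
print.round_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<round_stack> round %d: %dx%d px, channels: %s\n",
              x$round_id, d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF: uncompressed 16-bit grayscale, little-endian, single
# image per file. No TIFF package ships with the supported R environment, and
# only this one fixed layout is ever produced or consumed, so the format is
# implemented directly rather than pulled in as a dependency.

#' Read and write 16-bit grayscale TIFF images
#'
#' `write_tiff()` rounds intensities to integers, clamps to `[0, 65535]` and
#' writes an uncompressed little-endian baseline TIFF. `read_tiff()` reads
#' files of exactly that layout (single image, one sample per pixel, 16-bit
#' unsigned, any strip arrangement) back into a numeric matrix. Writing then
#' reading reproduces the rounded array exactly.
#'
#' @param img numeric matrix (rows x cols)
#' @param path file path
#' @return `read_tiff()`: a numeric matrix
#' @export
write_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  px <- as.integer(pmin(pmax(round(img), 0), 65535))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)  # header, IFD at offset 8
  tags <- list(  # tag, type (3 = SHORT, 4 = LONG), value
    c(256L, 4L, nc), c(257L, 4L, nr), c(258L, 3L, 16L), c(259L, 3L, 1L),
    c(262L, 3L, 1L), c(273L, 4L, 0L),  # strip offset patched below
    c(277L, 3L, 1L), c(278L, 4L, nr), c(279L, 4L, 2L * nr * nc),
    c(339L, 3L, 1L))
  data_offset <- 8L + 2L + 12L * length(tags) + 4L
  w2(length(tags))
  for (tg in tags) {
    w2(tg[1]); w2(tg[2]); w4(1L)
    val <- if (tg[1] == 273L) data_offset else tg[3]
    if (tg[2] == 3L) { w2(val); w2(0L) } else w4(val)
  }
  w4(0L)  # no next IFD
  # pixel data, row-major (TIFF scanlines)
  writeBin(as.integer(t(matrix(px, nr, nc))), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop2("TIFF file not found: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop2("not a TIFF file: %s", path)
  little <- rawToChar(raw[1:2]) == "II"
  if (!little && rawToChar(raw[1:2]) != "MM") stop2("not a TIFF file: %s", path)
  endian <- if (little) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               endian = endian, signed = FALSE)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  ifd <- u32(4)
  n_tags <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2 + 12 * (i - 1)
    tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
    vals <- if (type == 3L && count <= 2L) {
      vapply(seq_len(count), function(k) u16(base + 8 + 2 * (k - 1)), 0L)
    } else if (type == 4L && count == 1L) {
      u32(base + 8)
    } else {
      off <- u32(base + 8)
      sz <- if (type == 3L) 2L else 4L
      rd <- if (type == 3L) u16 else u32
      vapply(seq_len(count), function(k) rd(off + sz * (k - 1)), 0L)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop2("TIFF missing required tag %d: %s", tag, path)
      default
    } else v
  }
  nc <- need(256); nr <- need(257)
  if (!all(need(258, 16L) == 16L)) stop2("only 16-bit TIFF supported: %s", path)
  if (need(259, 1L) != 1L) stop2("only uncompressed TIFF supported: %s", path)
  if (need(277, 1L) != 1L) stop2("only single-sample TIFF supported: %s", path)
  offs <- need(273); counts <- need(279, 2L * nr * nc)
  pix <- integer(0)
  for (k in seq_along(offs)) {
    seg <- raw[(offs[k] + 1):(offs[k] + counts[k])]
    pix <- c(pix, readBin(seg, "integer", n = counts[k] / 2, size = 2,
                          endian = endian, signed = FALSE))
  }
  if (length(pix) != nr * nc) stop2("TIFF pixel count mismatch: %s", path)
  matrix(pix, nr, nc, byrow = TRUE) + 0  # numeric matrix, scanline order
}
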