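#' Load a raster image as a grayscale image
#'
#' Reads a PNG, TIFF or binary PGM (P5) raster and returns a [gray_image]
#' on the canonical \[0, 1\] scale. Integer formats are rescaled by their
#' maximum representable value (255 for 8-bit, 65535 for 16-bit). Color
#' inputs are reduced to a single channel by `channel`:
#'
#' * `"luminance"` (default) — Rec. 601 weighted sum
#'   `0.299 R + 0.587 G + 0.114 B`.
#' * `"hue"` — the H channel of the HSV colorspace, scaled to \[0, 1\] and
#'   treated as a plain linear channel (no circular arithmetic; see the
#'   methods vignette for the wrap-around caveat).
#' * a positive integer — that channel of the stored raster, verbatim.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.pgm` file.
#' @param channel `"luminance"`, `"hue"`, or a 1-based channel index.
#' @return A [gray_image].
#' @seealso [save_image()]
#' @export
load_image <- function(path, channel = "luminance") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, " (expected png, tiff or pgm)",
         call. = FALSE)
  )
  gray_image(collapse_channels(arr, channel))
}

collapse_channels <- function(arr, channel) {
  if (length(dim(arr)) == 2L || is.null(dim(arr))) {
    return(as.matrix(arr))
  }
  nc <- dim(arr)[3L]
  if (is.numeric(channel)) {
    channel <- as.integer(channel)
    if (channel < 1L || channel > nc) {
      stop("channel index ", channel, " out of range for a ", nc,
           "-channel image", call. = FALSE)
    }
    return(arr[, , channel])
  }
  channel <- match.arg(channel, c("luminance", "hue"))
  if (nc < 3L) {
    # grayscale(+alpha) stored as multi-channel: first channel is intensity
    return(arr[, , 1L])
  }
  r <- arr[, , 1L]; g <- arr[, , 2L]; b <- arr[, , 3L]
  if (channel == "luminance") {
    0.299 * r + 0.587 * g + 0.114 * b
  } else {
    h <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)[1L, ]
    matrix(h, nrow(r), ncol(r))
  }
}

#' Save a grayscale image as an 8-bit raster
#'
#' Writes `round(255 * v)` per pixel, so a save/load round trip reproduces
#' the image to within 1/255 per pixel. The format follows the file
#' extension: PNG, TIFF, or binary PGM (P5).
#'
#' @param img A [gray_image] (or matrix coercible to one).
#' @param path Output path ending in `.png`, `.tif`/`.tiff` or `.pgm`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  q <- round(255 * img_values(img)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q, path),
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    pgm = write_pgm(q, path),
    stop("unsupported image format: .", ext, " (expected png, tiff or pgm)",
         call. = FALSE)
  )
  invisible(path)
}

# ---- binary PGM (P5) ----------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pgm_token(con)
  if (!identical(magic, "P5")) {
    stop("only binary (P5) PGM files are supported, got magic '", magic, "'",
         call. = FALSE)
  }
  w <- as.integer(read_pgm_token(con))
  h <- as.integer(read_pgm_token(con))
  maxval <- as.integer(read_pgm_token(con))
  if (any(is.na(c(w, h, maxval))) || w < 1L || h < 1L || maxval < 1L) {
    stop("malformed PGM header", call. = FALSE)
  }
  n <- w * h
  if (maxval < 256L) {
    v <- as.integer(readBin(con, "raw", n))
  } else {
    v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(v) < n) stop("truncated PGM pixel data", call. = FALSE)
  matrix(v / maxval, h, w, byrow = TRUE)
}

# whitespace-delimited header token, skipping '#' comments
read_pgm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste0(tok, collapse = "")
}

write_pgm <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  bytes <- as.raw(round(255 * as.vector(t(m))))
  writeBin(bytes, con)
  invisible(path)
}
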