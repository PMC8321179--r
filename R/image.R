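#' Colour image representation
#'
#' Images are plain numeric arrays of dimension `H x W x 3` holding
#' sRGB-encoded intensities in `[0, 1]`.  All pipeline operations work
#' directly on the encoded values; no linearisation is performed, since the
#' observer model and the recolouring basis are defined on encoded RGB.
#'
#' `as_colour_image()` validates (and, for matrices, promotes) an object to
#' this layout.  A greyscale matrix is replicated onto three equal channels;
#' an alpha channel is dropped.
#'
#' @param x numeric matrix (`H x W`, greyscale) or array (`H x W x {1,2,3,4}`).
#' @return numeric `H x W x 3` array.
#' @export
as_colour_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x))
    stop("expected an H x W x C numeric array or an H x W matrix")
  nc <- dim(x)[3L]
  if (nc > 4L) stop("unsupported channel count: ", nc)
  if (nc == 2L || nc == 4L) x <- x[, , -nc, drop = FALSE]  # drop alpha
  if (dim(x)[3L] == 1L) x <- array(x, c(dim(x)[1:2], 3L))  # grey -> RGB
  if (dim(x)[3L] != 3L) stop("unsupported channel count: ", dim(x)[3L])
  storage.mode(x) <- "double"
  x
}

check_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(arg, " must be an H x W x 3 numeric array")
  invisible(img)
}

#' Read an RGB image
#'
#' Reads an 8- or 16-bit PNG, or a PPM (`P6` binary / `P3` ASCII), into an
#' `H x W x 3` array scaled to `[0, 1]` by the bit-depth maximum.
#' Greyscale files are promoted to three equal channels and any alpha channel
#' is dropped.  No gamma transform is applied.
#'
#' @param path file path; format chosen by content (PNG signature) with the
#'   `.ppm`/`.pnm` extension as fallback.
#' @return numeric `H x W x 3` array in `[0, 1]`.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  magic <- readBin(path, "raw", n = 8L)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8L && identical(magic, png_sig)) {
    img <- png::readPNG(path)
  } else if (length(magic) >= 2L && magic[1L] == charToRaw("P") &&
             magic[2L] %in% charToRaw("36")) {
    img <- read_ppm(path)
  } else {
    stop("unreadable image (not PNG or PPM): ", path)
  }
  as_colour_image(img)
}

#' Write an image as 8-bit PNG or PPM
#'
#' Values are clipped to `[0, 1]` and quantised as `floor(255 v + 0.5)`
#' (round half away from zero), so that `0.5` maps to level 128.  An image
#' whose values are exact multiples of `1/255` round-trips bit-for-bit
#' through `write_image()` / [read_image()].
#'
#' @param img `H x W x 3` array.
#' @param path output path; a `.ppm`/`.pnm` extension selects binary PPM
#'   (`P6`), anything else PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  q <- floor(pmin(pmax(img, 0), 1) * 255 + 0.5)
  if (grepl("\\.(ppm|pnm)$", path, ignore.case = TRUE)) {
    write_ppm(q, path)
  } else {
    png::writePNG(q / 255, path)
  }
  invisible(path)
}

read_ppm <- function(path) {
  magic <- rawToChar(readBin(path, "raw", n = 2L))
  if (magic == "P3") return(read_ppm_ascii(path))
  if (magic != "P6") stop("unsupported PPM flavour: ", magic)
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {  # next whitespace-separated token, '#' comments skipped
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PPM header: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  tok()  # magic, already checked
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PPM header: ", path)
  if (maxval > 255L) stop("16-bit P6 not supported: ", path)
  n <- 3L * w * h
  vals <- as.integer(readBin(con, "raw", n = n))
  if (length(vals) < n) stop("truncated PPM pixel data: ", path)
  aperm(array(vals / maxval, c(3L, w, h)), c(3L, 2L, 1L))
}

read_ppm_ascii <- function(path) {
  txt <- sub("#.*", "", readLines(path, warn = FALSE))
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  if (toks[1L] != "P3") stop("unsupported PPM flavour: ", toks[1L])
  hdr <- as.integer(toks[2:4])
  w <- hdr[1L]; h <- hdr[2L]; maxval <- hdr[3L]
  n <- 3L * w * h
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) < n || anyNA(vals)) stop("truncated PPM pixel data: ", path)
  aperm(array(vals[seq_len(n)] / maxval, c(3L, w, h)), c(3L, 2L, 1L))
}

write_ppm <- function(q, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dim(q)[2L], dim(q)[1L]), con,
            eos = NULL)
  writeBin(as.raw(aperm(q, c(3L, 2L, 1L))), con)
  invisible(path)
}

#' Clip an image to the RGB gamut
#'
#' The gamut projection used throughout: each channel is independently
#' clamped to `[0, 1]`.  Idempotent and non-expansive per channel.
#'
#' @param img numeric array (any values).
#' @return array of the same shape with all values in `[0, 1]`.
#' @export
gamut_clip <- function(img) {
  pmin(pmax(img, 0), 1)
}
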