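#' Read a stained-smear micrograph
#'
#' Reads a TIFF or PNG micrograph in its native bit depth and tags it with
#' the staining modality. Channel count is validated against the modality:
#' acridine-orange (AO) images must be RGB, transmission electron micrographs
#' (TEM) must be single-channel.
#'
#' @param path path to a readable TIFF or PNG file.
#' @param stain one of `"TB"`, `"FR"`, `"AO"`, `"TEM"`.
#' @param pixel_size_um optional physical pixel size in micrometres; only
#'   used to report areas in physical units.
#' @return A `micrograph` object: list with `pixels` (H x W matrix or
#'   H x W x 3 array of integers in `[0, 2^bit_depth - 1]`), `bit_depth`
#'   (8 or 16), `stain`, `source_path`, `pixel_size_um`.
#' @seealso [to_intensity()], [micrograph()] to wrap an in-memory array.
#' @export
load_micrograph <- function(path, stain = c("TB", "FR", "AO", "TEM"),
                            pixel_size_um = NULL) {
  stain <- match.arg(stain)
  if (!file.exists(path))
    cd_stop(sprintf("file not found: %s", path), "cd_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    bit_depth <- png_bit_depth(path)
    arr <- png::readPNG(path)
    pixels <- round(arr * (2^bit_depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      cd_stop("the 'tiff' package is required to read TIFF files", "cd_io_error")
    arr <- tiff::readTIFF(path, info = TRUE)
    bit_depth <- attr(arr, "bits.per.sample") %||% 8L
    pixels <- round(arr * (2^bit_depth - 1))
  } else {
    cd_stop(sprintf("unsupported image format: '%s'", ext), "cd_io_error")
  }
  # drop alpha if present; collapse H x W x 1 to a matrix
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 4L)
    pixels <- pixels[, , 1:3, drop = FALSE]
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 1L)
    pixels <- pixels[, , 1]
  micrograph(pixels, bit_depth = as.integer(bit_depth), stain = stain,
             source_path = path, pixel_size_um = pixel_size_um)
}

# PNG stores the IHDR bit depth in byte 25 of the file.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L ||
      !identical(hdr[1:8],
                 as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    cd_stop(sprintf("not a PNG file: %s", path), "cd_io_error")
  as.integer(hdr[25])
}

#' Construct a micrograph from an in-memory pixel array
#'
#' @param pixels H x W matrix or H x W x 3 array of integer pixel values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16.
#' @inheritParams load_micrograph
#' @param source_path provenance string.
#' @return A `micrograph` object.
#' @export
micrograph <- function(pixels, bit_depth = 8L,
                       stain = c("TB", "FR", "AO", "TEM"),
                       source_path = "<memory>", pixel_size_um = NULL) {
  stain <- match.arg(stain)
  if (!bit_depth %in% c(8L, 16L))
    cd_stop("bit_depth must be 8 or 16", "cd_modality_error")
  nd <- length(dim(pixels))
  nchan <- if (nd == 3L) dim(pixels)[3] else 1L
  if (stain == "AO" && nchan != 3L)
    cd_stop("AO micrographs must have 3 channels", "cd_modality_error")
  if (stain == "TEM" && nchan != 1L)
    cd_stop("TEM micrographs must be single-channel", "cd_modality_error")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    cd_stop("pixel values outside [0, 2^bit_depth - 1]", "cd_modality_error")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 stain = stain, source_path = source_path,
                 pixel_size_um = pixel_size_um),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<micrograph> %s, %d-bit, %d x %d%s\n", x$stain, x$bit_depth,
              d[1], d[2],
              if (length(d) == 3L) sprintf(" x %d", d[3]) else ""))
  invisible(x)
}

#' Normalize a micrograph to a unit intensity field
#'
#' Reduces the micrograph to a single channel and rescales to `[0, 1]` by the
#' full bit-depth range (`2^bit_depth - 1`), preserving pixel order. The
#' resulting convention is *higher = lighter*; in TB/FR smears lighter heads
#' are the more compacted ones. 16-bit inputs are divided by 65535 regardless
#' of their occupied dynamic range; no percentile stretching is applied, so
#' relative deficit thresholds downstream are unaffected by global scale.
#'
#' @param m a [micrograph()].
#' @param channel_policy how RGB input is reduced: `"luminance"` (Rec.709
#'   weights 0.2126/0.7152/0.0722), a single channel, or `"asis"` which
#'   requires single-channel input.
#' @param invert flip polarity (`1 - value`); use for acquisitions where
#'   heads are lighter than the background (e.g. fluorescence).
#' @return An `intensity_image`: list with `values` (H x W matrix in
#'   `[0, 1]`) and `stain`.
#' @export
to_intensity <- function(m, channel_policy = c("luminance", "red", "green",
                                               "blue", "asis"),
                         invert = FALSE) {
  channel_policy <- match.arg(channel_policy)
  if (inherits(m, "intensity_image")) {
    if (invert) m$values <- 1 - m$values
    return(m)  # already normalized: idempotent
  }
  stopifnot(inherits(m, "micrograph"))
  px <- m$pixels
  rgb_input <- length(dim(px)) == 3L
  if (channel_policy == "asis" && rgb_input)
    cd_stop("channel_policy 'asis' requires single-channel input",
            "cd_policy_error")
  v <- if (!rgb_input) {
    px
  } else {
    ch <- function(i) matrix(px[, , i], dim(px)[1], dim(px)[2])
    switch(channel_policy,
           luminance = 0.2126 * ch(1) + 0.7152 * ch(2) + 0.0722 * ch(3),
           red = ch(1), green = ch(2), blue = ch(3))
  }
  v <- v / (2^m$bit_depth - 1)
  if (invert) v <- 1 - v
  intensity_image(v, stain = m$stain)
}

#' @rdname to_intensity
#' @param values H x W matrix of reals in `[0, 1]`.
#' @param stain staining modality tag.
#' @export
intensity_image <- function(values, stain = c("TB", "FR", "AO", "TEM")) {
  stain <- match.arg(stain)
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    cd_stop("intensity values must lie in [0, 1]", "cd_modality_error")
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, stain = stain), class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %s, %d x %d, range [%.3f, %.3f]\n", x$stain,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
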