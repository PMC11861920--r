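#' Write a grayscale rendering with white region outlines
#'
#' Renders the intensity image as gray RGB and paints the outline pixels of
#' the supplied boundaries pure white, the convention used to delineate
#' decompacted regions on review images. Pixels outside the outlines are
#' never altered, and overlapping outlines are drawn once (set union).
#'
#' @param img an `intensity_image`.
#' @param outlines result of [boundary_outlines()], or a list of n x 2
#'   (row, col) matrices of pixels to whiten.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, outlines, path) {
  stopifnot(inherits(img, "intensity_image"))
  v <- img$values
  px <- outline_pixels(outlines)
  if (nrow(px) > 0) {
    if (min(px) < 1 || max(px[, 1]) > nrow(v) || max(px[, 2]) > ncol(v))
      cd_stop("outline coordinates outside image bounds", "cd_io_error")
  }
  arr <- array(v, dim = c(nrow(v), ncol(v), 3L))
  if (nrow(px) > 0)
    for (ch in 1:3) arr[cbind(px, ch)] <- 1
  ok <- tryCatch({ png::writePNG(arr, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) cd_stop(sprintf("cannot write overlay to %s", path), "cd_io_error")
  invisible(path)
}

# Collapse outline structures to a unique (row, col) pixel matrix.
outline_pixels <- function(outlines) {
  if (is.null(outlines) || length(outlines) == 0L)
    return(matrix(integer(0), 0, 2))
  mats <- lapply(outlines, function(o) {
    if (is.list(o) && !is.null(o$pixels)) o$pixels else o
  })
  px <- do.call(rbind, mats)
  unique(px)
}

#' Write per-head results to CSV
#'
#' One row per head, stable column order, header always present (an empty
#' record set writes a header-only file). Numeric fields round-trip at full
#' double precision.
#'
#' @param records a data.frame of per-head results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a smear summary as JSON
#'
#' @param summary result of [summarize_smear()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_smear_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
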