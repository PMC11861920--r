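#' Segmentation parameters
#'
#' Controls histogram thresholding, component shape filters, and perimeter
#' erosion of segmented sperm heads. The shape filters reject tails, debris
#' and fused heads: bovine heads are compact ovals (high solidity, moderate
#' eccentricity), while tails are thin and highly eccentric.
#'
#' @param threshold_method `"otsu"` (between-class-variance maximization over
#'   a 256-bin histogram) or `"fixed"`.
#' @param fixed_threshold threshold in (0, 1), required when
#'   `threshold_method = "fixed"`.
#' @param min_area_px,max_area_px component area bounds in pixels, applied
#'   before erosion.
#' @param min_solidity minimum area / convex-hull-area ratio.
#' @param max_eccentricity maximum moment eccentricity (0 = circle).
#' @param erosion_radius_px,erosion_iterations perimeter erosion: disk
#'   structuring element radius (radius 1 is realized as the 4-connected
#'   cross) and number of passes.
#' @param keep_border_heads keep components touching the image border
#'   (default `FALSE`: truncated heads are rejected).
#' @param fill_holes fill enclosed background inside foreground components
#'   before labeling; required for TEM sections, where clear (light)
#'   chromatin regions fall outside the dark foreground and would punch
#'   holes in the section mask.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 400L, max_area_px = 20000L,
                                min_solidity = 0.85, max_eccentricity = 0.95,
                                erosion_radius_px = 1L,
                                erosion_iterations = 1L,
                                keep_border_heads = FALSE,
                                fill_holes = FALSE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold <= 0 || fixed_threshold >= 1))
    cd_stop("fixed_threshold in (0,1) required for method 'fixed'",
            "cd_param_error")
  stopifnot(min_area_px < max_area_px, min_solidity > 0, min_solidity <= 1,
            max_eccentricity > 0, max_eccentricity < 1,
            erosion_radius_px >= 1, erosion_iterations >= 1)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 min_solidity = min_solidity,
                 max_eccentricity = max_eccentricity,
                 erosion_radius_px = as.integer(erosion_radius_px),
                 erosion_iterations = as.integer(erosion_iterations),
                 keep_border_heads = keep_border_heads,
                 fill_holes = fill_holes),
            class = "segmentation_params")
}

#' Histogram-based foreground thresholding
#'
#' Stained heads are darker than the background, so the foreground is the set
#' of pixels *below* the threshold. The default threshold is Otsu's
#' between-class-variance maximizer over a 256-bin histogram.
#'
#' @param img an `intensity_image`.
#' @param params a [segmentation_params()].
#' @return list with `mask` (logical matrix) and `threshold` (the value used).
#' @export
threshold_histogram <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "intensity_image"))
  v <- img$values
  if (params$threshold_method == "otsu") {
    if (length(unique(as.vector(v))) < 2L)
      cd_stop("constant image: histogram is degenerate under Otsu",
              "cd_degenerate_histogram")
    thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  } else {
    thr <- params$fixed_threshold
  }
  list(mask = v < thr, threshold = as.numeric(thr))
}

#' Extract sperm heads from a foreground mask
#'
#' Labels 8-connected components, rejects components violating the area,
#' solidity, eccentricity, or border filters, erodes each survivor's
#' perimeter, and computes per-head mean intensity and coefficient of
#' variation over the *eroded* mask. Survivors are relabeled 1..n in raster
#' order of their centroids.
#'
#' @param mask logical foreground matrix (from [threshold_histogram()]).
#' @param img the `intensity_image` the mask was derived from.
#' @param params a [segmentation_params()].
#' @return A `labeled_heads` object: list with `heads` (list of `sperm_head`),
#'   `label_image` (integer matrix, 0 background), `params_used`, and
#'   `rejected` (data.frame of rejected components with reasons).
#' @export
extract_heads <- function(mask, img, params = segmentation_params()) {
  stopifnot(inherits(img, "intensity_image"),
            all(dim(mask) == dim(img$values)))
  if (isTRUE(params$fill_holes))
    mask <- EBImage::fillHull(mask * 1) > 0.5
  lab <- label_components8(mask)
  n <- max(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  heads <- list()
  rejected <- list()
  if (n > 0) {
    idx <- which(lab > 0L)
    labs <- lab[idx]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    ord <- order(labs)
    labs <- labs[ord]; rows <- rows[ord]; cols <- cols[ord]
    bounds <- c(0L, cumsum(tabulate(labs, n)))
    for (i in seq_len(n)) {
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      px <- cbind(row = rows[sel], col = cols[sel])
      area <- nrow(px)
      reason <- NULL
      if (!params$keep_border_heads &&
          (min(px) == 1L || max(px[, 1]) == nr || max(px[, 2]) == nc)) {
        reason <- "border"
      } else if (area < params$min_area_px) {
        reason <- "min_area"
      } else if (area > params$max_area_px) {
        reason <- "max_area"
      } else {
        pr <- mask_shape_props(px)
        if (pr$solidity < params$min_solidity) reason <- "solidity"
        else if (pr$eccentricity > params$max_eccentricity)
          reason <- "eccentricity"
      }
      if (!is.null(reason)) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(area_px = area, reason = reason,
                     centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
        next
      }
      epx <- tryCatch(
        erode_head(px, params$erosion_radius_px, params$erosion_iterations),
        cd_head_too_small = function(e) NULL)
      if (is.null(epx)) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(area_px = area, reason = "eroded_to_empty",
                     centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
        next
      }
      ivals <- img$values[epx]
      mu <- mean(ivals)
      heads[[length(heads) + 1L]] <- structure(
        list(label = NA_integer_, pixels = epx, pixels_raw = px,
             centroid = c(mean(epx[, 1]), mean(epx[, 2])),
             area_px = nrow(epx), mean_intensity = mu,
             cv_intensity = if (mu > 0) pop_sd(ivals) / mu else 0),
        class = "sperm_head")
    }
  }
  # relabel survivors in raster order of centroid (row, then col)
  if (length(heads) > 0) {
    cent <- t(vapply(heads, function(h) h$centroid, numeric(2)))
    ord <- order(cent[, 1], cent[, 2])
    heads <- heads[ord]
    for (i in seq_along(heads)) heads[[i]]$label <- i
  }
  label_image <- matrix(0L, nr, nc)
  for (h in heads) label_image[h$pixels] <- h$label
  structure(list(heads = heads, label_image = label_image,
                 params_used = params,
                 rejected = if (length(rejected)) do.call(rbind, rejected)
                            else data.frame(area_px = integer(0),
                                            reason = character(0),
                                            centroid_row = numeric(0),
                                            centroid_col = numeric(0))),
            class = "labeled_heads")
}

#' @export
print.labeled_heads <- function(x, ...) {
  cat(sprintf("<labeled_heads> %d heads (%d components rejected)\n",
              length(x$heads), nrow(x$rejected)))
  invisible(x)
}

# Shape properties of a pixel set: centroid, moment eccentricity, solidity.
# Solidity uses the convex hull of pixel *corners* so that a convex
# rasterized shape scores ~1.
mask_shape_props <- function(px) {
  r <- px[, 1]; c <- px[, 2]
  mu20 <- mean((r - mean(r))^2)
  mu02 <- mean((c - mean(c))^2)
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  # convex hull over the 4 corners of each pixel
  corners <- rbind(cbind(r - 0.5, c - 0.5), cbind(r - 0.5, c + 0.5),
                   cbind(r + 0.5, c - 0.5), cbind(r + 0.5, c + 0.5))
  h <- chull(corners)
  hx <- corners[h, 1]; hy <- corners[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  list(centroid = c(mean(r), mean(c)), eccentricity = ecc,
       solidity = nrow(px) / hull_area)
}

#' Erode a head mask
#'
#' Morphological erosion by a disk structuring element (radius 1 is the
#' 4-connected cross), applied `iterations` times: discards perimeter pixels
#' and smooths the contour. The result is always a subset of the input.
#'
#' @param px n x 2 (row, col) pixel matrix, or a logical mask matrix.
#' @param radius_px disk radius in pixels (>= 1).
#' @param iterations number of erosion passes (>= 1).
#' @return eroded pixel matrix (or logical mask if a mask was supplied).
#'   Erosion to the empty set raises a `cd_head_too_small` error.
#' @export
erode_head <- function(px, radius_px = 1L, iterations = 1L) {
  stopifnot(radius_px >= 1, iterations >= 1)
  pad <- radius_px * iterations + 1L
  as_mask <- is.logical(px) && is.matrix(px)
  if (as_mask) {
    if (!any(px)) cd_stop("empty mask", "cd_head_too_small")
    dims <- dim(px)
    sm <- px_submask(which(px, arr.ind = TRUE), pad = pad)
  } else {
    if (nrow(px) == 0L) cd_stop("empty mask", "cd_head_too_small")
    sm <- px_submask(px, pad = pad)
  }
  brush <- if (radius_px == 1L) EBImage::makeBrush(3L, shape = "diamond")
           else EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  # EBImage treats out-of-bounds as foreground during erosion; the submask is
  # padded with background on all sides so the perimeter erodes properly.
  m <- sm$mask * 1
  for (i in seq_len(iterations)) m <- EBImage::erode(m, brush)
  m <- m > 0.5
  if (!any(m))
    cd_stop("head eroded to the empty set", "cd_head_too_small")
  epx <- submask_px(m, sm$r0, sm$c0)
  if (as_mask) {
    out <- matrix(FALSE, dims[1], dims[2])
    out[epx] <- TRUE
    return(out)
  }
  epx
}
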