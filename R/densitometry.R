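#' Select the sample's reference heads
#'
#' The staining reference of a smear is built from the K lightest (most
#' compacted) and most homogeneous heads: heads are ranked by mean intensity
#' (descending) and by coefficient of variation (ascending), and the K
#' smallest rank sums are selected. Ties in the rank sum are broken by higher
#' mean intensity, then lower label. The scalar reference intensity is the
#' mean of the selected heads' mean intensities.
#'
#' @param heads a `labeled_heads` object (or list of `sperm_head`).
#' @param K number of reference heads (default 10); if the sample holds fewer
#'   heads, all are used with a warning.
#' @return A `reference_set`: list with `head_labels`, `reference_intensity`,
#'   `K`.
#' @export
select_reference <- function(heads, K = 10L) {
  hl <- if (inherits(heads, "labeled_heads")) heads$heads else heads
  n <- length(hl)
  if (n == 0L) cd_stop("no heads in sample", "cd_empty_sample")
  if (n < K)
    cd_warn(sprintf("only %d heads available for a reference of %d", n, K),
            "cd_small_reference")
  mu <- vapply(hl, function(h) h$mean_intensity, numeric(1))
  cv <- vapply(hl, function(h) h$cv_intensity, numeric(1))
  lab <- vapply(hl, function(h) h$label, integer(1))
  score <- rank(-mu, ties.method = "average") +
    rank(cv, ties.method = "average")
  sel <- order(score, -mu, lab)[seq_len(min(K, n))]
  structure(list(head_labels = lab[sel],
                 reference_intensity = mean(mu[sel]),
                 K = as.integer(K)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d heads, reference intensity %.4f\n",
              length(x$head_labels), x$reference_intensity))
  invisible(x)
}

#' Per-pixel relative intensity deficit of a head
#'
#' For each mask pixel p, `deficit(p) = (ref - I(p)) / ref` where `ref` is
#' the sample-wide reference intensity. Pixels lighter than the reference
#' carry negative deficits (retained, not clipped); decompacted chromatin
#' stains darker, giving positive deficits.
#'
#' @param img the `intensity_image`.
#' @param head a `sperm_head`.
#' @param ref a [select_reference()] result (or a positive scalar).
#' @return A `deficit_map`: list with `head_label`, `pixels` (n x 2),
#'   `deficit` (numeric vector aligned with `pixels`), `smoothed` flag,
#'   `head_area`.
#' @export
deficit_map <- function(img, head, ref) {
  stopifnot(inherits(img, "intensity_image"), inherits(head, "sperm_head"))
  r <- if (is.numeric(ref)) ref else ref$reference_intensity
  if (r <= 0) cd_stop("reference intensity must be positive", "cd_param_error")
  d <- (r - img$values[head$pixels]) / r
  structure(list(head_label = head$label, pixels = head$pixels,
                 deficit = d, smoothed = FALSE, head_area = nrow(head$pixels)),
            class = "deficit_map")
}

#' Smooth a deficit map with a mask-restricted Gaussian filter
#'
#' Convolves the continuous deficit field with a truncated discrete Gaussian
#' (window `2*radius + 1` per axis, renormalized to sum 1). The convolution
#' is restricted to the head mask with mask-normalized weights: pixels
#' outside the mask carry zero weight and the kernel is renormalized over the
#' in-mask support, so boundary values are never diluted by background.
#'
#' @param dm an unsmoothed `deficit_map`.
#' @param sigma Gaussian standard deviation in pixels (default 2).
#' @param radius truncation radius in pixels (default 5; an 11 x 11 window).
#' @return the smoothed `deficit_map`.
#' @export
smooth_deficit <- function(dm, sigma = 2, radius = 5L) {
  stopifnot(inherits(dm, "deficit_map"))
  if (dm$smoothed) cd_stop("deficit map is already smoothed", "cd_param_error")
  k <- gaussian_kernel(sigma, radius)
  sm <- px_submask(dm$pixels, pad = radius + 1L)
  D <- matrix(0, nrow(sm$mask), ncol(sm$mask))
  D[cbind(dm$pixels[, 1] - sm$r0 + 1L, dm$pixels[, 2] - sm$c0 + 1L)] <-
    dm$deficit
  M <- sm$mask * 1
  num <- EBImage::filter2(D * M, k, boundary = 0)
  den <- EBImage::filter2(M, k, boundary = 0)
  S <- matrix(0, nrow(M), ncol(M))
  inm <- sm$mask
  S[inm] <- num[inm] / den[inm]
  dm$deficit <- S[cbind(dm$pixels[, 1] - sm$r0 + 1L,
                        dm$pixels[, 2] - sm$c0 + 1L)]
  dm$smoothed <- TRUE
  dm$sigma <- sigma
  dm$radius <- as.integer(radius)
  dm
}

#' Default deficit threshold for a stain
#'
#' Decompacted regions are pixels whose smoothed deficit meets or exceeds
#' tau: 7% below the sample reference for toluidine blue, 4% for the Feulgen
#' reaction (FR stains decompaction more weakly, so its threshold is lower
#' and flags a superset of the TB pixels on identical images).
#'
#' @param stain `"TB"` or `"FR"`.
#' @return tau in (0, 1).
#' @export
default_tau <- function(stain) {
  switch(stain, TB = 0.07, FR = 0.04,
         cd_stop(sprintf("no default deficit threshold for stain '%s'", stain),
                 "cd_param_error"))
}

#' Extract altered (decompacted) regions from a smoothed deficit map
#'
#' Thresholds the smoothed deficit at `>= tau`, labels 8-connected
#' components, drops components smaller than `min_component_px` (noise the
#' Gaussian may leave), and computes the altered fraction of the head.
#'
#' @param dm a smoothed `deficit_map`.
#' @param tau deficit threshold in (0, 1); defaults to the stain's value via
#'   [default_tau()] when `stain` is given.
#' @param min_component_px minimum component area; default
#'   `max(5, 0.5% of head area)`.
#' @param stain used only to look up the default `tau`.
#' @return An `altered_region_set`: list with `head_label`, `components`
#'   (list of n x 2 pixel matrices), `component_areas`, `altered_pixels`,
#'   `altered_fraction`, `tau`, `min_component_px`.
#' @export
altered_regions <- function(dm, tau = NULL, min_component_px = NULL,
                            stain = NULL) {
  stopifnot(inherits(dm, "deficit_map"))
  if (!dm$smoothed)
    cd_warn("altered_regions called on an unsmoothed deficit map",
            "cd_unsmoothed")
  if (is.null(tau)) {
    if (is.null(stain))
      cd_stop("either tau or stain must be supplied", "cd_param_error")
    tau <- default_tau(stain)
  }
  if (tau <= 0 || tau >= 1) cd_stop("tau must lie in (0,1)", "cd_param_error")
  if (is.null(min_component_px))
    min_component_px <- max(5L, ceiling(0.005 * dm$head_area))
  keep <- dm$deficit >= tau
  comps <- list()
  areas <- integer(0)
  if (any(keep)) {
    px <- dm$pixels[keep, , drop = FALSE]
    sm <- px_submask(px)
    lab <- label_components8(sm$mask)
    for (i in seq_len(max(lab))) {
      w <- which(lab == i, arr.ind = TRUE)
      if (nrow(w) >= min_component_px) {
        comps[[length(comps) + 1L]] <-
          cbind(row = w[, 1] + sm$r0 - 1L, col = w[, 2] + sm$c0 - 1L)
        areas <- c(areas, nrow(w))
      }
    }
  }
  altered <- if (length(comps)) do.call(rbind, comps)
             else matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  structure(list(head_label = dm$head_label, components = comps,
                 component_areas = areas, altered_pixels = altered,
                 altered_fraction = nrow(altered) / dm$head_area,
                 head_area = dm$head_area,
                 tau = tau, min_component_px = as.integer(min_component_px)),
            class = "altered_region_set")
}

#' Trace the boundary of each altered region
#'
#' Walks the pixel-boundary edges of every component (marching-squares
#' style): each closed polyline is a sequence of pixel-corner vertices in
#' half-integer coordinates, with the component's interior on its left. The
#' associated `pixels` matrix holds the interior boundary pixels, used by
#' [write_overlay()] to whiten the delineation.
#'
#' @param ars an `altered_region_set` (or a list of n x 2 pixel matrices).
#' @return list of outlines, one per component: each a list with `vertices`
#'   (closed loop of (row, col) corner coordinates of the outer boundary) and
#'   `pixels` (boundary pixels of the component).
#' @export
boundary_outlines <- function(ars) {
  comps <- if (inherits(ars, "altered_region_set")) ars$components else ars
  lapply(comps, function(px) {
    sm <- px_submask(px, pad = 1L)
    loops <- trace_boundary_loops(sm$mask)
    # outer boundary: loop with the most vertices
    outer <- loops[[which.max(vapply(loops, nrow, integer(1)))]]
    outer[, 1] <- outer[, 1] + sm$r0 - 1
    outer[, 2] <- outer[, 2] + sm$c0 - 1
    bpx <- boundary_pixels(sm$mask)
    list(vertices = outer,
         pixels = cbind(row = bpx[, 1] + sm$r0 - 1L,
                        col = bpx[, 2] + sm$c0 - 1L))
  })
}

# Pixels of a mask adjacent (4-neighborhood) to background or border.
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

# Trace all closed boundary loops of a mask. Boundary edges are directed so
# the mask interior lies on the left; at 4-valent corner vertices the walk
# prefers the left turn, keeping diagonally-linked components in one loop.
# Vertices are pixel corners in half-integer (row, col) coordinates.
trace_boundary_loops <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  edges <- list()
  has <- function(r, c) r >= 1 && r <= nrow(mask) && c >= 1 &&
    c <= ncol(mask) && mask[r, c]
  for (i in seq_len(nrow(w))) {
    r <- w[i, 1]; c <- w[i, 2]
    # corners: TL=(r-.5,c-.5) TR=(r-.5,c+.5) BL=(r+.5,c-.5) BR=(r+.5,c+.5)
    if (!has(r - 1L, c))  # top edge, interior below: go left-to-right? keep
      edges[[length(edges) + 1L]] <- c(r - 0.5, c - 0.5, r - 0.5, c + 0.5)
    if (!has(r + 1L, c))  # bottom edge, interior above: right-to-left
      edges[[length(edges) + 1L]] <- c(r + 0.5, c + 0.5, r + 0.5, c - 0.5)
    if (!has(r, c - 1L))  # left edge, interior right: bottom-to-top
      edges[[length(edges) + 1L]] <- c(r + 0.5, c - 0.5, r - 0.5, c - 0.5)
    if (!has(r, c + 1L))  # right edge, interior left: top-to-bottom
      edges[[length(edges) + 1L]] <- c(r - 0.5, c + 0.5, r + 0.5, c + 0.5)
  }
  if (length(edges) == 0L) return(list())
  E <- do.call(rbind, edges)
  key <- function(r, c) paste0(r * 2, ",", c * 2)
  from <- key(E[, 1], E[, 2])
  out_by_vertex <- split(seq_len(nrow(E)), from)
  used <- rep(FALSE, nrow(E))
  loops <- list()
  dir_of <- function(e) c(e[3] - e[1], e[4] - e[2])
  for (start in seq_len(nrow(E))) {
    if (used[start]) next
    loop <- list(E[start, 1:2])
    cur <- start
    repeat {
      used[cur] <- TRUE
      loop[[length(loop) + 1L]] <- E[cur, 3:4]
      if (all(E[cur, 3:4] == loop[[1]])) break  # closed
      nxt_cands <- out_by_vertex[[key(E[cur, 3], E[cur, 4])]]
      nxt_cands <- nxt_cands[!used[nxt_cands]]
      if (length(nxt_cands) == 0L) break
      if (length(nxt_cands) == 1L) {
        cur <- nxt_cands
      } else {
        # prefer left turn relative to current direction
        d <- dir_of(E[cur, ])
        left <- c(-d[2], d[1])
        scores <- vapply(nxt_cands, function(j) {
          dj <- dir_of(E[j, ])
          sum(dj * left) * 2 + sum(dj * d)
        }, numeric(1))
        cur <- nxt_cands[which.max(scores)]
      }
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop)
  }
  lapply(loops, function(m) { colnames(m) <- c("row", "col"); m })
}
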