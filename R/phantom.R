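#' Specification of a synthetic phantom micrograph
#'
#' Phantoms are statistical test doubles for stained-smear, AO fluorescence
#' and TEM imagery: rasterized elliptical heads (tapered toward the apex) on
#' a uniform background, stain-dependent polarity, per-head stamped regions
#' matching an assigned ground-truth category, additive Gaussian noise, and
#' optional tail-like debris filaments. No optics are modelled.
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_heads number of heads to place.
#' @param head_axes_px list with `a` and `b`, each a `(min, max)` range for
#'   the semi-major and semi-minor axis in pixels.
#' @param background_intensity,head_intensity normalized intensities. For
#'   TB/FR the background is lighter than the heads; for TEM the head is
#'   dark on a light field with clear (light) stamped regions; for AO the
#'   background is dark and heads fluoresce.
#' @param categories per-head ground-truth assignment: pattern categories
#'   (`N/BD/BHD/CAD/BAD/TD/DD`) for TB/FR, grades (`N0/G1..G4`) for TEM,
#'   states (`intact`/`denatured`) for AO. `NULL` cycles through the
#'   modality's categories.
#' @param deficit_depth intensity drop inside stamped regions as a fraction
#'   of the head intensity (TB/FR).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param debris number of tail-like filaments added away from heads.
#' @param stain modality tag.
#' @param seed integer seed (R's Mersenne-Twister); fixed seed gives
#'   bitwise-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(512L, 512L), n_heads = 12L,
                         head_axes_px = list(a = c(20, 25), b = c(11, 14)),
                         background_intensity = 0.92, head_intensity = 0.75,
                         categories = NULL, deficit_depth = 0.15,
                         noise_sigma = 0.01, debris = 2L,
                         stain = c("TB", "FR", "AO", "TEM"), seed = 1L) {
  stain <- match.arg(stain)
  stopifnot(n_heads >= 1, deficit_depth > 0, deficit_depth < 1,
            noise_sigma >= 0, length(image_size) == 2L)
  if (is.null(categories)) {
    pool <- switch(stain,
                   TB = pattern_levels(), FR = pattern_levels(),
                   TEM = c("N0", "G1", "G2", "G3", "G4"),
                   AO = c("intact", "denatured"))
    categories <- rep_len(pool, n_heads)
  }
  if (length(categories) != n_heads)
    cd_stop("categories must have one entry per head", "cd_spec_error")
  structure(list(image_size = as.integer(image_size),
                 n_heads = as.integer(n_heads), head_axes_px = head_axes_px,
                 background_intensity = background_intensity,
                 head_intensity = head_intensity, categories = categories,
                 deficit_depth = deficit_depth, noise_sigma = noise_sigma,
                 debris = as.integer(debris), stain = stain,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize one tapered ellipse head. Returns pixels plus per-pixel
# normalized major coordinate u in [-1, 1] (base at -1) and minor coordinate
# v in pixels.
rasterize_head <- function(center, a, b, theta, H, W, taper = 0.25) {
  u_ax <- c(cos(theta), sin(theta))
  v_ax <- c(-sin(theta), cos(theta))
  rad <- ceiling(a) + 2L
  rr <- max(1L, floor(center[1] - rad)):min(H, ceiling(center[1] + rad))
  cc <- max(1L, floor(center[2] - rad)):min(W, ceiling(center[2] + rad))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - center[1]; dc <- g$col - center[2]
  u <- (dr * u_ax[1] + dc * u_ax[2]) / a
  v <- dr * v_ax[1] + dc * v_ax[2]
  f <- 1 - taper * pmax(0, (u - 0.2) / 0.8)   # apex (u -> 1) narrows
  inside <- u^2 + (v / (b * f))^2 <= 1
  list(pixels = cbind(row = g$row[inside], col = g$col[inside]),
       u = u[inside], v = v[inside], a = a, b = b,
       center = center, theta = theta)
}

#' Stamp a ground-truth decompaction template onto a head
#'
#' Generative templates mirror the location taxonomy: BD is a compact cap
#' confined to the basal quartile, BHD fills the base-most 40% of the head
#' (80% of the basal half), CAD is a narrow band along the major axis, BAD
#' caps both ends, TD covers 90% of the head, DD scatters one small blob per
#' quartile off-axis. `N` stamps nothing. TEM grades stamp internal clear
#' spots/regions; AO states stamp nothing (the state sets the fluorescence
#' channels instead).
#'
#' @param geom head geometry from the generator: list with `pixels`, `u`
#'   (normalized major coordinate, base at -1), `v` (minor coordinate, px),
#'   `b` (semi-minor axis).
#' @param category the assigned ground-truth label.
#' @return logical vector over `geom$pixels`: the stamped subset.
#' @export
stamp_pattern <- function(geom, category) {
  n <- nrow(geom$pixels)
  u <- geom$u; v <- geom$v
  rk <- rank(u, ties.method = "first")      # distance from base, by rank
  q <- ceiling(4 * rk / n)
  base_cap <- function(frac_of_head) rk <= frac_of_head * n
  quart_cap <- function(k, frac) {
    # the base-most (k=1) or apex-most (k=4) frac of quartile k
    in_q <- q == k
    rq <- rank(if (k == 1L) u[in_q] else -u[in_q], ties.method = "first")
    out <- rep(FALSE, n)
    out[which(in_q)[rq <= frac * sum(in_q)]] <- TRUE
    out
  }
  blob_at <- function(center_rc, radius) {
    d2 <- (geom$pixels[, 1] - center_rc[1])^2 +
      (geom$pixels[, 2] - center_rc[2])^2
    d2 <= radius^2
  }
  switch(category,
    N = rep(FALSE, n),
    TD = base_cap(0.90),
    BHD = base_cap(0.40),
    BD = quart_cap(1L, 0.55),
    BAD = quart_cap(1L, 0.55) | quart_cap(4L, 0.55),
    CAD = abs(v) <= geom$b / 5 & abs(u) <= 0.8,
    DD = {
      out <- rep(FALSE, n)
      for (k in 1:4) {
        in_q <- q == k
        ctr <- c(mean(geom$pixels[in_q, 1]), mean(geom$pixels[in_q, 2]))
        # offset off-axis, alternating sides, staying inside the head
        v_ax <- c(-sin(geom$theta), cos(geom$theta))
        off <- (-1)^k * 0.35 * geom$b
        out <- out | blob_at(ctr + off * v_ax, 3.5)
      }
      out
    },
    cd_stop(sprintf("unknown category '%s'", category), "cd_spec_error"))
}

# TEM clear-region templates: internal spots or an internal clear ellipse
# (kept off the section boundary so the section mask encloses it).
stamp_tem <- function(geom, grade) {
  n <- nrow(geom$pixels)
  u <- geom$u; v <- geom$v
  spots <- function(k) {
    out <- rep(FALSE, n)
    centers_u <- seq(-0.6, 0.6, length.out = k)
    for (i in seq_len(k)) {
      off_v <- (-1)^i * 0.25 * geom$b
      d2 <- (u * geom$a - centers_u[i] * geom$a)^2 + (v - off_v)^2
      out <- out | d2 <= 1.8^2
    }
    out
  }
  interior_region <- function(frac) {
    # internal ellipse scaled to ~frac of the head area, 2 px inside
    s <- sqrt(frac / ((1 - 2 / geom$a) * (1 - 2 / geom$b)))
    (u * geom$a / ((geom$a - 2) * s))^2 + (v / ((geom$b - 2) * s))^2 <= 1
  }
  switch(grade,
    N0 = rep(FALSE, n),
    G1 = spots(2L),
    G2 = spots(5L),
    G3 = interior_region(0.35),
    G4 = interior_region(0.60),
    cd_stop(sprintf("unknown TEM grade '%s'", grade), "cd_spec_error"))
}

#' Generate a synthetic phantom micrograph with exact ground truth
#'
#' Deterministic for a fixed `spec$seed` (R's Mersenne-Twister). Heads are
#' placed by rejection sampling (no overlap, clear of the borders); the
#' assigned category's template is stamped; Gaussian noise is added and the
#' image clipped to `[0, 1]` before 8-bit quantization.
#'
#' @param spec a [phantom_spec()].
#' @return list with `micrograph` (a [micrograph()]) and `ground_truth`:
#'   list of per-head records (`label`, `centroid`, `pixels`, `category`,
#'   `stamp_pixels`, `stamp_fraction`) plus a summary `table` data.frame and
#'   the generator's `label_image`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  a_rng <- spec$head_axes_px$a; b_rng <- spec$head_axes_px$b
  margin <- max(a_rng) + 6
  centers <- matrix(numeric(0), 0, 2)
  geoms <- list()
  attempts <- 0L
  while (length(geoms) < spec$n_heads) {
    attempts <- attempts + 1L
    if (attempts > 10000L)
      cd_stop("could not place all heads within 10000 attempts",
              "cd_infeasible_spec")
    a <- runif(1, a_rng[1], a_rng[2])
    b <- runif(1, b_rng[1], b_rng[2])
    ctr <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
    if (nrow(centers) > 0 &&
        any(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 2,
                                           byrow = TRUE))^2)) <
            2 * max(a_rng) + 6))
      next
    theta <- runif(1, 0, pi)
    geoms[[length(geoms) + 1L]] <- rasterize_head(ctr, a, b, theta, H, W)
    centers <- rbind(centers, ctr)
  }

  is_ao <- spec$stain == "AO"
  is_tem <- spec$stain == "TEM"
  bg <- if (is_ao) 0.05 else if (is_tem) 0.95 else spec$background_intensity
  canvas <- matrix(bg, H, W)
  if (is_ao) canvas_rgb <- list(R = matrix(0.02, H, W),
                                G = matrix(0.02, H, W),
                                B = matrix(0.02, H, W))
  label_image <- matrix(0L, H, W)
  gt <- list()
  occupied <- matrix(FALSE, H, W)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    cat_i <- spec$categories[i]
    if (is_tem) {
      stamp <- stamp_tem(g, cat_i)
      canvas[g$pixels] <- 0.25
      canvas[g$pixels[stamp, , drop = FALSE]] <- 0.85
    } else if (is_ao) {
      if (cat_i == "denatured") {
        canvas_rgb$R[g$pixels] <- 0.80
        canvas_rgb$G[g$pixels] <- 0.15
      } else {
        canvas_rgb$R[g$pixels] <- 0.08
        canvas_rgb$G[g$pixels] <- 0.80
      }
      stamp <- rep(FALSE, nrow(g$pixels))
    } else {
      stamp <- stamp_pattern(g, cat_i)
      canvas[g$pixels] <- spec$head_intensity
      canvas[g$pixels[stamp, , drop = FALSE]] <-
        spec$head_intensity * (1 - spec$deficit_depth)
    }
    label_image[g$pixels] <- i
    occupied[g$pixels] <- TRUE
    gt[[i]] <- list(label = i, centroid = c(mean(g$pixels[, 1]),
                                            mean(g$pixels[, 2])),
                    pixels = g$pixels, category = cat_i,
                    stamp_pixels = g$pixels[stamp, , drop = FALSE],
                    stamp_fraction = mean(stamp), geom = g)
  }

  # debris: tail-like filaments placed clear of the heads
  occ_d <- EBImage::dilate(occupied * 1,
                           EBImage::makeBrush(9L, shape = "disc")) > 0.5
  n_deb <- 0L; tries <- 0L
  while (n_deb < spec$debris && tries < 200L) {
    tries <- tries + 1L
    p0 <- c(runif(1, 10, H - 10), runif(1, 10, W - 10))
    ang <- runif(1, 0, pi)
    len <- runif(1, 140, 200)
    tseq <- seq(0, len, by = 0.5)
    pts <- cbind(round(p0[1] + tseq * cos(ang) +
                         4 * sin(tseq / 25)),       # slight curvature
                 round(p0[2] + tseq * sin(ang)))
    keep <- pts[, 1] >= 2 & pts[, 1] <= H - 1 & pts[, 2] >= 2 & pts[, 2] <= W - 1
    pts <- unique(pts[keep, , drop = FALSE])
    if (nrow(pts) < 50L) next
    # thicken to ~3 px
    thick <- rbind(pts, cbind(pts[, 1] + 1L, pts[, 2]),
                   cbind(pts[, 1], pts[, 2] + 1L))
    thick <- unique(thick)
    if (any(occ_d[thick])) next
    canvas[thick] <- if (is_tem) 0.45 else if (is_ao) 0.02 else
      spec$head_intensity * 0.85
    if (is_ao) canvas_rgb$G[thick] <- 0.30
    n_deb <- n_deb + 1L
  }

  add_noise <- function(m) {
    if (spec$noise_sigma > 0)
      m <- m + matrix(rnorm(length(m), 0, spec$noise_sigma), nrow(m))
    pmin(pmax(m, 0), 1)
  }
  if (is_ao) {
    arr <- array(0, dim = c(H, W, 3L))
    arr[, , 1] <- add_noise(canvas_rgb$R)
    arr[, , 2] <- add_noise(canvas_rgb$G)
    arr[, , 3] <- add_noise(canvas_rgb$B)
    pixels <- round(arr * 255)
  } else {
    pixels <- round(add_noise(canvas) * 255)
  }
  m <- micrograph(pixels, bit_depth = 8L, stain = spec$stain,
                  source_path = sprintf("<phantom seed=%d>", spec$seed))
  tab <- data.frame(label = vapply(gt, `[[`, integer(1), "label"),
                    category = vapply(gt, `[[`, character(1), "category"),
                    centroid_row = vapply(gt, function(x) x$centroid[1],
                                          numeric(1)),
                    centroid_col = vapply(gt, function(x) x$centroid[2],
                                          numeric(1)),
                    area_px = vapply(gt, function(x) nrow(x$pixels),
                                     integer(1)),
                    stamp_fraction = vapply(gt, `[[`, numeric(1),
                                            "stamp_fraction"))
  list(micrograph = m,
       ground_truth = list(heads = gt, table = tab,
                           label_image = label_image))
}
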