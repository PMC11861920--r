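#' Principal-axis frame of a sperm head
#'
#' Builds the geometric scaffold of the location taxonomy: major and minor
#' axes from the mask's second-moment principal directions, length and width
#' as the full moment-equivalent extents (`4 * sqrt(eigenvalue)`, which
#' equals the full axis length for a solid ellipse), and the base end chosen
#' as the major-axis end whose terminal 25% of the length is broader (the
#' bovine head tapers toward the apex). Circularly symmetric heads fall back
#' to a fixed deterministic sign with `ambiguous = TRUE`.
#'
#' @param head a `sperm_head`.
#' @return A `head_frame`: list with `center`, `major_axis`, `minor_axis`
#'   (orthonormal, row/col components), `length_px`, `width_px`, `base_sign`
#'   (+/-1; the base lies in direction `base_sign * major_axis` from the
#'   center), `ambiguous`.
#' @export
head_axes <- function(head) {
  px <- head$pixels
  if (nrow(px) < 3L) cd_stop("head has fewer than 3 pixels", "cd_geometry_error")
  r <- px[, 1]; c <- px[, 2]
  ctr <- c(mean(r), mean(c))
  mu20 <- mean((r - ctr[1])^2)
  mu02 <- mean((c - ctr[2])^2)
  mu11 <- mean((r - ctr[1]) * (c - ctr[2]))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)
  if (ev$values[1] < 1e-12)
    cd_stop("degenerate (collinear) head mask", "cd_geometry_error")
  u <- ev$vectors[, 1]  # major
  # canonical sign: first nonzero component positive
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  v <- c(-u[2], u[1])   # minor, left-orthogonal
  len <- 4 * sqrt(ev$values[1])
  wid <- 4 * sqrt(max(ev$values[2], 0))
  # base detection: mean |minor coordinate| over each terminal 25% of length
  t <- (r - ctr[1]) * u[1] + (c - ctr[2]) * u[2]
  s <- (r - ctr[1]) * v[1] + (c - ctr[2]) * v[2]
  tmin <- min(t); tmax <- max(t); span <- tmax - tmin
  lo <- t <= tmin + 0.25 * span
  hi <- t >= tmax - 0.25 * span
  w_lo <- mean(abs(s[lo]))
  w_hi <- mean(abs(s[hi]))
  ambiguous <- isTRUE(all.equal(w_lo, w_hi, tolerance = 1e-9))
  base_sign <- if (ambiguous) 1L else if (w_lo > w_hi) -1L else 1L
  structure(list(center = ctr, major_axis = u, minor_axis = v,
                 length_px = len, width_px = wid,
                 base_sign = base_sign, ambiguous = ambiguous),
            class = "head_frame")
}

#' Partition a head into base-to-apex quartiles and an axial band
#'
#' Mask pixels are ordered by their signed projection onto the major axis
#' (base first) and split into four equal-count quartiles Q1 (base) .. Q4
#' (apex); Q1 and Q2 form the basal half. The axial band is the set of mask
#' pixels whose perpendicular distance to the major-axis line is at most
#' `width_px / 6`.
#'
#' @param frame a [head_axes()] result.
#' @param head the same `sperm_head`.
#' @return A `region_partition`: list with `quartile` (integer 1..4 per mask
#'   pixel, aligned with `head$pixels`), `axial_band` (logical per pixel),
#'   `areas` (pixel counts Q1..Q4), `band_area`.
#' @export
region_partition <- function(frame, head) {
  px <- head$pixels
  r <- px[, 1]; c <- px[, 2]
  u <- frame$major_axis; v <- frame$minor_axis; ctr <- frame$center
  t <- (r - ctr[1]) * u[1] + (c - ctr[2]) * u[2]
  s <- (r - ctr[1]) * v[1] + (c - ctr[2]) * v[2]
  # distance from the base end grows with -base_sign * t
  d_base <- -frame$base_sign * t
  n <- length(d_base)
  q <- ceiling(4 * rank(d_base, ties.method = "first") / n)
  band <- abs(s) <= frame$width_px / 6
  structure(list(quartile = as.integer(q), axial_band = band,
                 areas = tabulate(q, 4L), band_area = sum(band),
                 pixels = px),
            class = "region_partition")
}

#' Decision thresholds for the location-based decompaction taxonomy
#'
#' The taxonomy's semantics are location containment; these cutoffs make
#' them operational and are deliberately exposed so a laboratory can
#' recalibrate them. A head is normal (N) below `f_min` altered fraction;
#' total decompaction (TD) requires `td_min_fraction` of the head; base-apex
#' (BAD) requires coverage of both terminal quartiles; basal-half (BHD),
#' base (BD) and central-axis (CAD) decompaction require the stated share of
#' altered pixels confined to the region (plus a minimum basal-half coverage
#' for BHD); anything else is dispersed decompaction (DD).
#'
#' @param f_min altered fraction below which a head is normal.
#' @param td_min_fraction minimum altered fraction for TD.
#' @param bad_end_coverage minimum altered coverage of Q1 and of Q4 for BAD.
#' @param bhd_fraction minimum share of altered pixels in the basal half for
#'   BHD.
#' @param bhd_coverage minimum altered coverage of the basal half for BHD.
#' @param bd_fraction minimum share of altered pixels in Q1 for BD.
#' @param cad_fraction minimum share of altered pixels in the axial band for
#'   CAD.
#' @return A `pattern_rules` list.
#' @export
pattern_rules <- function(f_min = 0.02, td_min_fraction = 0.75,
                          bad_end_coverage = 0.25, bhd_fraction = 0.80,
                          bhd_coverage = 0.40, bd_fraction = 0.80,
                          cad_fraction = 0.80) {
  structure(list(f_min = f_min, td_min_fraction = td_min_fraction,
                 bad_end_coverage = bad_end_coverage,
                 bhd_fraction = bhd_fraction, bhd_coverage = bhd_coverage,
                 bd_fraction = bd_fraction, cad_fraction = cad_fraction),
            class = "pattern_rules")
}

#' Classify a head's decompaction pattern by location
#'
#' Evaluates the decision list in fixed precedence order
#' N, TD, BAD, BHD, BD, CAD, DD over the altered regions and the head's
#' base-to-apex partition. The list is total: every head receives exactly
#' one category, and any altered head matching no positive rule falls
#' through to dispersed decompaction (DD).
#'
#' @param ars an [altered_regions()] result for the head.
#' @param part a [region_partition()] for the same head.
#' @param rules a [pattern_rules()] object.
#' @return A `pattern_call`: list with `head_label`, `category` (factor with
#'   levels N, BD, BHD, CAD, BAD, TD, DD) and `features` (the regional
#'   quantities the decision used).
#' @export
classify_pattern <- function(ars, part, rules = pattern_rules()) {
  stopifnot(inherits(ars, "altered_region_set"),
            inherits(part, "region_partition"))
  n_head <- nrow(part$pixels)
  nr_key <- max(part$pixels[, 1]) + 1L
  head_keys <- px_key(part$pixels, nr_key)
  alt_keys <- if (nrow(ars$altered_pixels)) px_key(ars$altered_pixels, nr_key)
              else integer(0)
  in_alt <- head_keys %in% alt_keys
  n_alt <- sum(in_alt)
  af <- ars$altered_fraction
  cov_q <- vapply(1:4, function(k) {
    a <- part$areas[k]
    if (a == 0) 0 else sum(in_alt & part$quartile == k) / a
  }, numeric(1))
  basal <- part$quartile <= 2L
  frac_basal <- if (n_alt) sum(in_alt & basal) / n_alt else 0
  cov_basal <- if (sum(basal)) sum(in_alt & basal) / sum(basal) else 0
  frac_q1 <- if (n_alt) sum(in_alt & part$quartile == 1L) / n_alt else 0
  frac_band <- if (n_alt) sum(in_alt & part$axial_band) / n_alt else 0
  quartiles_touched <- sum(vapply(1:4, function(k)
    any(in_alt & part$quartile == k), logical(1)))
  category <-
    if (af < rules$f_min) "N"
    else if (af >= rules$td_min_fraction) "TD"
    else if (cov_q[1] >= rules$bad_end_coverage &&
             cov_q[4] >= rules$bad_end_coverage) "BAD"
    else if (frac_basal >= rules$bhd_fraction &&
             cov_basal >= rules$bhd_coverage) "BHD"
    else if (frac_q1 >= rules$bd_fraction) "BD"
    else if (frac_band >= rules$cad_fraction) "CAD"
    else "DD"
  structure(list(head_label = ars$head_label,
                 category = factor(category, levels = pattern_levels()),
                 features = list(altered_fraction = af,
                                 coverage_q = cov_q,
                                 frac_basal = frac_basal,
                                 cov_basal = cov_basal,
                                 frac_q1 = frac_q1,
                                 frac_band = frac_band,
                                 n_components = length(ars$components),
                                 quartiles_touched = quartiles_touched)),
            class = "pattern_call")
}

pattern_levels <- function() c("N", "BD", "BHD", "CAD", "BAD", "TD", "DD")

#' Summarize per-head calls for one smear
#'
#' Counts calls per category (TB/FR patterns), TEM grade, or AO call, and
#' reports the percentage of altered heads relative to the total counted:
#' altered means category != N for patterns, grade != N0 for TEM, and a
#' denatured call for AO.
#'
#' @param calls non-empty list of `pattern_call`, `tem_observation`, or
#'   `ao_observation` objects (one modality).
#' @return A `smear_summary`: list with `modality`, `n_heads`, `counts`
#'   (named integer vector), `percent_altered`.
#' @export
summarize_smear <- function(calls) {
  if (length(calls) == 0L) cd_stop("no calls to summarize", "cd_empty_sample")
  cls <- unique(vapply(calls, function(x) class(x)[1], character(1)))
  if (length(cls) != 1L)
    cd_stop("calls mix modalities", "cd_param_error")
  if (cls == "pattern_call") {
    cats <- factor(vapply(calls, function(x) as.character(x$category),
                          character(1)), levels = pattern_levels())
    counts <- table(cats)
    altered <- sum(counts) - counts[["N"]]
    modality <- "pattern"
  } else if (cls == "tem_observation") {
    lv <- c("N0", "G1", "G2", "G3", "G4")
    cats <- factor(vapply(calls, function(x) as.character(x$grade),
                          character(1)), levels = lv)
    counts <- table(cats)
    altered <- sum(counts) - counts[["N0"]]
    modality <- "TEM"
  } else if (cls == "ao_observation") {
    cats <- factor(vapply(calls, function(x) as.character(x$call),
                          character(1)), levels = c("intact", "denatured"))
    counts <- table(cats)
    altered <- counts[["denatured"]]
    modality <- "AO"
  } else {
    cd_stop(sprintf("unknown call type '%s'", cls), "cd_param_error")
  }
  n <- length(calls)
  structure(list(modality = modality, n_heads = n,
                 counts = as.integer(counts),
                 categories = names(counts),
                 percent_altered = 100 * altered / n),
            class = "smear_summary")
}

#' @export
print.smear_summary <- function(x, ...) {
  cat(sprintf("<smear_summary> %s: %d heads, %.1f%% altered\n", x$modality,
              x$n_heads, x$percent_altered))
  print(stats::setNames(x$counts, x$categories))
  invisible(x)
}
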