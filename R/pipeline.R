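#' Analyze a TB/FR smear micrograph end to end
#'
#' Runs the full densitometric pipeline: channel reduction, histogram
#' thresholding, head extraction with perimeter erosion, reference selection
#' (the K lightest, most homogeneous heads), per-head deficit mapping,
#' Gaussian smoothing, stain-specific deficit thresholding, and
#' location-based pattern classification.
#'
#' @param m a TB or FR [micrograph()] (or an `intensity_image`).
#' @param seg_params a [segmentation_params()].
#' @param rules a [pattern_rules()].
#' @param tau deficit threshold override; defaults to the stain's value.
#' @param K number of reference heads.
#' @param sigma,radius Gaussian smoothing parameters.
#' @param channel_policy passed to [to_intensity()] for RGB input.
#' @return An `smear_analysis` list: `heads` (`labeled_heads`), `reference`,
#'   `calls` (list of `pattern_call`), `regions` (list of
#'   `altered_region_set`), `results` (per-head data.frame), `summary`
#'   (a `smear_summary`), `threshold`.
#' @export
analyze_smear <- function(m, seg_params = segmentation_params(),
                          rules = pattern_rules(), tau = NULL, K = 10L,
                          sigma = 2, radius = 5L,
                          channel_policy = "luminance") {
  img <- if (inherits(m, "intensity_image")) m
         else to_intensity(m, channel_policy)
  if (!img$stain %in% c("TB", "FR"))
    cd_stop("analyze_smear expects a TB or FR image", "cd_modality_error")
  th <- threshold_histogram(img, seg_params)
  lh <- extract_heads(th$mask, img, seg_params)
  if (length(lh$heads) == 0L)
    cd_stop("no heads segmented from smear", "cd_empty_sample")
  ref <- select_reference(lh, K)
  tau <- tau %||% default_tau(img$stain)
  calls <- vector("list", length(lh$heads))
  regions <- vector("list", length(lh$heads))
  for (i in seq_along(lh$heads)) {
    h <- lh$heads[[i]]
    dm <- smooth_deficit(deficit_map(img, h, ref), sigma, radius)
    ars <- altered_regions(dm, tau = tau)
    part <- region_partition(head_axes(h), h)
    calls[[i]] <- classify_pattern(ars, part, rules)
    regions[[i]] <- ars
  }
  results <- data.frame(
    label = vapply(lh$heads, function(h) h$label, integer(1)),
    modality = img$stain,
    area_px = vapply(lh$heads, function(h) h$area_px, integer(1)),
    mean_intensity = vapply(lh$heads, function(h) h$mean_intensity,
                            numeric(1)),
    cv_intensity = vapply(lh$heads, function(h) h$cv_intensity, numeric(1)),
    altered_fraction = vapply(regions, function(r) r$altered_fraction,
                              numeric(1)),
    category = vapply(calls, function(x) as.character(x$category),
                      character(1)),
    is_reference = vapply(lh$heads, function(h)
      h$label %in% ref$head_labels, logical(1)))
  structure(list(heads = lh, reference = ref, calls = calls,
                 regions = regions, results = results,
                 summary = summarize_smear(calls), threshold = th$threshold,
                 tau = tau),
            class = "smear_analysis")
}

#' Analyze a TEM micrograph
#'
#' Segments dark head sections on the light field (with hole filling so
#' internal clear regions stay inside the section mask), detects clear
#' chromatin regions per head, and grades each section.
#'
#' @param m a TEM [micrograph()] (or `intensity_image`).
#' @param seg_params segmentation parameters; `fill_holes` is forced on.
#' @param clear_tau,small_spot_max_fraction see [detect_clear_regions()].
#' @return list with `heads`, `observations` (graded `tem_observation`s),
#'   `results` data.frame, `summary`.
#' @export
analyze_tem <- function(m, seg_params = segmentation_params(),
                        clear_tau = 0.60, small_spot_max_fraction = 0.02) {
  img <- if (inherits(m, "intensity_image")) m else to_intensity(m, "asis")
  if (img$stain != "TEM")
    cd_stop("analyze_tem expects a TEM image", "cd_modality_error")
  seg_params$fill_holes <- TRUE
  th <- threshold_histogram(img, seg_params)
  lh <- extract_heads(th$mask, img, seg_params)
  if (length(lh$heads) == 0L)
    cd_stop("no head sections segmented", "cd_empty_sample")
  obs <- lapply(lh$heads, function(h)
    grade_tem(detect_clear_regions(img, h, clear_tau,
                                   small_spot_max_fraction)))
  results <- data.frame(
    label = vapply(lh$heads, function(h) h$label, integer(1)),
    modality = "TEM",
    n_clear_spots = vapply(obs, function(o) o$n_clear_spots, integer(1)),
    largest_clear_fraction = vapply(obs, function(o)
      o$largest_clear_fraction, numeric(1)),
    grade = vapply(obs, function(o) o$grade, character(1)))
  list(heads = lh, observations = obs, results = results,
       summary = summarize_smear(obs))
}

#' Analyze an acridine-orange fluorescence micrograph
#'
#' Heads fluoresce on a dark field, so segmentation runs on the inverted
#' luminance; the intact/denatured call uses the red share of each head's
#' mean fluorescence on the original channels.
#'
#' @param m a 3-channel AO [micrograph()].
#' @param seg_params a [segmentation_params()].
#' @param red_fraction_threshold see [classify_ao()].
#' @return list with `heads`, `observations` (`ao_observation`s), `results`
#'   data.frame, `summary`.
#' @export
analyze_ao <- function(m, seg_params = segmentation_params(),
                       red_fraction_threshold = 0.40) {
  stopifnot(inherits(m, "micrograph"))
  if (m$stain != "AO") cd_stop("analyze_ao expects an AO image",
                               "cd_modality_error")
  img <- to_intensity(m, "luminance", invert = TRUE)
  th <- threshold_histogram(img, seg_params)
  lh <- extract_heads(th$mask, img, seg_params)
  if (length(lh$heads) == 0L)
    cd_stop("no heads segmented", "cd_empty_sample")
  obs <- list()
  for (h in lh$heads) {
    o <- tryCatch(classify_ao(m, h, red_fraction_threshold),
                  cd_unstained_head = function(e) NULL)
    if (!is.null(o)) obs[[length(obs) + 1L]] <- o
  }
  results <- data.frame(
    label = vapply(obs, function(o) o$head_label, integer(1)),
    modality = "AO",
    mean_red = vapply(obs, function(o) o$mean_red, numeric(1)),
    mean_green = vapply(obs, function(o) o$mean_green, numeric(1)),
    red_fraction = vapply(obs, function(o) o$red_fraction, numeric(1)),
    call = vapply(obs, function(o) o$call, character(1)))
  list(heads = lh, observations = obs, results = results,
       summary = summarize_smear(obs))
}
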