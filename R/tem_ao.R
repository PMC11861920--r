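#' Detect clear (electron-lucent) chromatin regions in a TEM head section
#'
#' In transmission electron micrographs condensed chromatin is electron-dense
#' (dark) and decompacted chromatin appears as clear, light regions. Clear
#' pixels are those with normalized intensity at or above `clear_tau`.
#' 8-connected clear components are partitioned into small spots (area
#' fraction of the head section at most `small_spot_max_fraction`), which
#' are counted, and larger regions, of which the maximum area fraction is
#' reported.
#'
#' @param img a TEM `intensity_image`.
#' @param head a `sperm_head` segmented from the same image.
#' @param clear_tau absolute normalized-intensity threshold for clear pixels
#'   (default 0.60).
#' @param small_spot_max_fraction largest head-area fraction a component may
#'   occupy and still count as a small spot (default 0.02).
#' @return A `tem_observation`: list with `head_label`, `n_clear_spots`,
#'   `largest_clear_fraction`, and `grade = NA` (set by [grade_tem()]).
#' @export
detect_clear_regions <- function(img, head, clear_tau = 0.60,
                                 small_spot_max_fraction = 0.02) {
  stopifnot(inherits(img, "intensity_image"), inherits(head, "sperm_head"))
  clear <- img$values[head$pixels] >= clear_tau
  n_spots <- 0L
  largest <- 0
  if (any(clear)) {
    px <- head$pixels[clear, , drop = FALSE]
    sm <- px_submask(px)
    lab <- label_components8(sm$mask)
    fr <- tabulate(lab[lab > 0L], max(lab)) / head$area_px
    n_spots <- sum(fr <= small_spot_max_fraction)
    if (any(fr > small_spot_max_fraction))
      largest <- max(fr[fr > small_spot_max_fraction])
  }
  structure(list(head_label = head$label, n_clear_spots = as.integer(n_spots),
                 largest_clear_fraction = largest, grade = NA_character_),
            class = "tem_observation")
}

#' @rdname detect_clear_regions
#' @param head_label head identifier.
#' @param n_clear_spots count of small clear components.
#' @param largest_clear_fraction largest non-spot clear region as a fraction
#'   of the head section area.
#' @export
tem_observation <- function(head_label, n_clear_spots,
                            largest_clear_fraction) {
  stopifnot(n_clear_spots >= 0, largest_clear_fraction >= 0,
            largest_clear_fraction <= 1)
  structure(list(head_label = head_label,
                 n_clear_spots = as.integer(n_clear_spots),
                 largest_clear_fraction = largest_clear_fraction,
                 grade = NA_character_),
            class = "tem_observation")
}

#' Grade a TEM head observation
#'
#' Closed-form grading of chromatin integrity from clear-region findings:
#' G1 for up to three small clear spots; G2 for four to six small spots or a
#' clearer region occupying up to a quarter of the head; G3 for more than
#' six spots or a clearer region up to half of the head; G4 for a clear
#' nuclear area of more than half the head. Heads with no findings receive
#' N0 (reported separately so G1-G4 percentages stay comparable). The
#' mapping is monotone: more spots or a larger clear fraction never lowers
#' the grade.
#'
#' @param obs a `tem_observation`.
#' @return the observation with `grade` set to one of
#'   `"N0","G1","G2","G3","G4"`.
#' @export
grade_tem <- function(obs) {
  stopifnot(inherits(obs, "tem_observation"))
  s <- obs$n_clear_spots
  f <- obs$largest_clear_fraction
  obs$grade <-
    if (f > 0.5) "G4"
    else if (s > 6L || f > 0.25) "G3"
    else if (s >= 4L || f > 0) "G2"
    else if (s >= 1L) "G1"
    else "N0"
  obs
}

#' Call intact versus denatured DNA from an acridine-orange head
#'
#' Acridine orange fluoresces green on double-stranded DNA and red on
#' denatured, single-stranded DNA; yellow/orange heads (red overlapping
#' green) indicate denaturation. The call thresholds the red share of the
#' head's mean fluorescence: `red_fraction = mean_red / (mean_red +
#' mean_green)`, denatured when `red_fraction >= red_fraction_threshold`
#' (boundary inclusive, the yellow/orange onset). One rule serves both the
#' confocal and the epifluorescence acquisition routes.
#'
#' @param m a 3-channel AO [micrograph()].
#' @param head a `sperm_head` segmented from the same image.
#' @param red_fraction_threshold decision boundary (default 0.40).
#' @param red_channel,green_channel channel indices (defaults 1 and 2).
#' @return An `ao_observation`: list with `head_label`, `mean_red`,
#'   `mean_green`, `red_fraction`, `call` (`"intact"` or `"denatured"`).
#' @export
classify_ao <- function(m, head, red_fraction_threshold = 0.40,
                        red_channel = 1L, green_channel = 2L) {
  stopifnot(inherits(m, "micrograph"), inherits(head, "sperm_head"))
  if (length(dim(m$pixels)) != 3L)
    cd_stop("AO classification needs a 3-channel micrograph",
            "cd_modality_error")
  scale <- 2^m$bit_depth - 1
  mean_red <- mean(m$pixels[, , red_channel][head$pixels]) / scale
  mean_green <- mean(m$pixels[, , green_channel][head$pixels]) / scale
  if (mean_red + mean_green == 0)
    cd_stop("unstained head: zero red and green signal", "cd_unstained_head")
  rf <- mean_red / (mean_red + mean_green)
  structure(list(head_label = head$label, mean_red = mean_red,
                 mean_green = mean_green, red_fraction = rf,
                 call = if (rf >= red_fraction_threshold) "denatured"
                        else "intact"),
            class = "ao_observation")
}
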