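test_that("head axes recover the geometry of a rasterized ellipse", {
  m <- ellipse_mask(100, 100, c(50, 50), 40, 20)
  fr <- head_axes(make_head(m))
  expect_equal(abs(fr$major_axis), c(1, 0), tolerance = 1e-6)
  expect_equal(fr$length_px, 80, tolerance = 80 * 0.05)
  expect_equal(fr$width_px, 40, tolerance = 40 * 0.05)
  expect_equal(sum(fr$major_axis * fr$minor_axis), 0, tolerance = 1e-12)
  # perfect circle: ambiguous orientation, deterministic tie-break
  circ <- ellipse_mask(60, 60, c(30, 30), 15, 15)
  fc <- head_axes(make_head(circ))
  expect_true(fc$ambiguous)
  expect_equal(fc$base_sign, 1L)
  expect_equal(fc$length_px, fc$width_px, tolerance = 0.05 * fc$length_px)
  expect_error(head_axes(make_head(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))),
               class = "cd_geometry_error")
})

test_that("the base is the broader end of a tapered head", {
  ph <- generate_phantom(phantom_spec(n_heads = 4, seed = 21,
                                      noise_sigma = 0))
  for (g in ph$ground_truth$heads) {
    h <- make_head_from_px(g$pixels)
    fr <- head_axes(h)
    # ground truth: base lies in direction -u_axis of the generator
    gt_base_dir <- -c(cos(g$geom$theta), sin(g$geom$theta))
    est_base_dir <- fr$base_sign * fr$major_axis
    expect_gt(sum(gt_base_dir * est_base_dir), 0.9)
  }
})

test_that("region partition is a partition with equal quartiles", {
  rect <- matrix(FALSE, 60, 40); rect[11:50, 6:35] <- TRUE  # 40 x 30
  h <- make_head(rect)
  part <- region_partition(head_axes(h), h)
  expect_equal(sort(unique(part$quartile)), 1:4)
  expect_equal(part$areas, rep(300L, 4))           # 1200 px / 4
  expect_equal(sum(part$areas), h$area_px)
  # axial band of a width-30 rectangle: height 10 rows
  expect_equal(part$band_area, 40 * 10, tolerance = 40 * 2)
  expect_true(all(part$axial_band %in% c(TRUE, FALSE)))
})

test_that("quartile union equals the head mask on phantoms", {
  ph <- generate_phantom(phantom_spec(n_heads = 3, seed = 13,
                                      noise_sigma = 0))
  for (g in ph$ground_truth$heads) {
    h <- make_head_from_px(g$pixels)
    part <- region_partition(head_axes(h), h)
    expect_equal(length(part$quartile), nrow(g$pixels))
    expect_equal(sum(part$areas), nrow(g$pixels))
    expect_true(all(part$axial_band | !part$axial_band))
  }
})

test_that("the decision list is total, deterministic and respects N", {
  mask <- ellipse_mask(80, 80, c(40, 40), 24, 12)
  h <- make_head(mask)
  part <- region_partition(head_axes(h), h)
  empty_ars <- structure(list(head_label = 1L, components = list(),
                              component_areas = integer(0),
                              altered_pixels = matrix(integer(0), 0, 2),
                              altered_fraction = 0, head_area = h$area_px,
                              tau = 0.07, min_component_px = 5L),
                         class = "altered_region_set")
  expect_equal(as.character(classify_pattern(empty_ars, part)$category), "N")
  # full coverage forces TD
  full_ars <- empty_ars
  full_ars$altered_pixels <- h$pixels
  full_ars$components <- list(h$pixels)
  full_ars$altered_fraction <- 1
  expect_equal(as.character(classify_pattern(full_ars, part)$category), "TD")
})

test_that("phantom-stamped categories are recovered under default rules", {
  ph <- generate_phantom(phantom_spec(
    n_heads = 14, image_size = c(600, 600), seed = 17, noise_sigma = 0.01))
  an <- suppressWarnings(analyze_smear(ph$micrograph))
  matched <- match_to_gt(an, ph$ground_truth$table)
  expect_true(all(!is.na(matched$gt_category)))
  expect_equal(an$results$category, matched$gt_category)
  # determinism: shuffling head processing order never changes a call
  an2 <- analyze_smear(ph$micrograph)
  expect_equal(an$results$category, an2$results$category)
})

test_that("BAD needs both ends; a two-end phantom at moderate coverage is BAD", {
  ph <- generate_phantom(phantom_spec(n_heads = 5, seed = 23,
                                      categories = rep("BAD", 5),
                                      noise_sigma = 0.01))
  an <- suppressWarnings(analyze_smear(ph$micrograph))
  expect_true(all(an$results$category == "BAD"))
  expect_true(all(an$results$altered_fraction < 0.75))
})

test_that("smear summaries count every head exactly once", {
  calls <- c(replicate(180, list(structure(list(
    head_label = 1L, category = factor("N", levels = chromadens:::pattern_levels()),
    features = list()), class = "pattern_call"))),
    replicate(20, list(structure(list(
      head_label = 1L, category = factor("BD", levels = chromadens:::pattern_levels()),
      features = list()), class = "pattern_call"))))
  s <- summarize_smear(calls)
  expect_equal(s$n_heads, 200L)
  expect_equal(sum(s$counts), 200L)
  expect_equal(s$percent_altered, 10.0)
  all_n <- summarize_smear(calls[1:180])
  expect_equal(all_n$percent_altered, 0)
  expect_error(summarize_smear(list()), class = "cd_empty_sample")
})
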