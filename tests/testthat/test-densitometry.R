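heads_from <- function(mu, cv) {
  lapply(seq_along(mu), function(i)
    structure(list(label = i, pixels = cbind(row = i, col = 1L),
                   centroid = c(i, 1), area_px = 1L,
                   mean_intensity = mu[i], cv_intensity = cv[i]),
              class = "sperm_head"))
}

test_that("reference selection favours light, homogeneous heads", {
  mu <- c(rep(0.90, 10), rep(0.50, 20))
  cv <- c(rep(0.01, 10), rep(0.20, 20))
  rs <- select_reference(heads_from(mu, cv), K = 10)
  expect_setequal(rs$head_labels, 1:10)
  expect_equal(rs$reference_intensity, 0.90)
})

test_that("undersized samples select everything with a warning", {
  expect_warning(rs <- select_reference(heads_from(rep(0.8, 5),
                                                   rep(0.05, 5)), K = 10),
                 class = "cd_small_reference")
  expect_length(rs$head_labels, 5L)
  expect_error(select_reference(list(), K = 10), class = "cd_empty_sample")
})

test_that("conflicting ranks match the brute-force rank-sum oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(12:30, 1)
    mu <- runif(n, 0.4, 0.95)
    cv <- runif(n, 0.01, 0.3)
    rs <- select_reference(heads_from(mu, cv), K = 10)
    oracle <- brute_reference(mu, cv, 10)
    expect_setequal(rs$head_labels, oracle$selected)
    expect_equal(rs$reference_intensity, oracle$reference)
  }
  # when light and homogeneous coincide, the reference outranks the
  # unselected heads' mean intensities
  mu <- c(seq(0.90, 0.81, by = -0.01), seq(0.60, 0.41, by = -0.01))
  cv <- c(seq(0.01, 0.10, by = 0.01), seq(0.11, 0.30, by = 0.01))
  rs <- select_reference(heads_from(mu, cv), K = 10)
  expect_gte(sum(rs$reference_intensity >= mu), length(mu) - 10)
})

test_that("deficit map implements the relative-deficit definition", {
  v <- matrix(0.80, 10, 10)
  v[5, 5] <- 0.72; v[6, 6] <- 0.90
  mask <- matrix(TRUE, 10, 10)
  h <- make_head(mask, v)
  dm <- deficit_map(intensity_image(v, "TB"), h, 0.80)
  d <- matrix(0, 10, 10); d[cbind(dm$pixels)] <- dm$deficit
  expect_equal(d[5, 5], 0.10, tolerance = 1e-12)
  expect_equal(d[6, 6], -0.125, tolerance = 1e-12)
  expect_equal(d[1, 1], 0, tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants, impulses and ramps", {
  mask <- matrix(TRUE, 31, 31)
  img0 <- intensity_image(matrix(0.5, 31, 31), "TB")
  h <- make_head(mask, img0$values)
  # constant field is unchanged (kernel sums to 1)
  dm <- smooth_deficit(deficit_map(img0, h, 0.8), 2, 5)
  expect_equal(dm$deficit, rep(0.375, 31 * 31), tolerance = 1e-12)
  # impulse: centre value equals the kernel's central weight
  x <- seq(-5, 5); g <- exp(-x^2 / 8); k <- outer(g, g) / sum(outer(g, g))
  v <- matrix(0.8, 31, 31); v[16, 16] <- 0  # deficit 1 at the centre
  imp <- smooth_deficit(deficit_map(intensity_image(v, "TB"),
                                    make_head(mask, v), 0.8), 2, 5)
  D <- matrix(0, 31, 31); D[imp$pixels] <- imp$deficit
  expect_equal(D[16, 16], k[6, 6], tolerance = 1e-9)
  # linear ramp far from the boundary is unchanged (symmetric kernel)
  ramp <- matrix(rep(seq(0.5, 0.8, length.out = 31), each = 31), 31, 31)
  rm_ <- smooth_deficit(deficit_map(intensity_image(ramp, "TB"),
                                    make_head(mask, ramp), 0.8), 2, 5)
  Dr <- matrix(0, 31, 31); Dr[rm_$pixels] <- rm_$deficit
  expect_equal(Dr[10:22, 10:22], (0.8 - ramp[10:22, 10:22]) / 0.8,
               tolerance = 1e-9)
  # double smoothing is rejected
  expect_error(smooth_deficit(dm), class = "cd_param_error")
})

test_that("mask-restricted smoothing conserves interior deficit mass", {
  set.seed(5)
  mask <- ellipse_mask(60, 60, c(30, 30), 25, 20)
  v <- matrix(0.8, 60, 60)
  core <- ellipse_mask(60, 60, c(30, 30), 10, 8)
  v[core] <- 0.68
  h <- make_head(mask, v)
  dm0 <- deficit_map(intensity_image(v, "TB"), h, 0.8)
  dm1 <- smooth_deficit(dm0, 2, 5)
  expect_equal(sum(dm1$deficit), sum(dm0$deficit), tolerance = 1e-6)
})

test_that("altered regions obey the threshold and component filter", {
  mask <- matrix(FALSE, 9, 9); mask[2:8, 2:8] <- TRUE
  v <- matrix(0.8, 9, 9)
  v[3, 3] <- 0.8 * (1 - 0.03); v[5, 5] <- 0.8 * (1 - 0.05)
  v[7, 7] <- 0.8 * (1 - 0.08)
  dm <- deficit_map(intensity_image(v, "TB"), make_head(mask, v), 0.8)
  dm$smoothed <- TRUE  # test pure threshold semantics, no blur
  a7 <- altered_regions(dm, tau = 0.07, min_component_px = 1L)
  a4 <- altered_regions(dm, tau = 0.04, min_component_px = 1L)
  expect_equal(nrow(a7$altered_pixels), 1L)
  expect_equal(nrow(a4$altered_pixels), 2L)
  # null case
  v0 <- matrix(0.8, 9, 9)
  dm0 <- deficit_map(intensity_image(v0, "TB"), make_head(mask, v0), 0.8)
  dm0$smoothed <- TRUE
  a0 <- altered_regions(dm0, tau = 0.07)
  expect_equal(a0$altered_fraction, 0)
  expect_length(a0$components, 0L)
  # component filter drops small specks
  asmall <- altered_regions(dm, tau = 0.04, min_component_px = 2L)
  expect_equal(nrow(asmall$altered_pixels), 0L)
})

test_that("stamped basal region is recovered within tolerance", {
  ph <- generate_phantom(phantom_spec(n_heads = 6, seed = 9,
                                      categories = rep("BD", 6),
                                      noise_sigma = 0.01))
  an <- suppressWarnings(analyze_smear(ph$micrograph))
  for (i in seq_along(an$regions)) {
    expect_gte(an$regions[[i]]$altered_fraction, 0.05)
    expect_lte(an$regions[[i]]$altered_fraction, 0.25)
    expect_length(an$regions[[i]]$components, 1L)
  }
})

test_that("default tau is stain-specific", {
  expect_equal(default_tau("TB"), 0.07)
  expect_equal(default_tau("FR"), 0.04)
  expect_error(default_tau("TEM"), class = "cd_param_error")
})

test_that("boundary outlines trace unit squares and 3x3 blocks", {
  one <- boundary_outlines(list(cbind(row = 5L, col = 5L)))
  expect_length(one, 1L)
  verts <- one[[1]]$vertices
  expect_equal(nrow(verts), 5L)              # 4 edges, closed
  expect_equal(verts[1, ], verts[5, ])
  expect_setequal(paste(verts[1:4, 1], verts[1:4, 2]),
                  c("4.5 4.5", "4.5 5.5", "5.5 4.5", "5.5 5.5"))
  block <- as.matrix(expand.grid(row = 3:5, col = 7:9))
  b <- boundary_outlines(list(block))[[1]]
  expect_equal(nrow(b$vertices), 13L)        # 12 edges, closed
  expect_equal(b$vertices[1, ], b$vertices[13, ])
  expect_equal(nrow(b$pixels), 8L)           # all but the centre pixel
  expect_length(boundary_outlines(list()), 0L)
})
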