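make_flat_patch <- function(n = 8, lum = 100, pedestal = -7.5) {
  stereo_patch(matrix(lum, n, n), matrix(lum, n, n),
               matrix(pedestal, n, n))
}

test_that("disparity-contrast matches direct arithmetic on small patches", {
  # uniform weights, v - v0 = {0, 1, 2, 3} on 4 pixels -> sqrt(14/4)
  p <- stereo_patch(matrix(100, 2, 2), matrix(100, 2, 2),
                    matrix(c(0, 1, 2, 3), 2, 2), v0 = 0,
                    window = matrix(1, 2, 2))
  expect_equal(disparity_contrast(p), sqrt(14 / 4), tolerance = 1e-12)
  # constant deviation c with arbitrary weights -> |c|
  w <- matrix(runif(16, 0.1, 1), 4, 4)
  p2 <- stereo_patch(matrix(100, 4, 4), matrix(100, 4, 4),
                     matrix(-5 - 0.8, 4, 4), v0 = -5, window = w)
  expect_equal(disparity_contrast(p2), 0.8, tolerance = 1e-12)
  # flat map -> 0
  expect_equal(disparity_contrast(make_flat_patch()), 0)
})

test_that("disparity-contrast is shift-invariant in (v, v0) jointly and linear in the deviation", {
  set.seed(1)
  v <- matrix(rnorm(64, -7.5, 0.5), 8, 8)
  p <- stereo_patch(matrix(100, 8, 8), matrix(100, 8, 8), v, v0 = -7.5)
  base <- disparity_contrast(p)
  p_shift <- stereo_patch(matrix(100, 8, 8), matrix(100, 8, 8), v + 3,
                          v0 = -7.5 + 3)
  expect_equal(disparity_contrast(p_shift), base, tolerance = 1e-12)
  p_scaled <- stereo_patch(matrix(100, 8, 8), matrix(100, 8, 8),
                           -7.5 + 2.5 * (v + 7.5), v0 = -7.5)
  expect_equal(disparity_contrast(p_scaled), 2.5 * base, tolerance = 1e-12)
})

test_that("half-occluded pixels are excluded with window renormalisation", {
  v <- matrix(-7.5, 4, 4)
  v[1, 1] <- 100  # huge deviation, but masked out
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE
  p <- stereo_patch(matrix(100, 4, 4), matrix(100, 4, 4), v, v0 = -7.5,
                    halfocc_mask = mask)
  expect_equal(disparity_contrast(p), 0)
  # fully masked patch -> undefined-statistic error
  p_all <- stereo_patch(matrix(100, 2, 2), matrix(100, 2, 2),
                        matrix(-7.5, 2, 2),
                        halfocc_mask = matrix(TRUE, 2, 2))
  expect_error(disparity_contrast(p_all), "undefined")
})

test_that("RMS contrast matches direct arithmetic and fix_contrast is exact", {
  # blank patch -> 0
  expect_equal(rms_contrast(make_flat_patch()), 0)
  # |weber contrast| = 0.2 everywhere (balanced +/-) -> sqrt(0.08)
  n <- 4
  img <- matrix(100, n, n)
  img[, 1:2] <- 120; img[, 3:4] <- 80
  p <- stereo_patch(img, img, matrix(0, n, n), window = matrix(1, n, n))
  expect_equal(rms_contrast(p), sqrt(0.08), tolerance = 1e-12)
  # scaling to half the contrast is a factor-2 reduction of the statistic
  p_half <- fix_contrast(p, sqrt(0.08) / 2)
  expect_equal(rms_contrast(p_half), sqrt(0.08) / 2, tolerance = 1e-12)
  expect_equal(p_half$left_img - 100, (p$left_img - 100) / 2,
               tolerance = 1e-9)
  # fixing to the current value leaves the images unchanged
  p_same <- fix_contrast(p, rms_contrast(p))
  expect_equal(p_same$left_img, p$left_img, tolerance = 1e-12)
  # random patch to the conventional 0.3
  pr <- synth_patch(5, rms_target = NULL)
  pf <- fix_contrast(pr, 0.3)
  expect_equal(rms_contrast(pf), 0.3, tolerance = 1e-12)
  expect_error(fix_contrast(make_flat_patch(), 0.3), "zero-contrast")
})

test_that("RMS contrast is invariant to window renormalisation and eye swap", {
  p <- synth_patch(2)
  p2 <- p
  p2$window <- p$window * 7.3
  expect_equal(rms_contrast(p2), rms_contrast(p), tolerance = 1e-12)
  p3 <- p
  p3$left_img <- p$right_img
  p3$right_img <- p$left_img
  expect_equal(rms_contrast(p3), rms_contrast(p), tolerance = 1e-12)
})

test_that("flattening duplicates a half-image, zeroes disparity-contrast, and is idempotent", {
  p <- synth_patch(3, disparity_contrast_target = 0.8, halfocc_fraction = 0.05)
  f <- flatten(p, keep_eye = "left")
  expect_identical(f$left_img, f$right_img)
  expect_identical(f$left_img, p$left_img)
  expect_equal(disparity_contrast(f), 0)
  expect_identical(flatten(f, keep_eye = "left"), f)
  # seeded random eye choice is reproducible
  r1 <- flatten(p, keep_eye = "random", seed = 5)
  r2 <- flatten(p, keep_eye = "random", seed = 5)
  expect_identical(r1, r2)
})

test_that("the synthetic patch generator hits its disparity-contrast target", {
  for (target in c(0, 0.05, 0.75, 1.2)) {
    p <- synth_patch(7, disparity_contrast_target = target, pedestal = -5.63)
    expect_equal(disparity_contrast(p), target, tolerance = 1e-6)
    expect_equal(p$v0, -5.63)
  }
  p0 <- synth_patch(8, disparity_contrast_target = 0)
  expect_true(all(p0$vergence_map == p0$v0))
  expect_equal(sum(synth_patch(9, halfocc_fraction = 0)$halfocc_mask), 0)
  expect_gt(sum(synth_patch(9, halfocc_fraction = 0.1)$halfocc_mask), 0)
})

test_that("vetting accepts coherent centres and bins by whole-patch disparity-contrast", {
  flat <- make_flat_patch(32)
  r <- vet_patch(flat)
  expect_true(r$accepted)
  expect_equal(r$central_dc_arcsec, 0)
  expect_equal(r$bin, "none")

  hi <- synth_patch(11, disparity_contrast_target = 0.75)
  rh <- vet_patch(hi)
  expect_true(rh$accepted)
  expect_equal(rh$bin, "high")

  lo <- synth_patch(12, disparity_contrast_target = 0.08)
  expect_equal(vet_patch(lo)$bin, "low")

  # a bumpy centre is rejected (central disparity-contrast > 20 arcsec)
  bump <- synth_patch(13, disparity_contrast_target = 0)
  v <- bump$vergence_map
  ctr <- v[17, 17]
  v[17, 18] <- ctr + 2  # 2 arcmin step right at the centre
  bump$vergence_map <- v
  rb <- vet_patch(bump)
  expect_false(rb$accepted)
  expect_match(paste(rb$reasons, collapse = " "), "disparity-contrast")

  # a half-occluded pixel inside the central region is rejected
  occ <- synth_patch(14, disparity_contrast_target = 0.5)
  occ$halfocc_mask[17, 18] <- TRUE
  ro <- vet_patch(occ)
  expect_false(ro$accepted)
  expect_match(paste(ro$reasons, collapse = " "), "half-occluded")
})

test_that("patches round-trip through the TIFF + CSV layout", {
  p <- synth_patch(21, disparity_contrast_target = 0.6,
                   halfocc_fraction = 0.05)
  base <- file.path(withr::local_tempdir(), "patch01")
  write_patch(p, base)
  expect_true(file.exists(paste0(base, "_L.tif")))
  q <- read_patch(base)
  expect_equal(q$left_img, p$left_img, tolerance = 1e-5)
  expect_equal(q$right_img, p$right_img, tolerance = 1e-5)
  expect_equal(q$vergence_map, p$vergence_map, tolerance = 1e-12)
  expect_identical(q$halfocc_mask, p$halfocc_mask)
  expect_equal(q$v0, p$v0)
  expect_equal(disparity_contrast(q), disparity_contrast(p),
               tolerance = 1e-9)
})
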