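random_raster <- function(h = 12, w = 17, seed = 3) {
  withr::with_seed(seed, array(runif(h * w * 3), dim = c(h, w, 3)))
}

test_that("rotation is lossless with the documented orientation", {
  r <- random_raster()
  expect_identical(rotate_raster(r, 0), r)
  # four quarter turns compose to the identity
  out <- r
  for (i in 1:4) out <- rotate_raster(out, 90)
  expect_equal(out, r)
  expect_equal(rotate_raster(rotate_raster(r, 90), 270), r)
  expect_equal(rotate_raster(r, 180),
               rotate_raster(rotate_raster(r, 90), 90))
  # [[a, b]] rotated 90 degrees puts a above b (clockwise convention),
  # checked against the explicit coordinate map new[c, H-1-r] = old[r, c]
  ab <- array(c(0.1, 0.9), dim = c(1, 2, 1))[, , c(1, 1, 1), drop = FALSE]
  rot <- rotate_raster(ab, 90)
  expect_identical(dim(rot), c(2L, 1L, 3L))
  expect_equal(rot[1, 1, 1], 0.1)
  expect_equal(rot[2, 1, 1], 0.9)
  # dimensions swap at 90/270
  expect_identical(dim(rotate_raster(random_raster(5, 8), 90)),
                   c(8L, 5L, 3L))
  expect_error(rotate_raster(r, 45), class = "wsitriage_param_error")
})

test_that("mirroring is an involution with the documented axes", {
  r <- random_raster()
  expect_identical(mirror_raster(r, "none"), r)
  expect_identical(mirror_raster(mirror_raster(r, "horizontal"),
                                 "horizontal"), r)
  expect_identical(mirror_raster(mirror_raster(r, "vertical"),
                                 "vertical"), r)
  ab <- array(rep(c(0.1, 0.9), each = 1), dim = c(1, 2, 1))[, , c(1, 1, 1),
                                                            drop = FALSE]
  flipped <- mirror_raster(ab, "horizontal")
  expect_equal(flipped[1, , 1], c(0.9, 0.1))
  expect_error(mirror_raster(r, "diagonal"),
               class = "wsitriage_param_error")
})

test_that("geometric augmentations permute pixels", {
  r <- random_raster(9, 14)
  for (op in list(function(x) rotate_raster(x, 90),
                  function(x) rotate_raster(x, 180),
                  function(x) mirror_raster(x, "horizontal"),
                  function(x) mirror_raster(x, "vertical"))) {
    expect_identical(sort(as.numeric(op(r))), sort(as.numeric(r)))
  }
})

test_that("contrast shifts about the image mean and clips", {
  r <- random_raster()
  expect_equal(adjust_contrast(r, 1.0), r)
  const <- gray_raster(value = 0.37)
  expect_equal(adjust_contrast(const, 1.3), const)
  # {0.2, 0.6} at factor 1.3 -> {0.14, 0.66}
  two <- array(0, dim = c(1, 2, 3)); two[1, 1, ] <- 0.2; two[1, 2, ] <- 0.6
  out <- adjust_contrast(two, 1.3)
  expect_equal(out[1, 1, 1], 0.14)
  expect_equal(out[1, 2, 1], 0.66)
  expect_error(adjust_contrast(r, 0), class = "wsitriage_param_error")
})

test_that("brightness scales and clips", {
  r <- random_raster()
  expect_equal(adjust_brightness(r, 1.0), r)
  expect_equal(adjust_brightness(gray_raster(value = 1), 0.7),
               gray_raster(value = 0.7))
  expect_equal(adjust_brightness(gray_raster(value = 0.9), 1.3),
               gray_raster(value = 1))
})

test_that("RGB/H&E transforms are mutual inverses", {
  r <- random_raster(20, 20, seed = 11) * 0.98 + 0.01
  back <- he_to_rgb(rgb_to_he(r))
  expect_lt(max(abs(back - r)), 1 / 255)
  # background pixel maps to ~zero concentrations
  conc <- rgb_to_he(gray_raster(2, 2, value = 1))
  expect_lt(max(abs(conc[, , 1:2])), 1e-5)
  # forward-model oracle: synthesize a pixel from known concentrations
  sm <- stain_model()
  ch <- 0.4; ce <- 0.25
  od <- sm$m %*% c(ch, ce, 0)
  px <- array(rep(10^(-od), each = 1), dim = c(1, 1, 3))
  rec <- rgb_to_he(px, sm)
  expect_equal(rec[1, 1, 1], ch, tolerance = 1e-5)
  expect_equal(rec[1, 1, 2], ce, tolerance = 1e-5)
  expect_error(stain_model(eosin = c(0.650, 0.704, 0.286)),
               class = "wsitriage_config_error")
})

test_that("H&E color augmentation shifts concentrations as scalars", {
  r <- plausible_he_raster(15, 15, seed = 6)
  expect_lt(max(abs(he_color_augment(r, 0, 0) - r)), 1 / 255)
  # +0.05 on hematoxylin raises the recovered concentration by 0.05
  conc0 <- rgb_to_he(r)
  aug <- he_color_augment(r, 0.05, 0)
  conc1 <- rgb_to_he(aug)
  expect_equal(conc1[, , 1], conc0[, , 1] + 0.05, tolerance = 1e-4)
  expect_equal(conc1[, , 2], conc0[, , 2], tolerance = 1e-4)
  # white background stays white under non-positive deltas
  white <- gray_raster(3, 3, value = 1)
  expect_equal(he_color_augment(white, -0.05, -0.02), white,
               tolerance = 1 / 255)
  expect_error(he_color_augment(r, 0.2, 0),
               class = "wsitriage_param_error")
})

test_that("gaussian noise has the configured moments", {
  base <- gray_raster(522, 775, value = 0.5)
  expect_identical(add_gaussian_noise(base, 0), base)
  noisy <- add_gaussian_noise(base, 0.1, seed = 19)
  pert <- noisy - base
  expect_lt(abs(mean(pert)), 0.002)      # CLT bound at n ~ 1.2M
  expect_gt(stats::sd(pert), 0.095)      # chi-square band; clipping
  expect_lt(stats::sd(pert), 0.105)      # negligible at mid-gray
  expect_identical(noisy, add_gaussian_noise(base, 0.1, seed = 19))
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("gaussian blur conserves mass and fixes constants", {
  r <- random_raster(30, 40, seed = 23)
  expect_identical(gaussian_blur(r, 0), r)
  const <- gray_raster(20, 20, value = 0.42)
  expect_equal(gaussian_blur(const, 1.5), const, tolerance = 1e-12)
  # single bright pixel: output mass equals input mass
  spark <- array(0, dim = c(25, 25, 3))
  spark[13, 13, ] <- 1
  for (radius in c(0.1, 1, 3)) {
    out <- gaussian_blur(spark, radius)
    expect_equal(sum(out), sum(spark), tolerance = 1e-6)
  }
  # boundary pixel mass is also conserved (reflective extension)
  spark[13, 13, ] <- 0; spark[1, 1, ] <- 1
  expect_equal(sum(gaussian_blur(spark, 2)), 3, tolerance = 1e-6)
})

test_that("the joint augmentation is seeded and range-preserving", {
  r <- plausible_he_raster(20, 31, seed = 2)
  cfg <- augmentation_config()
  a <- augment_tile(r, cfg, seed = 5)
  b <- augment_tile(r, cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, augment_tile(r, cfg, seed = 6)))
  expect_true(all(a >= 0 & a <= 1))
  # degenerate configuration collapses to the identity
  id_cfg <- augmentation_config(
    rotation_angles = 0L, mirror_choices = "none",
    contrast_range = c(1, 1), brightness_range = c(1, 1),
    he_delta_range = c(0, 0), noise_sigma = 0, blur_radius = 0
  )
  expect_equal(augment_tile(r, id_cfg, seed = 1), r, tolerance = 1 / 255)
})
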