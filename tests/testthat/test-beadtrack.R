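test_that("ring synthesis places the outer ring where declared", {
  im <- synthesize_ring_image(outer_radius = 20, noise_sd = 0)
  ctr <- im$truth$centre
  prof <- im$image[round(ctr[2]), ]
  right <- prof[seq(ceiling(ctr[1]), length(prof))]
  peak <- which.max(right) + ceiling(ctr[1]) - 1 - ctr[1]
  expect_equal(peak, 20, tolerance = 0.1)
  # determinism under a seed
  i1 <- synthesize_ring_image(20, seed = 4, noise_sd = 5)
  i2 <- synthesize_ring_image(20, seed = 4, noise_sd = 5)
  expect_identical(i1$image, i2$image)
  # ring exceeding the frame is rejected
  expect_error(synthesize_ring_image(40, size = 64), "fit")
  expect_error(synthesize_ring_image(2, width = 2), "3 ring widths")
})

test_that("outer ring radius is sub-pixel accurate across radii", {
  for (r in c(10, 16, 24, 32, 40)) {
    im <- synthesize_ring_image(outer_radius = r, noise_sd = 0)
    est <- outer_ring_radius(im)
    expect_lt(abs(est$radius_px - r), 0.1)
  }
})

test_that("radius estimate is invariant to intensity scaling and offset", {
  im <- synthesize_ring_image(outer_radius = 18, seed = 9, noise_sd = 2)
  base <- outer_ring_radius(im)$radius_px
  im2 <- im
  im2$image <- 7.5 * im$image + 40
  expect_equal(outer_ring_radius(im2)$radius_px, base, tolerance = 1e-6)
})

test_that("radius RMSE stays below 0.2 px at 10% noise (100 seeds)", {
  errs <- vapply(1:100, function(s) {
    im <- synthesize_ring_image(outer_radius = 20, seed = s, noise_sd = 10,
                                contrast = 100)
    outer_ring_radius(im)$radius_px - 20
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.2)
})

test_that("ring-free images fail detection rather than returning zero", {
  flat <- matrix(10, 64, 64)
  expect_error(outer_ring_radius(flat, centre = c(32, 32)),
               class = "poroflow_no_rings")
})

test_that("piezo calibration is recovered from staircase data", {
  z <- seq(0, 2, by = 0.25)
  radii <- (z - 0.1) / 0.05
  cal <- calibrate(radii, z)
  expect_equal(cal$slope_um_px, 0.05, tolerance = 1e-12)
  expect_equal(cal$intercept_um, 0.1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_error(calibrate(radii[1:2], z[1:2]), "3 paired")
  expect_error(calibrate(rep(5, 5), z[1:5]), "monotone|[Dd]egenerate")
  expect_error(calibrate(rep(5, 9), z), "[Dd]egenerate")
  # noisy staircase: slope within 10% (Monte-Carlo)
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    calibrate(radii + rnorm(length(radii), sd = 0.1), z)$slope_um_px
  }, numeric(1))
  expect_lt(abs(median(slopes) / 0.05 - 1), 0.1)
})

test_that("tracking a synthetic stack recovers z(t) within 20 nm RMSE", {
  cal <- structure(list(slope_um_px = 0.05, intercept_um = 0,
                        r_squared = 1, n = 9), class = "ring_calibration")
  z_true <- 1 + seq(0, 0.4, length.out = 12)   # 1 um offset, 400 nm ramp
  stack <- gen_ring_stack(z_true, cal, seed = 21, noise_sd = 5,
                          size = 91, width = 2, contrast = 100)
  tr <- track_stack(stack, cal, dt = 0.1)
  expect_false(any(tr$gap))
  rmse <- sqrt(mean((tr$z_um - (z_true - z_true[1]))^2))
  expect_lt(rmse, 0.020)
  # constant-radius stack: flat trace at zero (up to noise)
  stack2 <- gen_ring_stack(rep(1, 6), cal, seed = 3, noise_sd = 2,
                           size = 91)
  tr2 <- track_stack(stack2, cal)
  expect_lt(max(abs(tr2$z_um)), 0.02)
})

test_that("stacks with mostly blank frames fail loudly", {
  cal <- structure(list(slope_um_px = 0.05, intercept_um = 0,
                        r_squared = 1, n = 5), class = "ring_calibration")
  good <- synthesize_ring_image(20, noise_sd = 0)
  blank <- matrix(10, nrow(good$image), ncol(good$image))
  stack <- list(good, blank, blank, blank, blank)
  expect_error(track_stack(stack, cal, centre = good$truth$centre),
               "half")
  # a minority of blanks is carried as gaps, not interpolated
  stack2 <- list(good, good, blank, good)
  tr <- track_stack(stack2, cal, centre = good$truth$centre)
  expect_equal(sum(tr$gap), 1)
  expect_true(is.na(tr$z_um[3]))
})
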