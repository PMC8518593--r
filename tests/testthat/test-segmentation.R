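test_that("noiseless movies segment to the exact support", {
  m <- lith_model(a = 3, b = 2, max_thickness = 0.8)
  mv <- render_movie(m, dissolution_scenario(v = 0.05, frame_interval = 2),
                     pixel_size = 0.1, dim = c(96, 96))
  masks <- segment_stack(mv$stack)
  expect_identical(masks$masks[, , 1], mv$truth$thickness > 0)
  expect_equal(masks$areas[1], sum(mv$truth$thickness > 0) * 0.01)
})

test_that("an empty movie raises a no-lith error", {
  cfg <- acquisition_config(2, 0.1)
  flat <- image_stack(array(0, c(32, 32, 3)), cfg)
  expect_error(segment_stack(flat), "no contrast|no lith")
  set.seed(3)
  noisy <- image_stack(array(rnorm(32 * 32 * 4, 0, 0.01), c(32, 32, 4)), cfg)
  expect_error(segment_stack(noisy), "no lith")
})

test_that("noisy frame-0 area is within 5% of the true support", {
  m <- placolith_model()
  for (seed in 1:5) {
    mv <- render_movie(m, dissolution_scenario(v = 0.056, frame_interval = 0.5,
                                               noise_sigma = 0.1, seed = seed),
                       pixel_size = 0.1, dim = c(128, 128))
    masks <- segment_stack(mv$stack)
    a_true <- sum(mv$truth$thickness > 0) * 0.01
    expect_lt(abs(masks$areas[1] - a_true) / a_true, 0.05)
  }
})

test_that("segmentation is invariant to positive intensity rescaling", {
  mv <- render_movie(placolith_model(),
                     dissolution_scenario(v = 0.056, frame_interval = 1,
                                          noise_sigma = 0.05, seed = 4),
                     pixel_size = 0.1, dim = c(96, 96))
  m1 <- segment_stack(mv$stack)
  scaled <- image_stack(mv$stack$frames * 37.5, mv$stack$config)
  m2 <- segment_stack(scaled)
  expect_identical(m1$masks, m2$masks)
})

test_that("masks of nested noiseless supports are nested", {
  mv <- render_movie(placolith_model(),
                     dissolution_scenario(v = 0.056, frame_interval = 2),
                     pixel_size = 0.1, dim = c(128, 128))
  masks <- segment_stack(mv$stack)$masks
  for (k in 2:dim(masks)[3])
    expect_true(all(!masks[, , k] | masks[, , k - 1]))
})

test_that("radius series: r_eff formula, lag and end detection", {
  # r_eff = sqrt(area / pi) identity on a constructed mask
  arr <- array(FALSE, c(64, 64, 3))
  arr[20:40, 20:40, 1:2] <- TRUE
  ms <- make_mask_stack(arr)
  s <- radius_series(ms)
  expect_equal(s$r_eff, sqrt(ms$areas / pi))
  expect_equal(sqrt(78.53982 / pi), 5, tolerance = 1e-6)
  expect_equal(s$end_time, 4)  # first empty frame at index 2 (t = 4)

  # constant-area movie: no onset, flagged
  arr2 <- array(FALSE, c(64, 64, 4)); arr2[20:40, 20:40, ] <- TRUE
  s2 <- radius_series(make_mask_stack(arr2))
  expect_true(is.na(s2$lag_time))
  expect_equal(s2$status, "no-onset")

  # never-empty but shrinking: incomplete
  arr3 <- arr2; arr3[, , 3:4] <- FALSE; arr3[25:30, 25:30, 3:4] <- TRUE
  expect_equal(radius_series(make_mask_stack(arr3))$status, "incomplete")
})

test_that("onset lag is recovered within one frame on synthetic scenarios", {
  m <- lith_model(a = 2.5, b = 2.5, max_thickness = 0.5)
  mv <- render_movie(m, dissolution_scenario(v = 0.2, frame_interval = 0.5,
                                             lag_time = 2.5),
                     pixel_size = 0.1, dim = c(80, 80))
  s <- radius_series(segment_stack(mv$stack))
  expect_lt(abs(s$lag_time - 2.5), 0.5 + 1e-9)
})

test_that("lith length matches the brute-force Feret oracle", {
  cfg <- acquisition_config(2, 0.1)

  # 5 um-radius disk: length 10 um within a pixel
  h <- make_lith(lith_model(a = 5, b = 5, max_thickness = 1,
                            profile = "uniform"), 0.1, c(128, 128))
  expect_equal(lith_length(h > 0, cfg), 10, tolerance = 0.1 / 10 * 2)

  # one-pixel mask degenerates to the pixel size
  m1 <- matrix(FALSE, 16, 16); m1[8, 8] <- TRUE
  expect_equal(lith_length(m1, cfg), 0.1)

  # ellipse a = 3, b = 2: length 6 um, against the pairwise-distance oracle
  he <- make_lith(lith_model(a = 3, b = 2, max_thickness = 1,
                             profile = "uniform"), 0.1, c(96, 96))
  expect_equal(lith_length(he > 0, cfg), 6, tolerance = 0.1 / 6 * 2)
  expect_equal(lith_length(he > 0, cfg), brute_feret(he > 0, 0.1))

  expect_error(lith_length(matrix(FALSE, 4, 4), cfg), "empty")
})

test_that("r_eff of synthetic movies is non-increasing and reaches zero", {
  for (seed in 1:3) {
    mv <- render_movie(placolith_model(),
                       dissolution_scenario(v = 0.056, frame_interval = 1,
                                            noise_sigma = 0.08, seed = seed),
                       pixel_size = 0.1, dim = c(96, 96))
    s <- radius_series(segment_stack(mv$stack))
    # allow one frame of noise jitter
    jitter_ok <- diff(s$r_eff) <= 0.05 * max(s$r_eff)
    expect_true(all(jitter_ok))
    expect_equal(s$r_eff[length(s$r_eff)], 0)
  }
})
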