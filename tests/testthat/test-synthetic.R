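test_that("discretized lith volumes match closed forms and quadrature", {
  # uniform cylinder: V = pi r^2 h
  m <- lith_model(a = 5, b = 5, max_thickness = 1, profile = "uniform")
  h <- make_lith(m, pixel_size = 0.1, dim = c(128, 128))
  expect_equal(sum(h) * 0.01, pi * 25 * 1, tolerance = 0.01)

  # zero-thickness model
  m0 <- lith_model(a = 3, b = 3, max_thickness = 0, profile = "uniform")
  expect_true(all(make_lith(m0, 0.1, c(96, 96)) == 0))

  # placolith profile: discrete sum vs independent quadrature of the profile
  mp <- lith_model(a = 4, b = 3, max_thickness = 1.2, centre_fraction = 0.25,
                   power = 2, rim_peak = 0.7, edge_fraction = 0.2)
  prof <- function(u) {
    inner <- 0.25 + 0.75 * (u / 0.7)^2
    outer <- 1 - 0.8 * ((u - 0.7) / 0.3)^2
    1.2 * ifelse(u <= 0.7, inner, outer)
  }
  v_quad <- 2 * pi * 4 * 3 * integrate(function(u) u * prof(u), 0, 1)$value
  hp <- make_lith(mp, 0.1, c(128, 128))
  expect_equal(sum(hp) * 0.01, v_quad, tolerance = 0.01)
  expect_equal(lith_volume(mp), v_quad, tolerance = 1e-6)

  # volume conservation at fine pixels (<= 0.2 um)
  for (px in c(0.2, 0.1)) {
    hh <- make_lith(mp, px, dim = c(ceiling(10 / px), ceiling(10 / px)))
    expect_equal(sum(hh) * px^2, v_quad, tolerance = 0.01)
  }

  expect_error(make_lith(lith_model(a = 50, b = 50, max_thickness = 1), 0.1,
                         c(64, 64)), "does not fit")
})

test_that("erosion removes v*dt from the top face and the lateral boundary", {
  m <- lith_model(a = 4, b = 4, max_thickness = 1, profile = "uniform")
  h <- make_lith(m, 0.1, c(128, 128))

  e <- erode_lith(h, v = 0.1, dt = 1)
  interior <- EBImage::distmap(h > 0) > 3
  expect_true(all(abs(e[interior] - 0.9) < 1e-12))

  # clipping at zero
  h2 <- h; h2[h2 > 0] <- 0.05
  attributes(h2) <- attributes(h)
  expect_true(all(erode_lith(h2, 0.1, 1) == 0))

  # lateral regime (thickness not limiting): support radius shrinks by v*dt
  mt <- lith_model(a = 4, b = 4, max_thickness = 5, profile = "uniform")
  ht <- make_lith(mt, 0.1, c(128, 128))
  e2 <- erode_lith(ht, v = 0.5, dt = 2)   # 1 um retreat
  r_before <- sqrt(sum(ht > 0) * 0.01 / pi)
  r_after <- sqrt(sum(e2 > 0) * 0.01 / pi)
  expect_equal(r_before - r_after, 1, tolerance = 0.1)

  expect_error(erode_lith(h, 0.1, -1), "negative")
})

test_that("erosion is monotone: volumes non-increasing, supports nested", {
  mv <- render_movie(placolith_model(),
                     dissolution_scenario(v = 0.056, frame_interval = 2),
                     pixel_size = 0.1, dim = c(128, 128))
  vols <- mv$truth$frame_volumes
  expect_true(all(diff(vols) <= 1e-12))
  expect_equal(vols[length(vols)], 0)
  sup_prev <- NULL
  for (k in seq_len(dim(mv$stack$frames)[3])) {
    sup <- mv$stack$frames[, , k] > 1e-9
    if (!is.null(sup_prev)) expect_true(all(!sup | sup_prev))
    sup_prev <- sup
  }
})

test_that("rendering is deterministic per seed and honours lag and duration", {
  m <- lith_model(a = 2.5, b = 2, max_thickness = 0.5)
  sc <- function(seed) dissolution_scenario(v = 0.1, frame_interval = 1,
                                            lag_time = 3, noise_sigma = 0.05,
                                            seed = seed)
  a <- render_movie(m, sc(11), pixel_size = 0.1, dim = c(80, 80))
  b <- render_movie(m, sc(11), pixel_size = 0.1, dim = c(80, 80))
  d <- render_movie(m, sc(12), pixel_size = 0.1, dim = c(80, 80))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_false(identical(a$stack$frames, d$stack$frames))
  # noise is the only difference between seeds
  expect_identical(a$truth$thickness, d$truth$thickness)
  expect_identical(a$truth$frame_volumes, d$truth$frame_volumes)

  # frames before lag are static
  expect_identical(a$truth$frame_volumes[1:3],
                   rep(a$truth$frame_volumes[1], 3))

  # duration covers lag + max thickness / v, and the movie ends empty
  n <- dim(a$stack$frames)[3]
  expect_gte((n - 1) * 1, 3 + 0.5 / 0.1)
  expect_equal(a$truth$frame_volumes[n], 0)
})

test_that("noise-free frame-0 support area is exact", {
  m <- lith_model(a = 3, b = 2, max_thickness = 0.8)
  mv <- render_movie(m, dissolution_scenario(v = 0.05, frame_interval = 2),
                     pixel_size = 0.1, dim = c(96, 96))
  sup0 <- mv$stack$frames[, , 1] > 0
  expect_identical(sup0, mv$truth$thickness > 0)
})

test_that("a thin disk shows the two-regime effective-radius decay", {
  mv <- render_movie(thin_disk_model(),
                     dissolution_scenario(v = 0.0125, frame_interval = 2),
                     pixel_size = 0.05, dim = c(224, 224))
  fit <- fit_two_regimes(radius_series(segment_stack(mv$stack)))
  expect_gt(fit$v_terminal, fit$v_initial)
  expect_gt(fit$v_terminal / fit$v_initial, 5)  # collapse is much faster
})
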