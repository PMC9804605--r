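test_that("midpoint displacement honours the grid, seed and amplitude contracts", {
  p <- sim_params(hurst = 0.5, level = 5, seed = 42)
  hm <- midpoint_displacement(p)
  expect_s3_class(hm, "heightmap")
  expect_equal(dim(hm), c(33L, 33L))

  # identical params + seed => identical surface
  expect_identical(midpoint_displacement(p)$heights, hm$heights)
  # different seed => different surface
  expect_false(identical(
    midpoint_displacement(sim_params(0.5, 5, seed = 43))$heights, hm$heights))

  # zero-noise case: perfectly flat
  flat <- midpoint_displacement(sim_params(0.5, 4, rms_amplitude = 0,
                                           seed = 1))
  expect_true(all(flat$heights == flat$heights[1, 1]))

  # allocation guard names the requested size
  expect_error(midpoint_displacement(sim_params(0.5, 15, seed = 1)),
               "32769")
})

test_that("simulated surfaces recover their nominal Hurst exponent from increment variances", {
  # Increment-variance ratios across lags estimate 2H. Both generators are
  # standard approximations of fBm with known systematic deviations
  # (diamond-square runs rough at high H, the cropped spectral field smooth
  # at low H), so the oracle asserts a fixed 0.15 band plus strict
  # monotonicity rather than pure Monte-Carlo error; see the methods
  # vignette.
  hs <- c(0.3, 0.5, 0.7)
  h_mpd <- vapply(hs, function(H) {
    increment_hurst(function(s) mpd_map(H, 7, s)$heights, n_seeds = 100)
  }, numeric(1))
  expect_true(all(abs(h_mpd - hs) < 0.15))
  expect_true(all(diff(h_mpd) > 0))

  h_spec <- vapply(hs, function(H) {
    increment_hurst(function(s)
      spectral_fbm_surface(sim_params(H, 7, seed = s), 129)$heights,
      n_seeds = 60)
  }, numeric(1))
  expect_true(all(abs(h_spec - hs) < 0.15))
  expect_true(all(diff(h_spec) > 0))
})

test_that("spectral surfaces have the fBm power-law spectrum", {
  # radial periodogram slope should be -(2H + 2)
  for (H in c(0.5, 0.99)) {
    slopes <- vapply(1:5, function(s)
      radial_spectrum_slope(spectral_fbm_surface(sim_params(H, 9, seed = s),
                                                 size = 257)),
      numeric(1))
    expect_equal(mean(slopes), -(2 * H + 2), tolerance = 0.08)
  }
  # determinism
  a <- spectral_fbm_surface(sim_params(0.5, 5, seed = 9), 33)
  b <- spectral_fbm_surface(sim_params(0.5, 5, seed = 9), 33)
  expect_identical(a$heights, b$heights)
  expect_error(spectral_fbm_surface(sim_params(0.5, 5, seed = 9), 1),
               ">= 3")
})

test_that("binarize thresholds correctly and flags degenerate outputs", {
  # checkerboard with a fixed threshold between the two values
  cb <- matrix(rep(c(0, 1), length.out = 16 * 16), 16, 16)
  bm <- binarize(heightmap(cb), rule = "fixed", value = 0.5)
  expect_identical(bm$cells, matrix(as.integer(cb), 16, 16))

  # flat surface: everything one class, complementary class empty
  flat <- analytic_fixture("flat", size = 8)
  b <- binarize(flat, "median")
  expect_true(all(b$cells == 1L))
  expect_true(isTRUE(attr(level_set_boundary(b), "empty")))

  # median rule splits a continuous surface in half
  hm <- mpd_map(0.5, 7, seed = 3)
  frac <- mean(binarize(hm, "median")$cells)
  expect_lt(abs(frac - 0.5), 1 / nrow(hm$heights))
})

test_that("level-set boundaries follow the 4-neighbour definition", {
  # solid filled square: boundary is its one-cell perimeter
  sq <- matrix(0L, 9, 9)
  sq[3:7, 3:7] <- 1L
  bd <- level_set_boundary(binary_map(sq))
  expected <- sq
  expected[4:6, 4:6] <- 0L   # interior hollowed out, perimeter retained
  expect_identical(bd$cells, expected)

  # a single isolated cell is its own boundary
  one <- matrix(0L, 5, 5)
  one[3, 3] <- 1L
  expect_identical(level_set_boundary(binary_map(one))$cells, one)

  # rougher surfaces have denser coastlines
  dens <- vapply(c(0.3, 0.8), function(H) {
    mean(vapply(1:6, function(s)
      mean(level_set_boundary(binarize(mpd_map(H, 7, 400 + s),
                                       "median"))$cells),
      numeric(1)))
  }, numeric(1))
  expect_gt(dens[1], dens[2])

  # boundary of a boundary stays within the 4-neighbourhood closure of the
  # original boundary
  b1 <- level_set_boundary(binarize(mpd_map(0.5, 6, 11), "median"))
  b2 <- level_set_boundary(b1)
  closure <- b1$cells
  n <- nrow(closure)
  closure[-1, ] <- pmax(closure[-1, ], b1$cells[-n, ])
  closure[-n, ] <- pmax(closure[-n, ], b1$cells[-1, ])
  closure[, -1] <- pmax(closure[, -1], b1$cells[, -n])
  closure[, -n] <- pmax(closure[, -n], b1$cells[, -1])
  expect_true(all(closure[b2$cells == 1L] == 1L))
})

test_that("Koch rasters have the right combinatorics and guard rails", {
  for (it in 1:4)
    expect_length(habcomplex:::koch_segments(it)$x0, 4^it)
  km <- koch_curve_raster(1, 128)
  expect_s3_class(km, "binary_map")
  expect_equal(dim(km), c(128L, 128L))
  expect_gt(sum(km$cells), 0)
  expect_error(koch_curve_raster(6, 256), "minimum")
  # deterministic: no RNG involved
  expect_identical(koch_curve_raster(3, 256)$cells,
                   koch_curve_raster(3, 256)$cells)
})

test_that("analytic fixtures match their closed forms", {
  expect_true(all(analytic_fixture("flat", 16, height = 2)$heights == 2))

  th <- 30 * pi / 180
  ip <- analytic_fixture("inclined_plane", 33, cell_size = 0.5, angle = 30)
  # column-to-column rise equals tan(theta) * cell_size
  expect_equal(unique(round(diff(ip$heights[1, ]), 12)),
               round(tan(th) * 0.5, 12))

  st <- analytic_profile("sawtooth", n = 9, spacing = 1, amplitude = 2,
                         period = 2)
  expect_equal(st$heights, rep(c(0, 2), length.out = 9))

  hs <- analytic_fixture("hemisphere", 65)
  ctr <- which(hs$heights == max(hs$heights), arr.ind = TRUE)[1, ]
  expect_true(all(abs(ctr - 33) <= 1))
  expect_error(analytic_fixture("inclined_plane", 16, angle = 95), "90")

  wm <- weierstrass_profile(0.5, n = 257)
  expect_s3_class(wm, "profile1d")
  expect_length(wm$heights, 257)
})
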