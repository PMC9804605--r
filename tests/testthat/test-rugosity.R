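test_that("surface and profile rugosity match closed-form geometry", {
  expect_equal(surface_rugosity(analytic_fixture("flat", 17))$r_value, 1)

  ip <- analytic_fixture("inclined_plane", 65, angle = 30)
  expect_equal(surface_rugosity(ip)$r_value, 1 / cos(30 * pi / 180),
               tolerance = 1e-6)

  expect_equal(profile_rugosity(analytic_profile("flat", 20))$r_value, 1)
  # sampled inclined line
  lp <- analytic_profile("inclined", n = 50, spacing = 0.5, angle = 40)
  expect_equal(profile_rugosity(lp)$r_value, 1 / cos(40 * pi / 180),
               tolerance = 1e-9)
  # sawtooth sampled at half-period spacing
  st <- analytic_profile("sawtooth", n = 21, spacing = 1, amplitude = 1.5,
                         period = 2)
  expect_equal(profile_rugosity(st)$r_value, sqrt(1 + 1.5^2),
               tolerance = 1e-9)

  # invariant r_value = A / planar to machine precision
  hm <- mpd_map(0.4, 6, 2)
  r <- surface_rugosity(hm)
  expect_equal(r$r_value, r$surface_area / r$planar_area, tolerance = 1e-12)
})

test_that("rugosity never drops below 1 (projection inequality)", {
  for (s in 1:10) {
    hm <- mpd_map(runif(1, 0.1, 0.9), 6, s)
    expect_gte(surface_rugosity(hm)$r_value, 1 - 1e-12)
    expect_gte(profile_rugosity(profile1d(hm$heights[5, ], 1))$r_value,
               1 - 1e-12)
  }
})

test_that("plane-of-best-fit correction removes tilt, nothing else", {
  for (ang in c(10, 30, 60)) {
    ip <- analytic_fixture("inclined_plane", 33, angle = ang)
    expect_equal(slope_corrected_rugosity(ip)$r_value, 1, tolerance = 1e-6)
  }
  flat <- analytic_fixture("flat", 33)
  expect_equal(slope_corrected_rugosity(flat)$r_value,
               surface_rugosity(flat)$r_value)

  # tilt invariance on rough surfaces (statistical)
  for (s in 1:5) {
    hm <- mpd_map(0.5, 7, 300 + s)
    n <- nrow(hm$heights)
    tilt <- rep((seq_len(n) - 0.5) * tan(20 * pi / 180), each = n)
    tilted <- heightmap(hm$heights + tilt, hm$cell_size)
    r0 <- slope_corrected_rugosity(hm)$r_value
    r1 <- slope_corrected_rugosity(tilted)$r_value
    expect_equal(r1, r0, tolerance = 0.01)
  }
})

test_that("coarsening monotonically erodes rugosity", {
  flat <- analytic_fixture("flat", 64)
  rs <- multiresolution_rugosity(flat, c(1, 2, 4, 8))
  expect_true(all(vapply(rs, `[[`, 1, "r_value") == 1))

  for (s in 1:5) {
    hm <- mpd_map(0.3, 7, 40 + s)
    rv <- vapply(multiresolution_rugosity(hm, c(1, 2, 4, 8, 16)),
                 `[[`, 1, "r_value")
    expect_true(all(diff(rv) <= 1e-9))
  }

  hm <- mpd_map(0.5, 6, 3)
  expect_equal(multiresolution_rugosity(hm, 1)[[1]]$r_value,
               surface_rugosity(hm)$r_value)
  # grains record the physical grain
  expect_equal(multiresolution_rugosity(hm, c(1, 4))[[2]]$grain,
               4 * hm$cell_size)
  expect_error(multiresolution_rugosity(hm, 128), "larger than map")
})

test_that("row-wise and column-wise profile rugosity agree on isotropic relief", {
  rel <- vapply(1:6, function(s) {
    z <- mpd_map(0.5, 8, 500 + s)$heights
    rowm <- mean(apply(z, 1, function(r)
      profile_rugosity(profile1d(r, 1))$r_value))
    colm <- mean(apply(z, 2, function(r)
      profile_rugosity(profile1d(r, 1))$r_value))
    abs(rowm - colm) / rowm
  }, numeric(1))
  expect_lt(max(rel), 0.01)
})

test_that("area-decoupled richness regression recovers and flags", {
  # noise-free: exact recovery
  set.seed(8)
  A <- exp(rnorm(40))
  R <- exp(abs(rnorm(40, 0, 0.3)))
  S <- exp(1.5) * A^0.25 * R^0.9
  f <- suppressWarnings(area_decoupled_regression(S, A, R))
  expect_equal(unname(f$coefficients), c(0.25, 0.9, 1.5), tolerance = 1e-10)
  expect_false(f$collinear)

  # constant rugosity: b inestimable, flagged
  f2 <- suppressWarnings(
    area_decoupled_regression(S, A, rep(1, 40)))
  expect_true(f2$collinear)

  # noisy recovery within 3 SE
  set.seed(9)
  Sn <- S * exp(rnorm(40, 0, 0.2))
  fn <- area_decoupled_regression(Sn, A, R)
  expect_true(all(abs(fn$coefficients[c("a", "b")] - c(0.25, 0.9)) <=
                    3 * fn$std_errors[c("a", "b")]))

  expect_error(area_decoupled_regression(S[1:3], A[1:3], R[1:3]),
               "at least 5")
  expect_error(area_decoupled_regression(-S, A, R), "positive")
})
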