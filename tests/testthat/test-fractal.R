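test_that("box counts equal exhaustive enumeration on small maps", {
  set.seed(77)
  for (case in 1:4) {
    nr <- sample(20:64, 1)
    nc <- sample(20:64, 1)
    cells <- matrix(rbinom(nr * nc, 1, runif(1, 0.05, 0.6)), nr, nc)
    if (sum(cells) == 0) cells[1, 1] <- 1L
    bm <- binary_map(cells)
    for (e in c(2L, 3L, 5L, 8L)) {
      if (e > min(nr, nc) %/% 2L) next
      for (o in list(c(0L, 0L), c(1L, 2L), c(e - 1L, 1L))) {
        got <- box_count(bm, e, origins = matrix(o, 1))$statistic
        expect_equal(got, brute_box_count(cells, e, o[1], o[2]),
                     info = sprintf("case %d e=%d o=(%d,%d)",
                                    case, e, o[1], o[2]))
      }
    }
  }
})

test_that("box counting honours the analytic count examples", {
  # all-ones map fully covered: N = (side/eps)^2
  ones <- binary_map(matrix(1L, 128, 128))
  expect_equal(box_count(ones, 8L, origins = c(0L, 0L))$statistic, 256)

  # a single cell occupies exactly one box at any scale
  single <- matrix(0L, 64, 64)
  single[30, 41] <- 1L
  sm <- binary_map(single)
  for (e in c(2L, 4L, 16L))
    expect_equal(box_count(sm, e, n_origins = 8L, seed = 2)$statistic, 1)

  # horizontal line: mean over origins within 1 of span/eps
  line <- matrix(0L, 64, 4096)
  line[32, ] <- 1L
  lb <- binary_map(line)
  for (e in c(4L, 8L, 16L)) {
    got <- box_count(lb, e, n_origins = 32L, seed = 3)$statistic
    expect_lt(abs(got - 4096 / e), 1 + 1e-9)
  }

  # bad inputs
  expect_error(box_count(ones, 100L), "\\[1, 64\\]")
  empty <- binary_map(matrix(0L, 8, 8), allow_empty = TRUE)
  expect_error(box_count(empty, 2L), "foreground")
})

test_that("dimension fits recover exact and near-exact power laws", {
  # exact space-filling law: D = 2 to machine precision
  ones <- binary_map(matrix(1L, 256, 256))
  crv <- suppressWarnings(box_count(ones, c(2L, 4L, 8L, 16L, 32L),
                                    origins = c(0L, 0L)))
  est <- suppressWarnings(fit_dimension(crv))
  expect_equal(est$d_hat, 2, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  # smooth-curve limit: a straight line reads D = 1
  line <- matrix(0L, 2048, 2048)
  line[1000, ] <- 1L
  lcrv <- box_count(binary_map(line), c(2L, 4L, 8L), n_origins = 16L,
                    seed = 1)
  expect_equal(fit_dimension(lcrv)$d_hat, 1, tolerance = 0.05)

  # Koch anchor at reduced size: D near log(4)/log(3)
  km <- koch_curve_raster(5, 1024)
  expect_equal(intermediate_scale_rule(1024), c(8, 32))
  kcrv <- box_count(km, c(8L, 16L, 32L), n_origins = 16L, seed = 1)
  expect_equal(fit_dimension(kcrv)$d_hat, log(4) / log(3), tolerance = 0.08)

  # contract errors
  expect_error(fit_dimension(crv, scale_range = c(2, 4)), ">= 3")
})

test_that("fit diagnostics flag curvature and behave on clean fits", {
  # strongly curved scaling relation: nonlinearity flagged
  eps <- c(2, 4, 8, 16, 32, 64, 128)
  bent <- scaling_curve(eps, 1e5 * eps^(-2 + 0.4 * log(eps)) + 1,
                        "box_count")
  est_bent <- fit_dimension(bent)
  expect_true(isTRUE(est_bent$diagnostics$nonlinearity))

  # noisy but linear: nonlinearity not flagged at the default level
  set.seed(4)
  lin <- scaling_curve(eps, exp(10 - 1.4 * log(eps) + rnorm(7, 0, 0.02)),
                       "box_count")
  expect_false(isTRUE(fit_dimension(lin)$diagnostics$nonlinearity))
})

test_that("the intermediate scale window rescales the 32-128 @ 4097 rule", {
  expect_equal(intermediate_scale_rule(4097), c(32, 128))
  expect_equal(intermediate_scale_rule(1025), c(8, 32))
  expect_equal(intermediate_scale_rule(513), c(4, 16))
  expect_error(intermediate_scale_rule(32), ">= 64")
  expect_error(intermediate_scale_rule(64), "larger map")
})

test_that("the variation method matches its analytic and simulation oracles", {
  # inclined plane: oscillation scales linearly in window size, D = 2
  ip <- analytic_fixture("inclined_plane", 257, angle = 30)
  expect_equal(variation_dimension(ip, epsilons = c(2, 4, 8, 16))$d_hat, 2,
               tolerance = 0.05)

  # flat surface: dimension undefined
  expect_error(variation_dimension(analytic_fixture("flat", 33)), "flat")

  # surfaces: D = 3 - H at intermediate scales (5 seeds here; the full
  # 20-seed sweep lives in the acceptance suite)
  win <- intermediate_scale_rule(513)
  d <- vapply(1:5, function(s)
    variation_dimension(mpd_map(0.5, 9, 100 + s),
                        scale_range = win)$d_hat, numeric(1))
  expect_equal(mean(d), 2.5, tolerance = 0.1)

  # profiles: D = 2 - H
  d1 <- vapply(1:10, function(s) {
    z <- mpd_map(0.5, 9, 200 + s)$heights
    variation_dimension(profile1d(z[257, ], 1),
                        scale_range = c(4, 16))$d_hat
  }, numeric(1))
  expect_equal(mean(d1), 1.5, tolerance = 0.1)
})

test_that("oscillation sweeps agree with direct window evaluation", {
  # the doubling-ladder filter must equal a brute-force windowed max - min
  set.seed(12)
  z <- matrix(rnorm(30 * 24), 30, 24)
  crv <- variation_curve(heightmap(z), epsilons = c(1, 2, 3, 5, 8))
  brute <- vapply(c(1, 2, 3, 5, 8), function(e) {
    osc <- matrix(NA_real_, 30, 24)
    for (i in 1:30) for (j in 1:24) {
      ri <- max(1, i - e):min(30, i + e)
      cj <- max(1, j - e):min(24, j + e)
      osc[i, j] <- max(z[ri, cj]) - min(z[ri, cj])
    }
    mean(osc)
  }, numeric(1))
  expect_equal(crv$statistic, brute, tolerance = 1e-12)

  h <- rnorm(40)
  crv1 <- variation_curve(profile1d(h, 1), epsilons = c(1, 2, 4, 7))
  brute1 <- vapply(c(1, 2, 4, 7), function(e) {
    mean(vapply(seq_along(h), function(i) {
      w <- h[max(1, i - e):min(40, i + e)]
      max(w) - min(w)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(crv1$statistic, brute1, tolerance = 1e-12)
})

test_that("scaling-curve invariants hold on simulated sweeps", {
  bm <- level_set_boundary(binarize(mpd_map(0.4, 8, 5), "median"), "both")
  crv <- box_count(bm, n_origins = 8L, seed = 9)
  side <- nrow(bm$cells)
  expect_true(all(diff(crv$statistic) < 0))
  expect_true(all(crv$statistic >= 1))
  expect_true(all(crv$statistic <= (side / crv$epsilon)^2))

  vc <- variation_curve(mpd_map(0.4, 7, 6))
  expect_true(all(diff(vc$statistic) > 0))   # oscillation grows with window
})

test_that("random-origin averaging shrinks the count variance", {
  km <- koch_curve_raster(4, 512)
  n1 <- vapply(1:40, function(s)
    box_count(km, 16L, n_origins = 1L, seed = s)$statistic, numeric(1))
  n16 <- vapply(1:40, function(s)
    box_count(km, 16L, n_origins = 16L, seed = s)$statistic, numeric(1))
  expect_lt(sd(n16), sd(n1) / 2)   # expect ~1/4 for independent draws
})

test_that("fractality assessment reports decades and piecewise fits", {
  eps <- 2^(2:12)
  exact <- scaling_curve(eps, 1e7 * eps^(-1.5), "box_count")
  rep1 <- suppressWarnings(assess_fractality(exact, split = 128))
  expect_lt(rep1$d_difference, 1e-6)
  expect_equal(rep1$orders_of_magnitude, log10(4096 / 4))
  expect_true(rep1$sufficient_range)

  eps2 <- c(8, 12, 16, 24, 32, 48, 64)
  short <- scaling_curve(eps2, 1e4 * eps2^(-1.2), "box_count")
  rep2 <- suppressWarnings(assess_fractality(short, split = 20))
  expect_false(rep2$sufficient_range)

  expect_error(assess_fractality(exact, split = 1), "outside")
  expect_error(assess_fractality(short, split = 12), ">= 3")
})
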