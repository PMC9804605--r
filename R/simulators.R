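#' Simulation parameters for fractional Brownian surfaces
#'
#' @param hurst Hurst exponent H, 0 < H < 1. The true fractal dimension of
#'   the simulated surface is 3 - H; of its median level-set boundary (a
#'   planar "coastline"), 2 - H.
#' @param level grid-size exponent: the simulated grid has side 2^level + 1.
#' @param rms_amplitude initial displacement scale (length units).
#' @param seed integer RNG seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(hurst, level, rms_amplitude = 1, seed = 1L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must be a single number in (0, 1)")
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be an integer >= 1")
  if (!is.numeric(rms_amplitude) || rms_amplitude < 0)
    stop("rms_amplitude must be >= 0")
  structure(list(hurst = hurst, level = level,
                 rms_amplitude = as.numeric(rms_amplitude),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Deterministic child seeds: one root seed spawns independent per-replicate
# streams, so replicate r is reproducible in isolation. The derivation is a
# fixed 32-bit LCG hash of (root_seed, index); documented in the vignette.
child_seed <- function(root_seed, index) {
  s <- (as.double(root_seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

#' Fractional Brownian surface via midpoint displacement (diamond-square)
#'
#' Generates a self-affine Gaussian surface of known roughness by recursive
#' subdivision: at each recursion both the diamond (square-centre) and square
#' (edge-midpoint) points are set to the mean of their neighbours plus a
#' Gaussian displacement, and the displacement standard deviation is
#' multiplied by 2^(-H) at each halving of the lateral scale. Corner cells
#' are initialised to 0. The surface approximates fractional Brownian motion
#' with Hurst exponent H; its fractal dimension is 3 - H.
#'
#' @param params a [sim_params()] object.
#' @param cell_size physical cell size of the output grid.
#' @return A [heightmap()] with side 2^level + 1.
#' @examples
#' hm <- midpoint_displacement(sim_params(hurst = 0.5, level = 5, seed = 42))
#' dim(hm)  # 33 x 33
#' @export
midpoint_displacement <- function(params, cell_size = 1) {
  stopifnot(inherits(params, "sim_params"))
  n <- 2^params$level + 1
  if (n > 16385)
    stop("requested grid ", n, " x ", n,
         " exceeds the supported allocation limit (16385 x 16385)")
  z <- matrix(0, n, n)
  set.seed(params$seed)
  sdev <- params$rms_amplitude
  s <- n - 1L
  while (s >= 2L) {
    half <- s %/% 2L
    sdev <- sdev * 2^(-params$hurst)
    # diamond step: centres of all s x s squares
    r0 <- seq(1L, n - s, by = s)
    cr <- r0 + half
    k <- length(r0)
    z[cr, cr] <- (z[r0, r0] + z[r0 + s, r0] + z[r0, r0 + s] +
                    z[r0 + s, r0 + s]) / 4 +
      matrix(stats::rnorm(k * k, 0, sdev), k, k)
    # square step: edge midpoints, averaging the 3-4 in-grid neighbours at
    # distance `half`
    rows_a <- cr                      # odd multiples of half
    cols_a <- seq(1L, n, by = s)      # even multiples of half
    z[rows_a, cols_a] <- mid_neighbour_mean(z, rows_a, cols_a, half, n) +
      matrix(stats::rnorm(length(rows_a) * length(cols_a), 0, sdev),
             length(rows_a), length(cols_a))
    z[cols_a, rows_a] <- mid_neighbour_mean(z, cols_a, rows_a, half, n) +
      matrix(stats::rnorm(length(cols_a) * length(rows_a), 0, sdev),
             length(cols_a), length(rows_a))
    s <- half
  }
  heightmap(z, cell_size = cell_size)
}

# Mean over the in-grid 4-neighbourhood at offset `half` for the grid of
# points R x C (both index vectors); used by the square step.
mid_neighbour_mean <- function(z, R, C, half, n) {
  acc <- matrix(0, length(R), length(C))
  cnt <- matrix(0, length(R), length(C))
  for (d in list(c(-half, 0L), c(half, 0L), c(0L, -half), c(0L, half))) {
    Rr <- R + d[1]
    Cc <- C + d[2]
    okr <- Rr >= 1L & Rr <= n
    okc <- Cc >= 1L & Cc <= n
    acc[okr, okc] <- acc[okr, okc] + z[Rr[okr], Cc[okc], drop = FALSE]
    cnt[okr, okc] <- cnt[okr, okc] + 1
  }
  acc / cnt
}

#' Fractional Brownian surface via Fourier (spectral) synthesis
#'
#' Filters white Gaussian noise in the frequency domain with amplitude
#' |f|^-(H+1), so the radially averaged power spectrum follows a power law
#' with exponent -(2H + 2) — the spectral signature of a 2D fBm surface.
#' Synthesis happens on the enclosing power-of-two periodic grid and is
#' cropped to the requested (odd) size; the result is normalised to zero
#' mean and standard deviation `rms_amplitude`.
#'
#' @param params a [sim_params()]; its `level` field is ignored, the size
#'   comes from `size`.
#' @param size odd integer edge length >= 3.
#' @param cell_size physical cell size.
#' @return A [heightmap()] of dimension `size` x `size`.
#' @export
spectral_fbm_surface <- function(params, size, cell_size = 1) {
  stopifnot(inherits(params, "sim_params"))
  size <- as.integer(size)
  if (is.na(size) || size < 3L) stop("size must be an integer >= 3")
  m <- 2^ceiling(log2(size))
  set.seed(params$seed)
  fx <- c(0:(m / 2), -((m / 2 - 1):1)) / m
  f2 <- outer(fx^2, fx^2, "+")
  amp <- f2^(-(params$hurst + 1) / 2)
  amp[1, 1] <- 0  # no DC component
  noise <- matrix(stats::rnorm(m * m), m, m)
  z <- Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) / (m * m)
  z <- z[seq_len(size), seq_len(size)]
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0 && params$rms_amplitude > 0) z <- z * params$rms_amplitude / s
  heightmap(z, cell_size = cell_size)
}

#' Threshold a heightmap into a binary map
#'
#' Cells with height >= threshold become foreground (1). Bridges simulated
#' surfaces to the binary planar sets that box-counting consumes.
#'
#' @param map a [heightmap()] without nodata.
#' @param rule "median", "mean", or "fixed".
#' @param value threshold when `rule = "fixed"`.
#' @return A [binary_map()]; all-one-class results are allowed and flagged
#'   via the `empty` attribute on the complementary class being absent.
#' @export
binarize <- function(map, rule = c("median", "mean", "fixed"), value = NULL) {
  stopifnot(inherits(map, "heightmap"))
  rule <- match.arg(rule)
  z <- map$heights
  if (all(is.na(z))) stop("cannot binarize an all-nodata heightmap")
  thr <- switch(rule,
                median = stats::median(z, na.rm = TRUE),
                mean   = mean(z, na.rm = TRUE),
                fixed  = {
                  if (is.null(value)) stop("rule = 'fixed' needs a value")
                  value
                })
  cells <- ifelse(is.na(z), 0L, as.integer(z >= thr))
  binary_map(cells, cell_size = map$cell_size, allow_empty = TRUE)
}

#' Extract the level-set boundary of a binary map
#'
#' With `sides = "inner"` (default) the output foreground is the one-cell
#' inner perimeter: input foreground cells with at least one 4-neighbour of
#' the opposite class (map-edge cells are compared only against in-grid
#' neighbours). With `sides = "both"` cells of either class adjacent to the
#' interface are marked; this two-cell-thick version is the faithful
#' pixel discretization of the continuous level curve (every box crossed by
#' the curve contains a marked cell) and is what the estimator-bias study
#' box-counts. For a median-thresholded fBm surface the boundary is the
#' "coastline" whose fractal dimension is 2 - H.
#'
#' @param map a [binary_map()].
#' @param sides "inner" or "both"; see above.
#' @return A [binary_map()]; an empty boundary (uniform input) is returned
#'   flagged with attribute `empty = TRUE`.
#' @export
level_set_boundary <- function(map, sides = c("inner", "both")) {
  stopifnot(inherits(map, "binary_map"))
  sides <- match.arg(sides)
  m <- map$cells
  nr <- nrow(m)
  nc <- ncol(m)
  differs <- matrix(FALSE, nr, nc)
  differs[-nr, ] <- differs[-nr, ] | (m[-nr, ] != m[-1, ])
  differs[-1, ]  <- differs[-1, ]  | (m[-1, ]  != m[-nr, ])
  differs[, -nc] <- differs[, -nc] | (m[, -nc] != m[, -1])
  differs[, -1]  <- differs[, -1]  | (m[, -1]  != m[, -nc])
  keep <- if (sides == "inner") differs & m == 1L else differs
  binary_map(ifelse(keep, 1L, 0L), cell_size = map$cell_size,
             allow_empty = TRUE)
}

#' Rasterized Koch curve
#'
#' Iterates the classic Koch construction (each segment replaced by four of a
#' third the length) and draws the resulting 4^iterations segments onto a
#' binary grid with threshold-free line drawing: every cell the ideal segment
#' passes through is set. The analytic dimension of the limiting curve is
#' log 4 / log 3 (about 1.26).
#'
#' @param iterations number of Koch iterations >= 1.
#' @param raster_size edge length of the square raster in cells; the
#'   smallest segment must span at least 2 cells.
#' @param margin background border (cells) left around the curve, default
#'   `raster_size / 16`. Box-counting excludes boxes straddling the map
#'   edge, so the measured set must sit inside the grid with room at least
#'   one box size wide; the margin guarantees that for box sizes up to its
#'   width.
#' @return A square [binary_map()] of side `raster_size` containing the
#'   curve, centred, spanning `raster_size - 2 * margin` cells.
#' @examples
#' km <- koch_curve_raster(3, 128)
#' @export
koch_curve_raster <- function(iterations, raster_size,
                              margin = raster_size %/% 16L) {
  iterations <- as.integer(iterations)
  raster_size <- as.integer(raster_size)
  if (iterations < 1L) stop("iterations must be >= 1")
  span <- raster_size - 2L * as.integer(margin)
  min_size <- 2L * 3^iterations
  if (span < min_size)
    stop("raster_size ", raster_size, " too coarse for ", iterations,
         " iterations; minimum usable span is ", min_size, " cells (",
         "raster_size >= ", min_size + 2L * as.integer(margin), ")")
  seg <- koch_segments(iterations)
  # scale the unit base to `span` cells; centre the curve in the square grid
  x_off <- margin + 0.5
  y_off <- (raster_size - span * sqrt(3) / 6) / 2 + 0.5
  x0 <- seg$x0 * span + x_off
  x1 <- seg$x1 * span + x_off
  y0 <- seg$y0 * span + y_off
  y1 <- seg$y1 * span + y_off
  cells <- rasterize_segments(x0, y0, x1, y1, raster_size, raster_size)
  binary_map(cells, cell_size = 1)
}

# Segment list of the iterated Koch curve over the unit base, as parallel
# coordinate vectors; 4^iterations rows.
koch_segments <- function(iterations) {
  p <- c(0 + 0i, 1 + 0i)
  rot <- exp(1i * pi / 3)
  for (it in seq_len(iterations)) {
    a <- p[-length(p)]
    b <- p[-1]
    d <- (b - a) / 3
    q1 <- a + d
    q2 <- q1 + d * rot
    q3 <- a + 2 * d
    # interleave a, q1, q2, q3 per segment; close with the final endpoint
    p <- c(rbind(a, q1, q2, q3), p[length(p)])
  }
  list(x0 = Re(p[-length(p)]), y0 = Im(p[-length(p)]),
       x1 = Re(p[-1]), y1 = Im(p[-1]))
}

# Supercover-style rasterization by dense sampling (step 0.1 cell) along each
# segment; no anti-aliasing, a cell is either crossed or not.
rasterize_segments <- function(x0, y0, x1, y1, nr, nc) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  nstep <- pmax(2L, ceiling(len / 0.1) + 1L)
  total <- sum(nstep)
  t_all <- numeric(total)
  idx <- rep.int(seq_along(x0), nstep)
  t_all <- unlist(lapply(nstep, function(k) seq(0, 1, length.out = k)),
                  use.names = FALSE)
  xs <- x0[idx] + t_all * (x1[idx] - x0[idx])
  ys <- y0[idx] + t_all * (y1[idx] - y0[idx])
  ci <- pmin(pmax(floor(xs) + 1L, 1L), nc)
  ri <- pmin(pmax(floor(ys) + 1L, 1L), nr)
  cells <- matrix(0L, nr, nc)
  cells[unique(ri + (ci - 1L) * nr)] <- 1L
  cells
}

#' Analytic surface fixtures with known geometry
#'
#' Closed-form surfaces used as oracles for the rugosity and terrain metrics:
#' a flat plane, an inclined plane (true surface/planar area ratio
#' 1/cos(angle)), a 1D-periodic sawtooth ridge field, and a hemisphere.
#' Heights are evaluated at cell centres.
#'
#' @param kind one of "flat", "inclined_plane", "sawtooth", "hemisphere".
#' @param size grid side in cells.
#' @param cell_size physical cell size.
#' @param angle tilt angle in degrees (inclined plane), < 90.
#' @param amplitude,period sawtooth geometry (length units).
#' @param height base height for "flat".
#' @return A [heightmap()].
#' @examples
#' ip <- analytic_fixture("inclined_plane", size = 32, angle = 30)
#' @export
analytic_fixture <- function(kind = c("flat", "inclined_plane", "sawtooth",
                                      "hemisphere"),
                             size = 65, cell_size = 1, angle = 30,
                             amplitude = 1, period = 8 * cell_size,
                             height = 0) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  x <- (seq_len(size) - 0.5) * cell_size
  z <- switch(kind,
    flat = matrix(height, size, size),
    inclined_plane = {
      if (angle >= 90 || angle < 0) stop("angle must be in [0, 90) degrees")
      matrix(rep(x * tan(angle * pi / 180), each = size), size, size)
    },
    sawtooth = {
      if (amplitude < 0 || period <= 0) stop("bad sawtooth geometry")
      tri <- amplitude * 2 * abs(x / period - floor(x / period + 0.5))
      matrix(rep(tri, each = size), size, size)
    },
    hemisphere = {
      r <- size * cell_size / 2
      cx <- size * cell_size / 2
      d2 <- outer((x - cx)^2, (x - cx)^2, "+")
      sqrt(pmax(r^2 - d2, 0))
    })
  heightmap(z, cell_size = cell_size)
}

#' Analytic 1D profile fixtures
#'
#' @param kind "flat", "inclined" (line at `angle` degrees), or "sawtooth".
#' @param n number of samples.
#' @param spacing sample spacing.
#' @param angle,amplitude,period geometry parameters.
#' @return A [profile1d()].
#' @export
analytic_profile <- function(kind = c("flat", "inclined", "sawtooth"),
                             n = 65, spacing = 1, angle = 30,
                             amplitude = 1, period = 2 * spacing) {
  kind <- match.arg(kind)
  x <- (seq_len(n) - 1) * spacing
  h <- switch(kind,
    flat = rep(0, n),
    inclined = {
      if (angle >= 90) stop("angle must be < 90 degrees")
      x * tan(angle * pi / 180)
    },
    sawtooth = amplitude * 2 * abs(x / period - floor(x / period + 0.5)))
  profile1d(h, spacing = spacing)
}

#' Weierstrass-Mandelbrot 1D fractal profile (optional fixture)
#'
#' Truncated cosine series `sum_k gamma^(-k H) (1 - cos(gamma^k t))`; a
#' deterministic self-affine curve of dimension 2 - H. Provided as an extra
#' 1D fixture only; it is not part of any headline estimator check.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param n number of samples.
#' @param spacing sample spacing.
#' @param gamma frequency ratio > 1.
#' @param n_terms number of series terms.
#' @return A [profile1d()].
#' @export
weierstrass_profile <- function(hurst, n = 1025, spacing = 1, gamma = 1.5,
                                n_terms = 60) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must be in (0, 1)")
  t <- seq(0, 2 * pi, length.out = n)
  h <- numeric(n)
  for (k in seq_len(n_terms) - 1L)
    h <- h + gamma^(-k * hurst) * (1 - cos(gamma^k * t))
  profile1d(h, spacing = spacing)
}
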