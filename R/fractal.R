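#' Scaling curve: (scale, statistic) pairs from a box-counting or variation sweep
#'
#' @param epsilon strictly increasing scales (cells).
#' @param statistic box counts N(eps) (positive) or mean oscillations V(eps)
#'   (non-negative), matching `statistic_kind`.
#' @param statistic_kind "box_count" or "oscillation".
#' @param n_origins number of random grid origins averaged (box counts).
#' @param seed RNG seed used for the origin draws.
#' @return An object of class `scaling_curve` (a data frame with columns
#'   `epsilon` and `statistic`, plus metadata attributes).
#' @export
scaling_curve <- function(epsilon, statistic,
                          statistic_kind = c("box_count", "oscillation"),
                          n_origins = 1L, seed = NA_integer_) {
  statistic_kind <- match.arg(statistic_kind)
  if (length(epsilon) != length(statistic))
    stop("epsilon and statistic lengths differ")
  if (any(diff(epsilon) <= 0)) stop("epsilons must be strictly increasing")
  if (statistic_kind == "box_count" && any(statistic < 1))
    stop("box counts must be >= 1")
  if (statistic_kind == "oscillation" && any(statistic < 0))
    stop("oscillations must be >= 0")
  out <- data.frame(epsilon = as.numeric(epsilon),
                    statistic = as.numeric(statistic))
  structure(out, statistic_kind = statistic_kind,
            n_origins = as.integer(n_origins), seed = seed,
            class = c("scaling_curve", "data.frame"))
}

#' Box-counting sweep over a binary map
#'
#' For each box size `eps` and each grid origin, overlays a grid of
#' `eps` x `eps` boxes offset by the origin and counts boxes containing at
#' least one foreground cell. Only boxes lying entirely inside the map are
#' counted (regions outside the measured set are excluded); origins are drawn
#' uniformly from `[0, eps)^2` so the grid is never deliberately aligned to
#' features of the set. The curve statistic is the mean count across origins.
#'
#' @param map a [binary_map()] with non-empty foreground.
#' @param epsilons integer box edge lengths in cells, each between 1 and half
#'   the shorter map side. Default: dyadic scales 2, 4, ... up to half the
#'   shorter side.
#' @param n_origins number of random origins per scale (>= 1).
#' @param seed RNG seed for the origin draws.
#' @param origins optional n x 2 matrix of fixed (row, col) offsets in cells,
#'   overriding random draws; `origins = c(0, 0)` reproduces the naive
#'   aligned grid.
#' @param edge_rule "strict" (default): boxes straddling the map edge are
#'   excluded, so no region outside the measured window is ever counted;
#'   "permissive": the box grid covers the whole map including partial edge
#'   boxes. The permissive mode reproduces the classic naive protocol whose
#'   inclusion of regions outside the fractal biases the estimate; it exists
#'   for bias comparison and is never the default.
#' @return A [scaling_curve()] with `statistic_kind = "box_count"`.
#' @examples
#' m <- binary_map(matrix(1L, 64, 64))
#' box_count(m, epsilons = c(2, 4, 8), origins = c(0, 0))
#' @export
box_count <- function(map, epsilons = NULL, n_origins = 16L, seed = 1L,
                      origins = NULL, edge_rule = c("strict", "permissive")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(inherits(map, "binary_map"))
  if (isTRUE(attr(map, "empty")) || sum(map$cells) == 0L)
    stop("box counting needs a non-empty foreground")
  nr <- nrow(map$cells)
  nc <- ncol(map$cells)
  short <- min(nr, nc)
  if (is.null(epsilons)) epsilons <- dyadic_scales(2L, short %/% 2L)
  epsilons <- sort(unique(as.integer(epsilons)))
  if (any(epsilons < 1L) || any(epsilons > short %/% 2L))
    stop("box sizes must lie in [1, ", short %/% 2L, "] cells")
  if (!is.null(origins)) {
    origins <- matrix(as.integer(origins), ncol = 2)
    n_origins <- nrow(origins)
  }
  if (n_origins < 1L) stop("n_origins must be >= 1")
  fg <- which(map$cells == 1L)
  fr <- ((fg - 1L) %% nr) + 1L
  fc <- ((fg - 1L) %/% nr) + 1L
  set.seed(seed)
  counts <- vapply(epsilons, function(e) {
    offs <- if (is.null(origins)) {
      cbind(sample.int(e, n_origins, replace = TRUE) - 1L,
            sample.int(e, n_origins, replace = TRUE) - 1L)
    } else origins
    mean(apply(offs, 1L, function(o)
      count_boxes(fr, fc, nr, nc, e, o[1], o[2], edge_rule)))
  }, numeric(1))
  if (any(counts < 1))
    stop("no boxes fully inside the map contained foreground at some scale")
  scaling_curve(epsilons, counts, "box_count", n_origins = n_origins,
                seed = as.integer(seed))
}

# Occupied-box count for one box size and one origin offset. Under the
# strict rule, boxes straddling the map edge are excluded, so foreground in
# partially covered boxes does not count; under the permissive rule the grid
# covers every cell (partial edge boxes included).
count_boxes <- function(fr, fc, nr, nc, e, or, oc, edge_rule = "strict") {
  if (edge_rule == "permissive") {
    bi <- (fr + or - 1L) %/% e
    bj <- (fc + oc - 1L) %/% e
    return(length(unique(bi + (1L + (nr + or) %/% e) * bj)))
  }
  nbr <- (nr - or) %/% e   # rows of full boxes
  nbc <- (nc - oc) %/% e
  if (nbr < 1L || nbc < 1L) return(0)
  keep <- fr > or & fr <= or + nbr * e & fc > oc & fc <= oc + nbc * e
  if (!any(keep)) return(0)
  bi <- (fr[keep] - or - 1L) %/% e
  bj <- (fc[keep] - oc - 1L) %/% e
  length(unique(bi + nbr * bj))
}

# Dyadic scale grid 2^k covering [lo, hi].
dyadic_scales <- function(lo, hi) {
  if (hi < lo) stop("empty scale range [", lo, ", ", hi, "]")
  2L^(ceiling(log2(lo)):floor(log2(hi)))
}

#' Intermediate box-size window for a map of a given side
#'
#' Rescales the empirically accurate window (box sizes 32-128 cells on a
#' 4097-cell side, where small-scale discretisation and large-scale
#' stochasticity biases are both mild) proportionally to the map side:
#' `(round(side/128), round(side/32))`, each bound clamped to >= 2 cells.
#'
#' @param map_side grid side in cells, >= 64.
#' @return Numeric vector `c(eps_min, eps_max)`.
#' @examples
#' intermediate_scale_rule(4097)  # c(32, 128)
#' @export
intermediate_scale_rule <- function(map_side) {
  map_side <- as.integer(map_side)
  if (map_side < 64L) stop("map side must be >= 64 cells")
  lo <- max(2, round(map_side / 128))
  hi <- max(2, round(map_side / 32))
  if (floor(log2(hi)) - ceiling(log2(lo)) + 1L < 3L)
    stop("map side ", map_side, " admits fewer than 3 dyadic scales in the ",
         "intermediate window [", lo, ", ", hi, "]; use a larger map")
  c(lo, hi)
}

#' Fit a fractal dimension to a scaling curve
#'
#' Ordinary least squares of `log(statistic)` on `log(epsilon)` restricted to
#' `scale_range`. For box counts the dimension estimate is minus the slope;
#' for oscillation (variation-method) curves the slope estimates the Hurst
#' exponent and the dimension is `embed_dim - slope`. Residual diagnostics
#' flag violations of the regression assumptions behind the log-log fit:
#' nonlinearity (t-test on an added quadratic term), heteroskedasticity
#' (Breusch-Pagan score test) and non-normal residuals (Shapiro-Wilk, only
#' with at least 5 scales); a flag is `NA` when too few scales are
#' available to test it. Estimates are
#' deliberately not clamped to valid dimension ranges, so estimator bias
#' stays visible.
#'
#' @param curve a [scaling_curve()].
#' @param scale_range `c(eps_min, eps_max)` inclusive; default: full range.
#' @param embed_dim embedding dimension (2 for planar sets/profiles, 3 for
#'   surfaces); required for oscillation curves.
#' @param alpha significance level for the diagnostic flags.
#' @return An object of class `dimension_estimate`.
#' @export
fit_dimension <- function(curve, scale_range = NULL, embed_dim = 2L,
                          alpha = 0.05) {
  stopifnot(inherits(curve, "scaling_curve"))
  kind <- attr(curve, "statistic_kind")
  if (is.null(scale_range))
    scale_range <- range(curve$epsilon)
  if (scale_range[1] >= scale_range[2]) stop("eps_min must be < eps_max")
  sel <- curve$epsilon >= scale_range[1] & curve$epsilon <= scale_range[2]
  if (sum(sel) < 3L)
    stop("need >= 3 scales inside [", scale_range[1], ", ", scale_range[2],
         "], have ", sum(sel))
  eps <- curve$epsilon[sel]
  stat <- curve$statistic[sel]
  if (any(stat <= 0))
    stop("zero statistic inside the fit range; dimension undefined")
  x <- log(eps)
  y <- log(stat)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  d_hat <- if (kind == "box_count") -slope else embed_dim - slope
  res <- stats::residuals(fit)
  n <- length(res)
  diag_flags <- list(nonlinearity = NA, heteroskedasticity = NA,
                     non_normal_residuals = NA)
  if (n >= 4L && length(unique(x)) >= 3L) {
    q <- stats::lm(y ~ x + I(x^2))
    pq <- summary(q)$coefficients
    if (nrow(pq) >= 3L)
      diag_flags$nonlinearity <- unname(pq[3, 4] < alpha)
    # Breusch-Pagan score: n * R^2 of squared residuals on the regressor
    aux <- stats::lm(I(res^2) ~ x)
    lm_stat <- n * summary(aux)$r.squared
    diag_flags$heteroskedasticity <-
      unname(stats::pchisq(lm_stat, df = 1, lower.tail = FALSE) < alpha)
  }
  if (n >= 5L && stats::sd(res) > 0)
    diag_flags$non_normal_residuals <-
      unname(tryCatch(stats::shapiro.test(res)$p.value < alpha,
                      error = function(e) NA))
  method <- attr(curve, "fit_method")
  structure(list(
    d_hat = d_hat,
    intercept = unname(stats::coef(fit)[1]),
    std_error = se,
    scale_range = c(min(eps), max(eps)),
    r_squared = summary(fit)$r.squared,
    diagnostics = diag_flags,
    method = if (is.null(method)) kind else method,
    embed_dim = as.integer(embed_dim),
    n_scales = n,
    seed = attr(curve, "seed"),
    n_origins = attr(curve, "n_origins")
  ), class = "dimension_estimate")
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf(
    "<dimension_estimate> D = %.4f (SE %.4f), eps in [%g, %g] (%d scales), R2 = %.4f\n",
    x$d_hat, x$std_error, x$scale_range[1], x$scale_range[2], x$n_scales,
    x$r_squared))
  flags <- names(Filter(isTRUE, x$diagnostics))
  if (length(flags))
    cat("  assumption flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' Variation-method dimension estimate from a surface or profile
#'
#' The variation (oscillation) method: for each window half-width `eps`, the
#' oscillation at a cell is the max minus min of heights within the square
#' (Chebyshev) window of half-width `eps` centred there, truncated at map
#' edges; `V(eps)` is the mean oscillation over all cells. For fractional
#' Brownian relief `E[V(eps)]` grows like `eps^H`, so the log-log slope
#' estimates the Hurst exponent and `D = embed_dim - slope` (3 - H for
#' surfaces, 2 - H for profiles).
#'
#' @param map a [heightmap()] (nodata-free) or [profile1d()].
#' @param epsilons integer window half-widths in cells; default: dyadic
#'   1, 2, 4, ... up to a quarter of the (shorter) side.
#' @param scale_range optional `c(eps_min, eps_max)` restriction for the fit.
#' @param embed_dim 3 for surfaces, 2 for profiles (defaulted from the input
#'   class).
#' @param alpha significance level for regression diagnostics.
#' @return A `dimension_estimate`.
#' @export
variation_dimension <- function(map, epsilons = NULL, scale_range = NULL,
                                embed_dim = NULL, alpha = 0.05) {
  curve <- variation_curve(map, epsilons)
  if (is.null(embed_dim))
    embed_dim <- if (inherits(map, "heightmap")) 3L else 2L
  fit_dimension(curve, scale_range = scale_range, embed_dim = embed_dim,
                alpha = alpha)
}

#' Oscillation scaling curve (the variation method's raw sweep)
#'
#' @inheritParams variation_dimension
#' @return A [scaling_curve()] with `statistic_kind = "oscillation"`.
#' @export
variation_curve <- function(map, epsilons = NULL) {
  if (inherits(map, "heightmap")) {
    assert_no_nodata(map, "variation method")
    z <- map$heights
    short <- min(dim(z))
    if (is.null(epsilons)) epsilons <- dyadic_scales(1L, max(short %/% 4L, 2L))
    epsilons <- sort(unique(as.integer(epsilons)))
    if (any(epsilons < 1L)) stop("window half-widths must be >= 1 cell")
    v <- oscillation_sweep(z, epsilons, two_d = TRUE)
  } else if (inherits(map, "profile1d")) {
    h <- map$heights
    if (is.null(epsilons))
      epsilons <- dyadic_scales(1L, max(length(h) %/% 4L, 2L))
    epsilons <- sort(unique(as.integer(epsilons)))
    if (any(epsilons < 1L)) stop("window half-widths must be >= 1 sample")
    v <- oscillation_sweep(h, epsilons, two_d = FALSE)
  } else stop("variation method needs a heightmap or profile1d")
  if (all(v == 0))
    stop("flat input: oscillation is zero at every scale, dimension undefined")
  scaling_curve(epsilons, v, "oscillation")
}

# Mean oscillation (windowed max - min, truncated at edges) at each radius in
# `epsilons` (sorted increasing). Running max/min filters are grown
# incrementally: filters compose exactly under edge clamping
# (filter_a(filter_b(z)) = filter_{a+b}(z)), and a radius can be doubled with
# two clamped translates per axis, so dyadic sweeps cost O(log eps_max)
# matrix operations instead of O(eps_max).
oscillation_sweep <- function(z, epsilons, two_d) {
  grow <- if (two_d) {
    function(f, cur, target, op) {
      while (cur < target) {
        if (cur > 0L && target >= 2L * cur) {
          f <- cheb_double(f, cur, op)
          cur <- 2L * cur
        } else {
          f <- chebyshev_filter(f, target - cur, op)
          cur <- target
        }
      }
      list(f = f, cur = cur)
    }
  } else {
    function(f, cur, target, op) {
      while (cur < target) {
        if (cur > 0L && target >= 2L * cur) {
          n <- length(f)
          i <- seq_len(n)
          f <- op(f[pmax(i - cur, 1L)], f[pmin(i + cur, n)])
          cur <- 2L * cur
        } else {
          f <- running_extreme_vec(f, target - cur, op)
          cur <- target
        }
      }
      list(f = f, cur = cur)
    }
  }
  fmax <- z; fmin <- z
  rmax <- 0L; rmin <- 0L
  vapply(epsilons, function(e) {
    gx <- grow(fmax, rmax, e, pmax)
    gn <- grow(fmin, rmin, e, pmin)
    fmax <<- gx$f; rmax <<- gx$cur
    fmin <<- gn$f; rmin <<- gn$cur
    mean(fmax - fmin)
  }, numeric(1))
}

# Double the radius of an already radius-r 2D Chebyshev extreme filter:
# two clamped translates per axis.
cheb_double <- function(f, r, op) {
  nr <- nrow(f)
  i <- seq_len(nr)
  f <- op(f[pmax(i - r, 1L), , drop = FALSE],
          f[pmin(i + r, nr), , drop = FALSE])
  nc <- ncol(f)
  j <- seq_len(nc)
  op(f[, pmax(j - r, 1L), drop = FALSE], f[, pmin(j + r, nc), drop = FALSE])
}

# Separable 2D Chebyshev-window extreme filter with edge truncation.
chebyshev_filter <- function(z, r, op) {
  t(apply_rows_extreme(t(apply_rows_extreme(z, r, op)), r, op))
}

# Running extreme of half-width r along each column (i.e. over rows).
apply_rows_extreme <- function(z, r, op) {
  nr <- nrow(z)
  out <- z
  r <- min(r, nr - 1L)
  for (d in seq_len(r)) {
    out[1:(nr - d), ] <- op(out[1:(nr - d), , drop = FALSE],
                            z[(1 + d):nr, , drop = FALSE])
    out[(1 + d):nr, ] <- op(out[(1 + d):nr, , drop = FALSE],
                            z[1:(nr - d), , drop = FALSE])
  }
  out
}

running_extreme_vec <- function(h, r, op) {
  n <- length(h)
  out <- h
  r <- min(r, n - 1L)
  for (d in seq_len(r)) {
    out[1:(n - d)] <- op(out[1:(n - d)], h[(1 + d):n])
    out[(1 + d):n] <- op(out[(1 + d):n], h[1:(n - d)])
  }
  out
}

#' Assess closeness to fractal scaling over the observed range
#'
#' Fits separate dimensions below and above a split scale and reports the
#' decade coverage of the sweep. A measured set is treated as plausibly
#' fractal over its observed scales only if the sweep spans at least two
#' orders of magnitude and the piecewise dimensions agree; scale-dependent
#' dimension estimates signal a non-fractal (or multifractal) object, or
#' estimator bias.
#'
#' @param curve a [scaling_curve()].
#' @param split scale value separating the two fit ranges; entries with
#'   `epsilon <= split` form the small-scale fit, the rest the large-scale
#'   fit. Must leave >= 3 entries on each side.
#' @param embed_dim embedding dimension forwarded to [fit_dimension()].
#' @return An object of class `fractality_report`: list with
#'   `orders_of_magnitude`, `fit_small`, `fit_large`, `d_difference`,
#'   `sufficient_range`.
#' @export
assess_fractality <- function(curve, split, embed_dim = 2L) {
  stopifnot(inherits(curve, "scaling_curve"))
  rng <- range(curve$epsilon)
  if (split < rng[1] || split > rng[2])
    stop("split ", split, " outside the measured range [", rng[1], ", ",
         rng[2], "]")
  small <- curve$epsilon <= split
  if (sum(small) < 3L || sum(!small) < 3L)
    stop("need >= 3 scales on each side of the split")
  sub <- function(keep) {
    scaling_curve(curve$epsilon[keep], curve$statistic[keep],
                  attr(curve, "statistic_kind"),
                  n_origins = attr(curve, "n_origins"),
                  seed = attr(curve, "seed"))
  }
  fit_s <- fit_dimension(sub(small), embed_dim = embed_dim)
  fit_l <- fit_dimension(sub(!small), embed_dim = embed_dim)
  oom <- log10(rng[2] / rng[1])
  structure(list(orders_of_magnitude = oom,
                 fit_small = fit_s, fit_large = fit_l,
                 d_difference = abs(fit_s$d_hat - fit_l$d_hat),
                 sufficient_range = oom >= 2),
            class = "fractality_report")
}

#' @export
print.fractality_report <- function(x, ...) {
  cat(sprintf(
    "<fractality_report> %.2f decades (%ssufficient), D_small = %.3f, D_large = %.3f, |diff| = %.3f\n",
    x$orders_of_magnitude, if (x$sufficient_range) "" else "in",
    x$fit_small$d_hat, x$fit_large$d_hat, x$d_difference))
  invisible(x)
}
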