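#' Surface rugosity of a heightmap
#'
#' Rugosity R = A / planar area, where A is the triangulated 3D surface area
#' of the grid. Each cell quad is split into two triangles along each of its
#' two diagonals and the two triangulated areas are averaged, removing the
#' diagonal-orientation bias of a single triangulation. The planar area is
#' the horizontal extent of the quads, `(nrow-1) * (ncol-1) * cell_size^2`.
#' By construction R >= 1 (projection inequality), with equality for a
#' horizontal plane.
#'
#' @param map a [heightmap()] with no nodata inside the window.
#' @return An object of class `rugosity_result`: list with `r_value`,
#'   `surface_area`, `planar_area`, `grain`, `slope_corrected`, `method`.
#' @examples
#' surface_rugosity(analytic_fixture("inclined_plane", 33, angle = 30))
#' @export
surface_rugosity <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  assert_no_nodata(map, "surface rugosity")
  A <- triangulated_area(map$heights, map$cell_size)
  planar <- (nrow(map$heights) - 1) * (ncol(map$heights) - 1) *
    map$cell_size^2
  rugosity_result(A / planar, A, planar, grain = map$cell_size,
                  slope_corrected = FALSE, method = "triangulated_2d")
}

rugosity_result <- function(r_value, area, planar, grain, slope_corrected,
                            method) {
  structure(list(r_value = r_value, surface_area = area, planar_area = planar,
                 grain = grain, slope_corrected = slope_corrected,
                 method = method),
            class = "rugosity_result")
}

#' @export
print.rugosity_result <- function(x, ...) {
  cat(sprintf("<rugosity_result> R = %.6f (%s%s), grain = %g\n", x$r_value,
              x$method, if (x$slope_corrected) ", slope-corrected" else "",
              x$grain))
  invisible(x)
}

# Dual-diagonal triangulated surface area of a height grid with square cells.
# Triangle area via the cross product of two edge vectors; both diagonal
# orientations computed and averaged.
triangulated_area <- function(z, h) {
  nr <- nrow(z)
  nc <- ncol(z)
  z00 <- z[-nr, -nc]
  z10 <- z[-1, -nc]
  z01 <- z[-nr, -1]
  z11 <- z[-1, -1]
  tri <- function(dza, dzb) {
    # triangle with horizontal edge vectors (h,0,dza) and (0,h,dzb) from a
    # shared vertex: area = h/2 * sqrt(h^2 + dza^2 + dzb^2)
    0.5 * h * sqrt(h^2 + dza^2 + dzb^2)
  }
  # diagonal z00-z11: triangles (z00,z10,z11) and (z00,z01,z11)
  a1 <- tri(z10 - z00, z11 - z10) + tri(z01 - z00, z11 - z01)
  # diagonal z10-z01: triangles (z00,z10,z01) and (z10,z11,z01)
  a2 <- tri(z10 - z00, z01 - z00) + tri(z11 - z01, z11 - z10)
  sum(a1 + a2) / 2
}

#' Profile (chain) rugosity of a 1D elevation transect
#'
#' The digital analogue of draping a chain over the surface: contour length
#' `Lm = sum(sqrt(spacing^2 + dh^2))` divided by the linear extent
#' `L = spacing * (n - 1)`.
#'
#' @param profile a [profile1d()].
#' @return A `rugosity_result` with `method = "chain_1d"`; `surface_area`
#'   holds the contour length and `planar_area` the extent.
#' @export
profile_rugosity <- function(profile) {
  stopifnot(inherits(profile, "profile1d"))
  dh <- diff(profile$heights)
  lm_len <- sum(sqrt(profile$spacing^2 + dh^2))
  extent <- profile$spacing * (length(profile$heights) - 1)
  rugosity_result(lm_len / extent, lm_len, extent, grain = profile$spacing,
                  slope_corrected = FALSE, method = "chain_1d")
}

#' Slope-corrected surface rugosity (plane of best fit)
#'
#' A tilted but otherwise flat surface has raw rugosity 1/cos(tilt) even
#' though it is no rougher than a horizontal plane. The correction fits a
#' least-squares plane to the heights and replaces the planar denominator by
#' the window's area projected onto that plane (planar area times the secant
#' of the plane's tilt), so that any plane scores exactly 1 and gently tilted
#' rough surfaces score as if untilted.
#'
#' @param map a [heightmap()] with no nodata.
#' @return A `rugosity_result` with `slope_corrected = TRUE`.
#' @export
slope_corrected_rugosity <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  assert_no_nodata(map, "slope-corrected rugosity")
  z <- map$heights
  nr <- nrow(z)
  nc <- ncol(z)
  x <- rep((seq_len(nc) - 0.5) * map$cell_size, each = nr)
  y <- rep((seq_len(nr) - 0.5) * map$cell_size, times = nc)
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(z))
  if (fit$rank < 3L) stop("degenerate plane fit (collinear support)")
  gx <- unname(fit$coefficients[2])
  gy <- unname(fit$coefficients[3])
  sec_tilt <- sqrt(1 + gx^2 + gy^2)
  raw <- surface_rugosity(map)
  rugosity_result(raw$surface_area / (raw$planar_area * sec_tilt),
                  raw$surface_area, raw$planar_area * sec_tilt,
                  grain = map$cell_size, slope_corrected = TRUE,
                  method = "triangulated_2d")
}

#' Rugosity across resolutions
#'
#' Recomputes surface rugosity after coarsening the map by each factor
#' (block-mean aggregation by default), emulating scans of the same surface
#' at coarser grains. Rugosity can only decrease as relief is averaged away,
#' which is the classic resolution dependence of R.
#'
#' @param map a [heightmap()].
#' @param grains integer coarsening factors; each must leave at least a 2x2
#'   grid.
#' @param method coarsening operator, see [coarsen()].
#' @return A list of `rugosity_result`, ordered as `grains`.
#' @export
multiresolution_rugosity <- function(map, grains = c(1, 2, 4, 8),
                                     method = c("mean", "subsample")) {
  stopifnot(inherits(map, "heightmap"))
  method <- match.arg(method)
  grains <- as.integer(grains)
  lapply(grains, function(f) surface_rugosity(coarsen(map, f, method)))
}

#' Richness regression with rugosity decoupled from area
#'
#' Because available surface area A = planar area x R, a raw regression of
#' species richness S on rugosity is confounded with the species-area
#' relationship. This fits the log-log model
#' `log S = a log A + b log R + c` so that `b` measures the effect of
#' rugosity independent of area.
#'
#' @param richness positive species richness per site.
#' @param areas positive surface areas per site.
#' @param rugosities positive rugosity values per site.
#' @return An object of class `richness_model_fit`: list with `coefficients`
#'   (a, b, c), `std_errors`, `n_observations`, `collinear` flag (condition
#'   number of the design above 1e8, or an inestimable coefficient).
#' @examples
#' set.seed(1)
#' A <- exp(rnorm(50)); R <- exp(abs(rnorm(50, 0, 0.1)))
#' S <- exp(1) * A^0.25 * R^0.9 * exp(rnorm(50, 0, 0.05))
#' area_decoupled_regression(S, A, R)
#' @export
area_decoupled_regression <- function(richness, areas, rugosities) {
  n <- length(richness)
  if (length(areas) != n || length(rugosities) != n)
    stop("richness, areas and rugosities must have equal length")
  if (n < 5L) stop("need at least 5 observations")
  if (any(richness <= 0) || any(areas <= 0) || any(rugosities <= 0))
    stop("all inputs must be positive (the model is log-log)")
  df <- data.frame(lS = log(richness), lA = log(areas), lR = log(rugosities))
  fit <- stats::lm(lS ~ lA + lR, data = df)
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  X <- stats::model.matrix(fit)
  collinear <- any(is.na(cf)) || kappa(X, exact = TRUE) > 1e8
  if (collinear)
    warning("log A and log R are (near-)collinear or a coefficient is ",
            "inestimable; interpret b with caution")
  get_se <- function(nm) if (nm %in% rownames(sm)) sm[nm, 2] else NA_real_
  structure(list(
    coefficients = c(a = unname(cf["lA"]), b = unname(cf["lR"]),
                     c = unname(cf["(Intercept)"])),
    std_errors = c(a = get_se("lA"), b = get_se("lR"),
                   c = get_se("(Intercept)")),
    n_observations = n,
    collinear = collinear
  ), class = "richness_model_fit")
}

#' @export
print.richness_model_fit <- function(x, ...) {
  cat(sprintf(
    "<richness_model_fit> log S = %.4f log A + %.4f log R + %.4f (n = %d)%s\n",
    x$coefficients["a"], x$coefficients["b"], x$coefficients["c"],
    x$n_observations, if (x$collinear) " [collinear]" else ""))
  invisible(x)
}
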