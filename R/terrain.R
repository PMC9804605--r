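#' Height range of a heightmap
#'
#' @param map a [heightmap()].
#' @return max - min over valid cells (length units).
#' @export
height_range <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  z <- map$heights[!is.na(map$heights)]
  if (!length(z)) stop("all-nodata heightmap")
  max(z) - min(z)
}

#' Terrain ruggedness index (TRI)
#'
#' Per focal cell, the root-mean-square of the height differences to its
#' eight surrounding cells; the index is the average over all interior focal
#' cells (edge cells, which lack a full 8-neighbourhood, are excluded).
#'
#' @param map a [heightmap()] of at least 3x3 nodata-free cells.
#' @return The TRI in height units; 0 for a flat surface.
#' @export
terrain_ruggedness_index <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  assert_no_nodata(map, "terrain ruggedness index")
  z <- map$heights
  nr <- nrow(z)
  nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("TRI needs at least a 3x3 grid")
  core <- z[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  ss <- matrix(0, nr - 2L, nc - 2L)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), drop = FALSE]
    ss <- ss + (core - nb)^2
  }
  mean(sqrt(ss / 8))
}

#' Per-cell slope and aspect
#'
#' Gradients by central differences over the physical cell size; slope is
#' `atan(|grad|)` in degrees, aspect the downslope compass direction in
#' degrees clockwise from north (rows increasing = south). Aspect is `NA`
#' (undefined) where the gradient vanishes. Only interior cells have both
#' neighbours; edge cells are returned as `NA`.
#'
#' @param map a [heightmap()] of at least 3x3 nodata-free cells.
#' @return A list with matrices `slope` and `aspect` (degrees).
#' @export
slope_aspect <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  assert_no_nodata(map, "slope/aspect")
  z <- map$heights
  nr <- nrow(z)
  nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("slope/aspect needs at least a 3x3 grid")
  h2 <- 2 * map$cell_size
  gx <- matrix(NA_real_, nr, nc)  # d z / d x (columns, eastward)
  gy <- matrix(NA_real_, nr, nc)  # d z / d y (rows, southward)
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / h2
  gy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / h2
  gmag <- sqrt(gx^2 + gy^2)
  slope <- atan(gmag) * 180 / pi
  # downslope direction: -grad; compass angle measured from north (-y),
  # clockwise towards east (+x)
  aspect <- (atan2(-gx, gy) * 180 / pi) %% 360
  aspect[!is.na(gmag) & gmag == 0] <- NA_real_
  list(slope = slope, aspect = aspect)
}

#' Vector dispersion of surface facet normals
#'
#' Unit normals of every triangulated facet (the same dual-diagonal
#' triangulation as [surface_rugosity()], upward-oriented) are summed; with
#' mean resultant length `Rbar = |sum| / N`, the dispersion is `1 - Rbar`
#' (0 for any plane, approaching 1 as normals scatter). The Fisher-statistics
#' variant `(N - |sum|) / (N - 1)` is available via `variant = "fisher"`.
#'
#' @param map a [heightmap()] without nodata.
#' @param variant "resultant" (default, 1 - Rbar) or "fisher".
#' @return Dispersion in `[0, 1]`.
#' @export
vector_dispersion <- function(map, variant = c("resultant", "fisher")) {
  stopifnot(inherits(map, "heightmap"))
  variant <- match.arg(variant)
  assert_no_nodata(map, "vector dispersion")
  normals <- facet_normals(map$heights, map$cell_size)
  dispersion_from_normals(normals, variant)
}

# Unit normals (N x 3 matrix) of the four triangles per cell quad.
facet_normals <- function(z, h) {
  nr <- nrow(z)
  nc <- ncol(z)
  z00 <- as.vector(z[-nr, -nc])
  z10 <- as.vector(z[-1, -nc])
  z01 <- as.vector(z[-nr, -1])
  z11 <- as.vector(z[-1, -1])
  # cross products for the four triangles (see triangulated_area), scaled by
  # 1/h^2 so each normal is proportional to (nx, ny, 1), then normalised and
  # oriented upward
  mk <- function(nx, ny) {
    nz <- rep(1, length(nx))
    len <- sqrt(nx^2 + ny^2 + 1)
    cbind(nx / len, ny / len, nz / len)
  }
  # Triangle (z00,z10,z11): normal prop. to (-(z11-z10)/h, -(z10-z00)/h, 1)
  n1 <- mk(-(z11 - z10) / h, -(z10 - z00) / h)
  # Triangle (z00,z01,z11): normal prop. to (-(z01-z00)/h, -(z11-z01)/h, 1)
  n2 <- mk(-(z01 - z00) / h, -(z11 - z01) / h)
  # Triangle (z00,z10,z01): normal prop. to (-(z01-z00)/h, -(z10-z00)/h, 1)
  n3 <- mk(-(z01 - z00) / h, -(z10 - z00) / h)
  # Triangle (z10,z11,z01): normal prop. to (-(z11-z10)/h, -(z11-z01)/h, 1)
  n4 <- mk(-(z11 - z10) / h, -(z11 - z01) / h)
  rbind(n1, n2, n3, n4)
}

# Dispersion statistic from a matrix of unit normals.
dispersion_from_normals <- function(normals, variant = "resultant") {
  n <- nrow(normals)
  if (n < 1L) stop("no facets")
  res <- sqrt(sum(colSums(normals)^2))
  if (variant == "fisher") {
    if (n < 2L) stop("fisher variant needs >= 2 facets")
    (n - res) / (n - 1)
  } else {
    1 - res / n
  }
}

#' Summary of the geometric terrain metrics
#'
#' @param map a [heightmap()].
#' @return An object of class `terrain_summary`: `height_range`, `tri`,
#'   `mean_slope` (degrees, interior cells), `vector_dispersion`, `grain`.
#' @export
terrain_summary <- function(map) {
  sa <- slope_aspect(map)
  structure(list(height_range = height_range(map),
                 tri = terrain_ruggedness_index(map),
                 mean_slope = mean(sa$slope, na.rm = TRUE),
                 vector_dispersion = vector_dispersion(map),
                 grain = map$cell_size),
            class = "terrain_summary")
}

#' @export
print.terrain_summary <- function(x, ...) {
  cat(sprintf(
    "<terrain_summary> range = %.4g, TRI = %.4g, mean slope = %.2f deg, dispersion = %.4f (grain %g)\n",
    x$height_range, x$tri, x$mean_slope, x$vector_dispersion, x$grain))
  invisible(x)
}
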