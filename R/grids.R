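#' Rectangular elevation grid (heightmap / DEM)
#'
#' The container consumed by all geometric complexity metrics: a rectangular
#' grid of elevations with a physical cell size. Invalid (nodata) cells are
#' stored as `NA`; most metrics either refuse nodata inside their analysis
#' window or exclude it explicitly, per their own contracts.
#'
#' Grid convention (used throughout the package): row-major, origin at the
#' top-left corner, cell centres at `(i - 0.5, j - 0.5) * cell_size`.
#'
#' @param heights numeric matrix of elevations (length units). `NA` marks
#'   nodata cells.
#' @param cell_size physical edge length of one cell (length units), > 0.
#' @return An object of class `heightmap`: a list with elements `heights`
#'   (numeric matrix) and `cell_size` (scalar).
#' @examples
#' hm <- heightmap(matrix(runif(25), 5, 5), cell_size = 0.01)
#' dim(hm)
#' @export
heightmap <- function(heights, cell_size = 1) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (nrow(heights) < 2L || ncol(heights) < 2L)
    stop("heightmap needs at least 2x2 cells, got ",
         nrow(heights), "x", ncol(heights))
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (sum(!is.na(heights)) < 4L)
    stop("heightmap needs at least 4 valid (non-NA) cells")
  if (any(is.infinite(heights)))
    stop("heights must be finite or NA")
  structure(list(heights = heights, cell_size = as.numeric(cell_size)),
            class = "heightmap")
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

#' @export
print.heightmap <- function(x, ...) {
  n_na <- sum(is.na(x$heights))
  cat(sprintf("<heightmap> %d x %d cells, cell_size = %g", nrow(x$heights),
              ncol(x$heights), x$cell_size))
  if (n_na > 0) cat(sprintf(", %d nodata cells", n_na))
  rng <- range(x$heights, na.rm = TRUE)
  cat(sprintf(", height range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' One-dimensional elevation profile
#'
#' @param heights numeric vector of elevations (length units), all finite.
#' @param spacing horizontal distance between consecutive samples, > 0.
#' @return An object of class `profile1d`.
#' @examples
#' p <- profile1d(c(0, 1, 0, 1, 0), spacing = 0.5)
#' @export
profile1d <- function(heights, spacing = 1) {
  heights <- as.numeric(heights)
  if (length(heights) < 2L) stop("profile1d needs at least 2 samples")
  if (any(!is.finite(heights))) stop("profile heights must all be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("spacing must be a single positive number")
  structure(list(heights = heights, spacing = as.numeric(spacing)),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %d samples, spacing = %g, extent = %g\n",
              length(x$heights), x$spacing,
              x$spacing * (length(x$heights) - 1L)))
  invisible(x)
}

#' Binary raster map
#'
#' A rectangular 0/1 grid marking membership in a putatively fractal set;
#' the input to box-counting. An all-zero map is normally invalid (there is
#' nothing to measure); internal producers such as [level_set_boundary()] may
#' construct one with `allow_empty = TRUE`, in which case the result carries
#' the attribute `empty = TRUE` so that downstream consumers can refuse it
#' with a clear message.
#'
#' @param cells matrix coercible to 0/1 integers.
#' @param cell_size physical edge length of one cell, > 0.
#' @param allow_empty allow a foreground-free map (flagged, not silently).
#' @return An object of class `binary_map`.
#' @export
binary_map <- function(cells, cell_size = 1, allow_empty = FALSE) {
  cells <- as.matrix(cells)
  if (any(is.na(cells))) stop("binary map cells must not be NA")
  if (!all(cells %in% c(0, 1)))
    stop("binary map cells must be 0/1; offending values: ",
         paste(utils::head(setdiff(unique(as.vector(cells)), c(0, 1)), 5),
               collapse = ", "))
  storage.mode(cells) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  empty <- sum(cells) == 0L
  if (empty && !allow_empty)
    stop("binary map contains no foreground (1) cells")
  structure(list(cells = cells, cell_size = as.numeric(cell_size)),
            class = "binary_map", empty = empty)
}

#' @export
dim.binary_map <- function(x) dim(x$cells)

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %d x %d cells, %d foreground (%.2f%%)%s\n",
              nrow(x$cells), ncol(x$cells), sum(x$cells),
              100 * mean(x$cells),
              if (isTRUE(attr(x, "empty"))) " [EMPTY]" else ""))
  invisible(x)
}

# Crop a matrix to the largest top-left block whose side is a multiple of f.
crop_to_multiple <- function(m, f) {
  nr <- f * (nrow(m) %/% f)
  nc <- f * (ncol(m) %/% f)
  if (nr < f || nc < f) stop("coarsening factor ", f, " larger than map")
  m[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Coarsen a heightmap by block aggregation
#'
#' Aggregates `factor` x `factor` blocks of cells into one cell, emulating a
#' coarser-resolution scan of the same surface. The default operator is the
#' block mean (standard DEM resampling); `method = "subsample"` instead keeps
#' the top-left cell of each block, which aliases high-frequency relief and
#' is provided for comparison only.
#'
#' @param map a [heightmap()].
#' @param factor integer coarsening factor >= 1.
#' @param method "mean" (default) or "subsample".
#' @return A `heightmap` with cell size `factor * map$cell_size`.
#' @export
coarsen <- function(map, factor, method = c("mean", "subsample")) {
  stopifnot(inherits(map, "heightmap"))
  method <- match.arg(method)
  f <- as.integer(factor)
  if (f < 1L) stop("coarsening factor must be >= 1")
  if (f == 1L) return(map)
  z <- crop_to_multiple(map$heights, f)
  if (any(is.na(z))) stop("coarsening requires a nodata-free window")
  if (method == "mean") {
    nr <- nrow(z) %/% f
    nc <- ncol(z) %/% f
    # mean over f x f blocks: fold rows, then columns
    zr <- rowsum(z, rep(seq_len(nr), each = f)) / f
    zc <- t(rowsum(t(zr), rep(seq_len(nc), each = f))) / f
    z2 <- zc
  } else {
    z2 <- z[seq(1L, nrow(z), by = f), seq(1L, ncol(z), by = f), drop = FALSE]
  }
  if (nrow(z2) < 2L || ncol(z2) < 2L)
    stop("coarsening factor ", f, " leaves fewer than 2x2 cells")
  heightmap(z2, cell_size = map$cell_size * f)
}

# Stop if the analysis window contains nodata.
assert_no_nodata <- function(map, what) {
  if (any(is.na(map$heights)))
    stop(what, " requires a nodata-free heightmap window (",
         sum(is.na(map$heights)), " NA cells present)")
  invisible(map)
}
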