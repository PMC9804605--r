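#' Write a raster to an ESRI ASCII grid (.asc)
#'
#' Single-band plain-text raster: six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows top to bottom.
#' Heightmaps are written at full double precision; binary and categorical
#' rasters as integers. `NA` cells are written as the nodata value.
#'
#' @param x a [heightmap()], [binary_map()], or integer label matrix.
#' @param path output file path.
#' @param cell_size cell size when `x` is a bare matrix.
#' @param nodata nodata sentinel written to the header.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, cell_size = 1, nodata = -9999) {
  if (inherits(x, "heightmap")) {
    m <- x$heights
    cell_size <- x$cell_size
    fmt <- function(v) formatC(v, format = "g", digits = 17)
  } else if (inherits(x, "binary_map")) {
    m <- x$cells
    cell_size <- x$cell_size
    fmt <- function(v) formatC(v, format = "d")
  } else {
    m <- as.matrix(x)
    fmt <- function(v) formatC(v, format = "d")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               "xllcorner 0.0",
               "yllcorner 0.0",
               paste("cellsize", formatC(cell_size, format = "g",
                                         digits = 17)),
               paste("NODATA_value", nodata)), con)
  body <- m
  body[is.na(body)] <- nodata
  writeLines(apply(body, 1L, function(r) paste(fmt(r), collapse = " ")), con)
  invisible(path)
}

#' Read a raster from an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @param kind expected value kind: "height" returns a [heightmap()] with
#'   nodata as `NA`; "binary" validates 0/1 and returns a [binary_map()];
#'   "categorical" returns an integer label matrix with attribute
#'   `cell_size` (nodata as `NA`).
#' @return See `kind`.
#' @export
read_raster <- function(path, kind = c("height", "binary", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext != "asc")
    stop("unknown raster format '.", ext,
         "': only ESRI ASCII grids (.asc) are supported")
  hdr_lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L &&
        tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]])) stop("malformed .asc header: missing ", req)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  switch(kind,
    height = heightmap(m, cell_size = hdr$cellsize),
    binary = {
      bad <- stats::na.omit(setdiff(unique(as.vector(m)), c(0, 1)))
      if (length(bad))
        stop("binary raster contains non-{0,1} values: ",
             paste(utils::head(bad, 5), collapse = ", "))
      m[is.na(m)] <- 0
      binary_map(m, cell_size = hdr$cellsize, allow_empty = TRUE)
    },
    categorical = {
      storage.mode(m) <- "integer"
      attr(m, "cell_size") <- hdr$cellsize
      m
    })
}

#' Write / read a 1D elevation profile as two-column CSV
#'
#' Columns `distance,height`; spacing must be uniform and is recovered from
#' the distance column on read.
#'
#' @param profile a [profile1d()].
#' @param path CSV file path.
#' @return `write_profile`: `path` invisibly; `read_profile`: a
#'   [profile1d()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  d <- data.frame(
    distance = (seq_along(profile$heights) - 1) * profile$spacing,
    height = profile$heights)
  utils::write.csv(format(d, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("distance", "height") %in% names(d)))
    stop("profile CSV needs columns distance,height")
  sp <- diff(d$distance)
  if (length(sp) < 1L) stop("profile needs >= 2 samples")
  if (max(abs(sp - sp[1])) > 1e-9 * max(abs(sp[1]), 1))
    stop("profile sampling must be uniform")
  profile1d(d$height, spacing = sp[1])
}

#' Serialize analysis results to CSV
#'
#' Writes result objects as long-format CSV with a stable column order and
#' full float precision; every row carries method/seed/scale metadata so any
#' number in the file can be traced to its computation. Accepts a
#' `dimension_estimate`, `rugosity_result`, `entropy_result`,
#' `terrain_summary`, `bias_table`, `scaling_curve`, or a list of the
#' scalar-row kinds. An empty list yields a header-only CSV with the
#' dimension-estimate schema.
#'
#' @param results result object or list of result objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- results_to_df(results)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

results_to_df <- function(results) {
  if (inherits(results, "bias_table") ||
      inherits(results, "scaling_curve"))
    return(as.data.frame(results))
  if (!is.list(results) || !is.null(attr(results, "class")))
    results <- list(results)
  if (length(results) == 0L)
    return(data.frame(d_hat = numeric(), intercept = numeric(),
                      std_error = numeric(), eps_min = numeric(),
                      eps_max = numeric(), r_squared = numeric(),
                      method = character(), embed_dim = integer(),
                      n_origins = integer(), seed = integer()))
  do.call(rbind, lapply(results, result_row))
}

result_row <- function(x) {
  if (inherits(x, "dimension_estimate")) {
    data.frame(d_hat = x$d_hat, intercept = x$intercept,
               std_error = x$std_error, eps_min = x$scale_range[1],
               eps_max = x$scale_range[2], r_squared = x$r_squared,
               method = x$method, embed_dim = x$embed_dim,
               n_origins = if (is.null(x$n_origins)) NA_integer_
                           else x$n_origins,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed)
  } else if (inherits(x, "rugosity_result")) {
    data.frame(r_value = x$r_value, surface_area = x$surface_area,
               planar_area = x$planar_area, grain = x$grain,
               slope_corrected = x$slope_corrected, method = x$method)
  } else if (inherits(x, "entropy_result")) {
    data.frame(h_per_observation = x$h_per_observation, h_total = x$h_total,
               k_effective = x$k_effective,
               n_observations = x$n_observations)
  } else if (inherits(x, "terrain_summary")) {
    data.frame(height_range = x$height_range, tri = x$tri,
               mean_slope = x$mean_slope,
               vector_dispersion = x$vector_dispersion, grain = x$grain)
  } else stop("cannot serialize object of class ",
              paste(class(x), collapse = "/"))
}
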