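#' Regular lat/lon raster grid
#'
#' The core spatial container shared by every pipeline stage: a rectilinear
#' grid of one variable (SST in deg C, an anomaly in deg C, abundance in
#' individuals per 100 m^2, or an integer category code) on a geographic
#' lat/lon grid with cell-centre registration. Row 1 of `values` is the
#' southernmost row (latitude increases with row index) regardless of any
#' on-disk row order; masked-out (land/invalid) cells hold `NA` and are
#' excluded from every statistic.
#'
#' @param values Numeric matrix, rows = latitude (south to north), columns =
#'   longitude (west to east).
#' @param lon_origin,lat_origin Coordinates (decimal degrees) of the *centre*
#'   of the lower-left (south-west) cell.
#' @param resolution Cell size in degrees, equal in both axes. Must be > 0.
#' @param mask Logical matrix of the same shape; `TRUE` = sea (valid). Default
#'   marks non-`NA` cells valid.
#' @param variable Character label, e.g. `"sst_august"`, `"anomaly"`,
#'   `"abundance"`.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, lon_origin, lat_origin, resolution,
                        mask = NULL, variable = "value") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` must have identical shape", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  values[!mask] <- NA_real_
  structure(
    list(values = values, lon_origin = as.numeric(lon_origin),
         lat_origin = as.numeric(lat_origin), resolution = as.numeric(resolution),
         mask = mask, variable = variable, crs_note = "geographic lat/lon degrees"),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<raster_grid> %s: %d x %d cells at %g deg, origin (%g, %g)\n",
              x$variable, nrow(x$values), ncol(x$values), x$resolution,
              x$lon_origin, x$lat_origin))
  cat(sprintf("  sea cells: %d / %d", sum(x$mask), length(x$mask)))
  if (length(v)) cat(sprintf("; range %.3f .. %.3f", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [raster_grid()].
#' @return `grid_lons()`/`grid_lats()` return the vectors of column/row centre
#'   coordinates.
#' @export
grid_lons <- function(grid) grid$lon_origin + (seq_len(ncol(grid$values)) - 1) * grid$resolution

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) grid$lat_origin + (seq_len(nrow(grid$values)) - 1) * grid$resolution

#' Tidy a raster grid into a tibble of sea cells
#'
#' One row per valid (sea) cell with its centre coordinates, ready for
#' dplyr/ggplot2 work.
#'
#' @param x A [raster_grid()].
#' @param all_cells Include masked (land) cells with `NA` values? Default FALSE.
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `row`, `col`, `value`.
#' @export
as_tibble.raster_grid <- function(x, ..., all_cells = FALSE) {
  idx <- which(if (all_cells) matrix(TRUE, nrow(x$values), ncol(x$values)) else x$mask,
               arr.ind = TRUE)
  tibble::tibble(
    lon = x$lon_origin + (idx[, 2] - 1) * x$resolution,
    lat = x$lat_origin + (idx[, 1] - 1) * x$resolution,
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
    value = x$values[idx]
  )
}

#' Compare two grid geometries
#'
#' `TRUE` iff shape, origin and resolution agree within 1e-9 degrees. Masks and
#' values are not compared.
#'
#' @param a,b [raster_grid()] objects.
#' @return Logical scalar.
#' @export
regrid_check <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$lon_origin - b$lon_origin) < 1e-9 &&
    abs(a$lat_origin - b$lat_origin) < 1e-9 &&
    abs(a$resolution - b$resolution) < 1e-9
}

same_geometry_or_stop <- function(a, b, what = "grids") {
  if (!regrid_check(a, b))
    stop(sprintf("geometry mismatch between %s (shape/origin/resolution differ)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Grid stacks: labelled collections of grids on one geometry
#'
#' A `grid_stack` is a tibble with one list-column `grid` of [raster_grid()]
#' objects plus arbitrary label columns (decade, scenario, month, model ...).
#' All member grids must share geometry.
#'
#' @param grids List of [raster_grid()] objects.
#' @param ... Label vectors recycled against `grids` (e.g. `decade =`,
#'   `scenario =`).
#' @return A tibble with the label columns and a `grid` list-column.
#' @export
grid_stack <- function(grids, ...) {
  stopifnot(length(grids) >= 1)
  for (g in grids[-1]) same_geometry_or_stop(grids[[1]], g, "grid_stack members")
  tibble::tibble(..., grid = grids)
}

#' Read a raster from disk
#'
#' Reads a single-variable grid. The on-disk format is the plain-text ESRI
#' ASCII grid (`format = "ascii-grid"`), whose header declares the full
#' geometry (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`); nodata cells become masked-out cells. Geometry round-trips
#' exactly through [write_raster()].
#'
#' @param path File path.
#' @param format On-disk format; only `"ascii-grid"` is supported in this
#'   build (no GeoTIFF/NetCDF driver is linked).
#' @param variable Label to attach to the returned grid.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, format = "ascii-grid", variable = "value") {
  format <- match.arg(format, c("ascii-grid", "geotiff", "netcdf"))
  if (format != "ascii-grid")
    stop(sprintf("format '%s' is not supported by this build; use 'ascii-grid'", format),
         call. = FALSE)
  if (!file.exists(path)) stop(sprintf("cannot read raster: no such file '%s'", path),
                               call. = FALSE)
  lines <- readLines(path)
  hdr_n <- 6L
  hdr <- strsplit(trimws(lines[seq_len(hdr_n)]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(hdr, `[`, "", 2L)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys) || anyNA(vals[need]))
    stop(sprintf("missing or malformed geometry metadata in '%s'", path), call. = FALSE)
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-seq_len(hdr_n)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop(sprintf("'%s': expected %d values, found %d", path, ncols * nrows, length(body)),
         call. = FALSE)
  # file rows run north -> south; flip to south-first in memory
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)[nrows:1, , drop = FALSE]
  nodata <- vals[["nodata_value"]]
  mask <- !(is.na(m) | m == nodata)
  raster_grid(m, lon_origin = vals[["xllcorner"]] + vals[["cellsize"]] / 2,
              lat_origin = vals[["yllcorner"]] + vals[["cellsize"]] / 2,
              resolution = vals[["cellsize"]], mask = mask, variable = variable)
}

#' Write a raster to disk
#'
#' Writes an ESRI ASCII grid with explicit geometry metadata; masked cells are
#' encoded as the nodata value.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @param format Only `"ascii-grid"` is supported (see [read_raster()]).
#' @param nodata Nodata sentinel written to file (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = "ascii-grid", nodata = -9999) {
  format <- match.arg(format, c("ascii-grid", "geotiff", "netcdf"))
  if (format != "ascii-grid")
    stop(sprintf("format '%s' is not supported by this build; use 'ascii-grid'", format),
         call. = FALSE)
  m <- grid$values
  m[!grid$mask] <- nodata
  m <- m[nrow(m):1, , drop = FALSE]  # write north -> south
  hdr <- c(
    sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$lon_origin - grid$resolution / 2),
    sprintf("yllcorner %.10g", grid$lat_origin - grid$resolution / 2),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE), collapse = " "))
  ok <- tryCatch({ writeLines(c(hdr, rows), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write raster to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Map a function over grid values
#'
#' Applies `f` to the value matrix of a grid, preserving geometry and mask.
#' @param grid A [raster_grid()].
#' @param f Function taking and returning a matrix (or vectorised over values).
#' @param variable Optional new variable label.
#' @return A [raster_grid()].
#' @export
grid_map <- function(grid, f, variable = grid$variable) {
  raster_grid(f(grid$values), grid$lon_origin, grid$lat_origin, grid$resolution,
              mask = grid$mask, variable = variable)
}

#' Heat-map plot of a raster grid
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$variable) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (deg E)", y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}
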