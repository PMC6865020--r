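#' Define a regular latitude/longitude analysis grid
#'
#' A `grid_spec` describes a pixel-center registered regular grid:
#' latitudes descend north to south, longitudes ascend west to east,
#' both with uniform spacing. This is the common convention of gridded
#' reanalysis products and is assumed by [bilinear_resample()].
#'
#' @param n_rows,n_cols Number of grid rows (latitude) and columns
#'   (longitude). Must be positive integers.
#' @param lat_max Latitude of the northernmost pixel center (degrees).
#' @param lon_min Longitude of the westernmost pixel center (degrees).
#' @param spacing Grid spacing in degrees (same in both directions).
#'
#' @return An object of class `grid_spec`: a list with `n_rows`,
#'   `n_cols`, `lat` (descending pixel-center latitudes), `lon`
#'   (ascending pixel-center longitudes) and `spacing`.
#' @examples
#' g <- grid_spec(60, 80, lat_max = 55, lon_min = 60, spacing = 0.75)
#' g
#' @export
grid_spec <- function(n_rows, n_cols, lat_max = 55, lon_min = 60,
                      spacing = 0.75) {
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("`n_rows` and `n_cols` must be positive integers.", call. = FALSE)
  }
  if (spacing <= 0) stop("`spacing` must be positive.", call. = FALSE)
  lat <- lat_max - (seq_len(n_rows) - 1) * spacing
  lon <- lon_min + (seq_len(n_cols) - 1) * spacing
  if (any(abs(lat) > 90)) {
    stop("Grid latitudes exceed +/-90 degrees; shrink the grid or move `lat_max`.",
         call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         lat = lat, lon = lon, spacing = spacing),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.4g deg spacing\n",
              x$n_rows, x$n_cols, x$spacing))
  cat(sprintf("  lat %.4g .. %.4g (descending), lon %.4g .. %.4g\n",
              x$lat[1], x$lat[x$n_rows], x$lon[1], x$lon[x$n_cols]))
  invisible(x)
}

#' Tabulate the pixel centers of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per pixel: `row`, `col`, `lat`, `lon`,
#'   in row-major order (row 1 = northernmost).
#' @export
grid_pixels <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tibble::tibble(
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows),
    lat = rep(grid$lat, each = grid$n_cols),
    lon = rep(grid$lon, times = grid$n_rows)
  )
}

#' Spherical pixel areas of a regular lat/lon grid
#'
#' Pixel area on a spherical Earth of radius 6371 km:
#' `area(lat) = R^2 * dlon * dlat * cos(lat)` with the spacings in
#' radians. Relative areas (the quantity that matters for city sizes)
#' are insensitive to the spherical-vs-ellipsoidal choice.
#'
#' @param grid A [grid_spec()].
#' @return A tibble `row`, `col`, `lat`, `lon`, `area_km2`.
#' @examples
#' # a 0.75 degree pixel at the equator is about 6955 km^2
#' pixel_area(grid_spec(1, 1, lat_max = 0, lon_min = 0, spacing = 0.75))$area_km2
#' @export
pixel_area <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- grid$spacing * pi / 180
  px <- grid_pixels(grid)
  px$area_km2 <- EARTH_RADIUS_KM^2 * d * d * cos(px$lat * pi / 180)
  px
}

EARTH_RADIUS_KM <- 6371

# long tibble (row, col, value...) -> matrix in grid layout
layer_to_matrix <- function(data, grid, value = "value") {
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[cbind(data$row, data$col)] <- data[[value]]
  m
}

matrix_to_layer <- function(m, grid, value = "value") {
  px <- grid_pixels(grid)
  px[[value]] <- as.vector(t(m))
  px
}

#' Bilinearly resample a gridded layer onto a destination grid
#'
#' Each destination pixel-center value is the bilinear interpolation of
#' the four surrounding source pixel centers. Destination centers that
#' fall outside the convex hull of the source centers are returned as
#' `NA` (missing), never extrapolated.
#'
#' @param data A tibble with columns `row`, `col` and the value column,
#'   covering the source grid (as produced by [grid_pixels()] plus a
#'   value, or [matrix_to_layer()]).
#' @param src_grid,dst_grid Source and destination [grid_spec()]s.
#' @param value Name of the value column. Default `"value"`.
#' @return A tibble on the destination grid: `row`, `col`, `lat`,
#'   `lon`, and the resampled value column (`NA` where outside the
#'   source hull).
#' @export
bilinear_resample <- function(data, src_grid, dst_grid, value = "value") {
  stopifnot(inherits(src_grid, "grid_spec"), inherits(dst_grid, "grid_spec"))
  if (max(dst_grid$lon) < min(src_grid$lon) ||
      min(dst_grid$lon) > max(src_grid$lon) ||
      max(dst_grid$lat) < min(src_grid$lat) ||
      min(dst_grid$lat) > max(src_grid$lat)) {
    stop("Source and destination grids do not overlap.", call. = FALSE)
  }
  m <- layer_to_matrix(data, src_grid, value)
  # interp2 wants ascending y; our latitudes descend, so flip rows
  y <- rev(src_grid$lat)
  z <- m[rev(seq_len(src_grid$n_rows)), , drop = FALSE]
  out <- grid_pixels(dst_grid)
  out[[value]] <- pracma::interp2(src_grid$lon, y, z, out$lon, out$lat,
                                  method = "linear")
  out
}

#' Write and read a single gridded layer as ESRI ASCII grid
#'
#' Layers are serialized in the plain-text ESRI ASCII grid format
#' (`ncols/nrows/xllcenter/yllcenter/cellsize/NODATA_value` header
#' followed by row-major values, northernmost row first) with a JSON
#' sidecar (`<path>.json`) holding the units tag. Values are written at
#' full double precision (17 significant digits), so a write-then-read
#' round trip is exact.
#'
#' @param data Tibble with `row`, `col` and the value column.
#' @param grid The layer's [grid_spec()].
#' @param path Output path (conventionally `.asc`).
#' @param value Value column name.
#' @param units Units tag recorded in the sidecar.
#' @return `write_layer()` returns `path` invisibly. `read_layer()`
#'   returns a list with `data` (tibble `row`, `col`, `lat`, `lon`,
#'   `value`), `grid` and `units`.
#' @export
write_layer <- function(data, grid, path, value = "value", units = "") {
  m <- layer_to_matrix(data, grid, value)
  nodata <- -9999
  m[is.na(m)] <- nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcenter %.17g", grid$lon[1]),
    sprintf("yllcenter %.17g", grid$lat[grid$n_rows]),
    sprintf("cellsize %.17g", grid$spacing),
    sprintf("NODATA_value %d", nodata)
  )
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  jsonlite::write_json(list(units = units, crs = "EPSG:4326 (pixel-center)"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layer
#' @export
read_layer <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("Malformed ESRI ASCII grid: too few lines in ",
                              path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcenter", "yllcenter", "cellsize",
            "nodata_value")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys)) {
    stop("Malformed ESRI ASCII grid header: missing field(s) ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  n_rows <- vals[["nrows"]]; n_cols <- vals[["ncols"]]
  body <- lines[-(1:6)]
  if (length(body) != n_rows) {
    stop(sprintf("Malformed grid: header says nrows=%d but %d data rows found.",
                 n_rows, length(body)), call. = FALSE)
  }
  m <- do.call(rbind, lapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != n_cols) {
      stop(sprintf("Malformed grid: header says ncols=%d but a row has %d values.",
                   n_cols, length(v)), call. = FALSE)
    }
    v
  }))
  m[m == vals[["nodata_value"]]] <- NA_real_
  grid <- grid_spec(n_rows, n_cols,
                    lat_max = vals[["yllcenter"]] + (n_rows - 1) * vals[["cellsize"]],
                    lon_min = vals[["xllcenter"]],
                    spacing = vals[["cellsize"]])
  units <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    units <- jsonlite::read_json(sidecar)$units %||% ""
  }
  list(data = matrix_to_layer(m, grid), grid = grid, units = units)
}

#' Write and read an annual gridded series as long CSV
#'
#' Multi-year stacks (fluxes, greenness) are serialized as a long CSV
#' (`year,row,col,<vars>`) with full double precision, plus a JSON
#' header (`<path>.json`) describing the grid and units, so a round
#' trip reproduces values and grid metadata exactly.
#'
#' @param data Long tibble with `year`, `row`, `col` and value columns.
#' @param grid The [grid_spec()].
#' @param path CSV output path.
#' @param units Named list/character of per-variable units.
#' @return `write_series()`: `path`, invisibly. `read_series()`: list
#'   with `data`, `grid`, `units`.
#' @export
write_series <- function(data, grid, path, units = list()) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_rows = grid$n_rows, n_cols = grid$n_cols,
         lat_max = grid$lat[1], lon_min = grid$lon[1],
         spacing = grid$spacing, units = units),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) {
    stop("Series header not found: ", hdr_path, call. = FALSE)
  }
  hdr <- jsonlite::read_json(hdr_path)
  grid <- grid_spec(hdr$n_rows, hdr$n_cols, lat_max = hdr$lat_max,
                    lon_min = hdr$lon_min, spacing = hdr$spacing)
  df <- utils::read.csv(path)
  list(data = tibble::as_tibble(df), grid = grid, units = hdr$units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
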