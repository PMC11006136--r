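#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix with an affine geotransform.
#' Row 1 is the northernmost row, cells are registered at their centers, and
#' coordinates are geographic WGS84 decimal degrees. `NA` cells are nodata and
#' are excluded from every statistic computed on a grid.
#'
#' @param values Numeric matrix, row 1 = north.
#' @param xmin Western edge (degrees longitude) of the grid footprint.
#' @param ymax Northern edge (degrees latitude) of the grid footprint.
#' @param xres,yres Cell sizes in degrees; must be positive.
#' @param crs CRS identifier (informational; the package works in WGS84).
#'
#' @return A `raster_grid` object.
#' @export
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), xmin = 10, ymax = 70, xres = 0.5)
#' rg_extract(g, 10.25, 69.75)
raster_grid <- function(values, xmin, ymax, xres, yres = xres, crs = "EPSG:4326") {
  stopifnot(is.matrix(values), is.numeric(values) || is.logical(values))
  if (!is.finite(xres) || !is.finite(yres) || xres <= 0 || yres <= 0) {
    stop("cell sizes must be positive and finite", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         xres = xres, yres = yres, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<raster_grid> %d x %d cells, %.4g deg resolution\n  extent: lon [%.4g, %.4g], lat [%.4g, %.4g] (%s)\n",
    nrow(x$values), ncol(x$values), x$xres,
    x$xmin, x$xmin + ncol(x$values) * x$xres,
    x$ymax - nrow(x$values) * x$yres, x$ymax, x$crs
  ))
  if (length(v)) {
    cat(sprintf("  values: [%.6g, %.6g], %d nodata cells\n",
                min(v), max(v), sum(!is.finite(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @rdname raster_grid
#' @param g,a,b `raster_grid` objects.
#' @export
rg_lon_centers <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$xres

#' @rdname raster_grid
#' @export
rg_lat_centers <- function(g) g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$yres

#' @rdname raster_grid
#' @export
rg_same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$xres, a$yres),
                     c(b$xmin, b$ymax, b$xres, b$yres), tolerance = 1e-9))
}

# row/col of the cell containing a point; NA if outside the footprint
rg_cell_of <- function(g, lon, lat) {
  col <- floor((lon - g$xmin) / g$xres) + 1L
  row <- floor((g$ymax - lat) / g$yres) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values) |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Extract the value of the cell containing a point
#'
#' @param g A [raster_grid()].
#' @param lon,lat Point coordinates in decimal degrees (vectorized).
#' @return Numeric vector of cell values; `NA` for points off-grid or on
#'   nodata cells.
#' @export
rg_extract <- function(g, lon, lat) {
  rc <- rg_cell_of(g, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

# apply a function to the value matrix, preserving georeferencing
rg_map <- function(g, f) {
  g$values <- matrix(f(g$values), nrow(g$values), ncol(g$values))
  g
}

#' Tidy a raster to a long tibble of cell centers
#'
#' @param x A `raster_grid`.
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `value` (nodata cells included
#'   as `NA` so grids stay rectangular for plotting).
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.raster_grid <- function(x, ...) {
  tibble::tibble(
    lon = rep(rg_lon_centers(x), each = nrow(x$values)),
    lat = rep(rg_lat_centers(x), times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' @exportS3Method ggplot2::autoplot
#' @rdname as_tibble.raster_grid
#' @param object A `raster_grid`.
autoplot.raster_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble.raster_grid(object),
                  ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed(ratio = 1 / cos(mean(rg_lat_centers(object)) * pi / 180)) +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value") +
    ggplot2::theme_minimal()
}

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text single-band raster exchange. Requires square cells
#' (`xres == yres`), which every grid produced by this package has.
#'
#' @param g A [raster_grid()].
#' @param path File path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_esri_ascii()` returns `path` invisibly; `read_esri_ascii()`
#'   returns a `raster_grid`.
#' @export
write_esri_ascii <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "raster_grid"))
  if (abs(g$xres - g$yres) > 1e-12) {
    stop("Esri ASCII grids require square cells", call. = FALSE)
  }
  nr <- nrow(g$values); nc <- ncol(g$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", g$xmin),
    sprintf("yllcorner %.10f", g$ymax - nr * g$yres),
    sprintf("cellsize %.10f", g$xres),
    sprintf("NODATA_value %g", nodata)
  )
  m <- g$values
  m[!is.finite(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cell <- vals[["cellsize"]]; nodata <- vals[["nodata_value"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, xmin = vals[["xllcorner"]],
              ymax = vals[["yllcorner"]] + nr * cell, xres = cell)
}

# great-circle distance in km on a 6371-km sphere (vectorized)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(as.vector(lon1), n), rep_len(as.vector(lat1), n))
  p2 <- cbind(rep_len(as.vector(lon2), n), rep_len(as.vector(lat2), n))
  geosphere::distHaversine(p1, p2, r = 6371)
}

# destination point given bearing (deg) and distance (km)
dest_point <- function(lon, lat, bearing_deg, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_km * 1000,
                            a = 6371000, f = 0)
  list(lon = p[, 1], lat = p[, 2])
}
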