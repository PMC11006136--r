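# Shared fixtures, built in code at test time.

# small raster with known values; row 1 = north
toy_grid <- function(values = matrix(seq_len(12) / 10, 3, 4),
                     xmin = 10, ymax = 60, res = 0.5) {
  raster_grid(values, xmin = xmin, ymax = ymax, xres = res)
}

# constant raster
const_grid <- function(value, nr = 5, nc = 5, xmin = 10, ymax = 60, res = 0.5) {
  raster_grid(matrix(value, nr, nc), xmin = xmin, ymax = ymax, xres = res)
}

# small landscape reused by mid-weight tests (fast to build)
small_truth <- function(seed = 7, ...) {
  make_landscape(seed = seed, n_rows = 40, n_cols = 40, ...)
}

# independent haversine oracle (explicit formula, not the package path)
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# brute-force buffered mean: loop over every cell, filter by oracle distance
oracle_buffered_mean <- function(g, lon, lat, radius_km) {
  vals <- c()
  lons <- rg_lon_centers(g)
  lats <- rg_lat_centers(g)
  for (i in seq_len(nrow(g$values))) {
    for (j in seq_len(ncol(g$values))) {
      if (oracle_haversine_km(lons[j], lats[i], lon, lat) <= radius_km) {
        vals <- c(vals, g$values[i, j])
      }
    }
  }
  if (!length(vals)) vals <- rg_extract(g, lon, lat)
  mean(vals[is.finite(vals)])
}
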