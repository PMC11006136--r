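# Synthetic landscape, training samples, and individuals with known origins.
# Everything downstream (isoscape fitting, classification, calibration,
# assignment) can be validated against the ground truth generated here.

# separable Gaussian blur with reflective padding; sd in cells
gaussian_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    padded <- v[pmin(pmax(idx, 1L), n)]
    stats::convolve(padded, rev(k), type = "filter")
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

# smoothed standard-normal field (unit marginal SD after smoothing)
smooth_noise_field <- function(nr, nc, sd_cells) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sd_cells)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate a synthetic dual-isotope landscape with known ground truth
#'
#' Builds a piecewise-smooth bioavailable \eqn{^{87}Sr/^{86}Sr} field
#' (per-geology-unit base ratio + spatially correlated noise + a coastal
#' sea-salt pull toward the seawater ratio 0.7092), a precipitation
#' \eqn{\delta^{18}O} field declining with latitude and elevation, a stack of
#' predictor rasters (an informative proxy, elevation, coast distance, mean
#' annual temperature, pure noise), and a forest-cover raster. Geology units
#' are equal-frequency classes of an independent smoothed random field, so
#' their patches have a spatial scale set by `geo_kernel` cells.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param n_rows,n_cols Grid dimensions (at least 20 x 20).
#' @param n_geo_units Number of geology units (>= 1; >= 2 for a structured
#'   field).
#' @param sr_noise_sd Marginal SD (ratio units) of the spatially correlated
#'   within-unit Sr noise.
#' @param o_lapse Latitudinal \eqn{\delta^{18}O} decline, permil per degree
#'   latitude northward.
#' @param xmin,ymax,res Grid footprint (degrees); defaults span a
#'   Scandinavia-sized window.
#' @param base_range Range of per-unit Sr base ratios, spread evenly.
#' @param geo_kernel,noise_kernel Gaussian kernel SDs (cells) of the geology
#'   classification field and the Sr noise field.
#' @param coast_pull Maximum weight (0-1) of the coastal blend toward
#'   `coastal_sr`; 0 disables the sea-salt effect.
#' @param coastal_sr Seawater-like ratio coastal cells are pulled toward.
#' @param coast_efold_km E-folding distance of the coastal pull.
#' @param proxy_noise_sd SD (ratio units) of the smoothed error added to the
#'   Sr proxy predictor.
#' @param elev_max Maximum elevation (m) of the synthetic topography; 0 gives
#'   flat terrain.
#' @param o_south \eqn{\delta^{18}O} (permil VSMOW) at the southern edge at
#'   sea level.
#' @param o_elev_lapse \eqn{\delta^{18}O} decline per metre of elevation.
#' @param sea_margin_cols Number of westernmost columns turned into nodata
#'   "sea" (exercises nodata handling; default 0, all land).
#'
#' @return A `synthetic_truth` list: `sr_field`, `o_field` ([raster_grid()]s),
#'   `predictor_stack` (named list of raster grids), `forest_cover`,
#'   `geology`, `correlation_length_km`, `seed`, and `params`.
#' @export
#' @examples
#' truth <- make_landscape(seed = 1, n_rows = 40, n_cols = 40)
#' truth$sr_field
make_landscape <- function(seed, n_rows = 100, n_cols = 100, n_geo_units = 4,
                           sr_noise_sd = 0.002, o_lapse = 0.7,
                           xmin = 10, ymax = 70, res = 0.15,
                           base_range = c(0.712, 0.742),
                           geo_kernel = 5, noise_kernel = 5,
                           coast_pull = 0.4, coastal_sr = 0.7092,
                           coast_efold_km = 80,
                           proxy_noise_sd = 5e-4,
                           elev_max = 800, o_south = -8,
                           o_elev_lapse = 0.0028,
                           sea_margin_cols = 0) {
  if (n_rows < 20 || n_cols < 20) stop("grid must be at least 20 x 20", call. = FALSE)
  if (n_geo_units < 1) stop("n_geo_units must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  grid <- function(m) raster_grid(m, xmin = xmin, ymax = ymax, xres = res)
  lon <- xmin + (seq_len(n_cols) - 0.5) * res
  lat <- ymax - (seq_len(n_rows) - 0.5) * res
  lon_m <- matrix(lon, n_rows, n_cols, byrow = TRUE)
  lat_m <- matrix(lat, n_rows, n_cols)

  # geology: equal-frequency quantization of a smoothed field
  geo_f <- smooth_noise_field(n_rows, n_cols, geo_kernel)
  if (n_geo_units > 1) {
    breaks <- stats::quantile(geo_f, probs = seq(0, 1, length.out = n_geo_units + 1))
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
    geology <- matrix(findInterval(geo_f, breaks, rightmost.closed = TRUE),
                      n_rows, n_cols)
  } else {
    geology <- matrix(1L, n_rows, n_cols)
  }
  bases <- if (n_geo_units > 1) {
    seq(base_range[1], base_range[2], length.out = n_geo_units)
  } else {
    mean(base_range)
  }

  sr_noise <- if (sr_noise_sd > 0) {
    smooth_noise_field(n_rows, n_cols, noise_kernel) * sr_noise_sd
  } else {
    matrix(0, n_rows, n_cols)
  }
  sr <- matrix(bases[geology], n_rows, n_cols) + sr_noise

  # coast distance to the western margin (or to the sea strip edge)
  coast_lon <- xmin + sea_margin_cols * res
  coast_km <- haversine_km(lon_m, lat_m, pmin(lon_m, coast_lon), lat_m)
  coast_km <- matrix(coast_km, n_rows, n_cols)
  if (coast_pull > 0) {
    w <- coast_pull * exp(-coast_km / coast_efold_km)
    sr <- w * coastal_sr + (1 - w) * sr
  }

  elev <- if (elev_max > 0) {
    e <- smooth_noise_field(n_rows, n_cols, 8)
    elev_max * (e - min(e)) / (max(e) - min(e))
  } else {
    matrix(0, n_rows, n_cols)
  }

  o <- o_south - o_lapse * (lat_m - min(lat)) - o_elev_lapse * elev

  proxy <- sr + if (proxy_noise_sd > 0) {
    smooth_noise_field(n_rows, n_cols, noise_kernel) * proxy_noise_sd
  } else 0
  mat <- 8 - 0.6 * (lat_m - min(lat)) - 0.0065 * elev # mean annual temp, deg C
  noise_pred <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  cover <- smooth_noise_field(n_rows, n_cols, 6)
  cover <- 90 * (cover - min(cover)) / (max(cover) - min(cover))

  mask <- function(m) {
    if (sea_margin_cols > 0) m[, seq_len(sea_margin_cols)] <- NA_real_
    m
  }
  structure(list(
    seed = as.integer(seed),
    sr_field = grid(mask(sr)),
    o_field = grid(mask(o)),
    predictor_stack = list(
      sr_proxy  = grid(mask(proxy)),
      elevation = grid(mask(elev)),
      coast_km  = grid(mask(coast_km)),
      mat       = grid(mask(mat)),
      noise1    = grid(mask(noise_pred))
    ),
    forest_cover = grid(mask(cover)),
    geology = grid(mask(geology + 0)),
    correlation_length_km = noise_kernel * res * 111.195,
    params = list(n_rows = n_rows, n_cols = n_cols, n_geo_units = n_geo_units,
                  sr_noise_sd = sr_noise_sd, o_lapse = o_lapse, res = res,
                  xmin = xmin, ymax = ymax, coast_pull = coast_pull,
                  sea_margin_cols = sea_margin_cols)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> seed %d: %d x %d grid, %d geology units, %d predictors\n",
    x$seed, nrow(x$sr_field$values), ncol(x$sr_field$values),
    x$params$n_geo_units, length(x$predictor_stack)
  ))
  invisible(x)
}

# uniform draw of land-cell indices
sample_land_cells <- function(g, n, replace = FALSE) {
  land <- which(is.finite(g$values))
  if (!replace && n > length(land)) {
    stop("requested more points than land cells (replacement disabled)",
         call. = FALSE)
  }
  cells <- sample(land, n, replace = replace)
  list(row = ((cells - 1L) %% nrow(g$values)) + 1L,
       col = ((cells - 1L) %/% nrow(g$values)) + 1L)
}

#' Sample Sr training points from a synthetic landscape
#'
#' Emulates a literature compilation of bioavailable Sr point measurements:
#' locations uniform over land cells, values equal to the true field at the
#' cell plus independent Normal measurement noise.
#'
#' @param truth A [make_landscape()] result.
#' @param n Number of points (>= 10).
#' @param meas_noise_sd Measurement noise SD (ratio units).
#' @param seed Integer RNG seed.
#' @param replace Sample cells with replacement (allows replicate sites).
#' @return Tibble with `lon`, `lat`, `sr87_86`.
#' @export
sample_training_points <- function(truth, n, meas_noise_sd = 0.002, seed = 1,
                                   replace = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 10) stop("need at least 10 training points", call. = FALSE)
  set.seed(as.integer(seed))
  g <- truth$sr_field
  rc <- sample_land_cells(g, n, replace = replace)
  tibble::tibble(
    lon = rg_lon_centers(g)[rc$col],
    lat = rg_lat_centers(g)[rc$row],
    sr87_86 = g$values[cbind(rc$row, rc$col)] +
      stats::rnorm(n, 0, meas_noise_sd)
  )
}

#' Simulate individuals with known origins and tissue isotope values
#'
#' Each individual lives at a true origin drawn uniformly over land. Tissue
#' \eqn{^{87}Sr/^{86}Sr} is the Sr field at the origin plus noise; tissue
#' \eqn{\delta^{18}O} (drinking-water-equivalent) is the precipitation field
#' at the origin plus a tissue-type offset (antler above bone, reflecting
#' spring-summer antler growth) plus noise. A fraction of individuals are
#' "non-local": their death site is displaced from the origin by
#' `displacement_km` along a uniform random bearing (resampled until it lands
#' on a land cell). When an atmospheric record is supplied, raw tissue
#' \eqn{\delta^{13}C} values inherit the atmospheric trend at the year of
#' death so the Suess correction has real work to do.
#'
#' @param truth A [make_landscape()] result.
#' @param n Number of individuals.
#' @param frac_nonlocal Fraction displaced (0-1).
#' @param displacement_km Displacement distance; default 3x the landscape
#'   correlation length. Must be smaller than the grid extent.
#' @param tissue_sr_sd,tissue_o_sd Tissue-level noise SDs (ratio, permil).
#' @param seed Integer RNG seed.
#' @param antler_o_offset,bone_o_offset Additive tissue \eqn{\delta^{18}O}
#'   offsets (permil); antler default +1 above bone.
#' @param antler_frac Fraction of antler samples (rest are bone).
#' @param year_range Calendar years of death, drawn uniformly.
#' @param atm_record Optional atmosphere record from
#'   [make_atmosphere_record()]; enables \eqn{\delta^{13}C} simulation.
#' @param d13c_base Mean tissue \eqn{\delta^{13}C} (permil VPDB) of bone at
#'   the reference year.
#' @param antler_c_offset Antler \eqn{^{13}C} enrichment relative to bone.
#' @param d13c_sd Tissue \eqn{\delta^{13}C} noise SD.
#' @param d13c_ref_year Year whose atmospheric value anchors `d13c_base`.
#'
#' @return Tibble, one row per individual: id, sex, tissue, year of death,
#'   true origin, death site, displacement, `local` flag, tissue values
#'   (`sr87_86`, `d18o_water`, and `d13c_vpdb_raw` if simulated).
#' @export
simulate_individuals <- function(truth, n, frac_nonlocal = 0.15,
                                 displacement_km = NULL,
                                 tissue_sr_sd = 0.002, tissue_o_sd = 0.3,
                                 seed = 1,
                                 antler_o_offset = 1, bone_o_offset = 0,
                                 antler_frac = 15 / 65,
                                 year_range = c(1800, 1994),
                                 atm_record = NULL,
                                 d13c_base = -16.2, antler_c_offset = 1.3,
                                 d13c_sd = 1.0, d13c_ref_year = 1994) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (frac_nonlocal < 0 || frac_nonlocal > 1) {
    stop("frac_nonlocal must be in [0, 1]", call. = FALSE)
  }
  g <- truth$sr_field
  if (is.null(displacement_km)) {
    displacement_km <- 3 * truth$correlation_length_km
  }
  extent_km <- haversine_km(g$xmin, g$ymax,
                            g$xmin + ncol(g$values) * g$xres,
                            g$ymax - nrow(g$values) * g$yres)
  if (displacement_km > extent_km) {
    stop("displacement_km exceeds the grid extent", call. = FALSE)
  }
  set.seed(as.integer(seed))

  rc <- sample_land_cells(g, n, replace = TRUE)
  origin_lon <- rg_lon_centers(g)[rc$col]
  origin_lat <- rg_lat_centers(g)[rc$row]
  nonlocal <- seq_len(n) <= round(frac_nonlocal * n)
  nonlocal <- sample(nonlocal) # random order

  death_lon <- origin_lon
  death_lat <- origin_lat
  for (i in which(nonlocal)) {
    if (displacement_km == 0) break
    for (try in 1:200) {
      b <- stats::runif(1, 0, 360)
      d <- dest_point(origin_lon[i], origin_lat[i], b, displacement_km)
      if (!is.na(rg_extract(g, d$lon, d$lat))) {
        death_lon[i] <- d$lon; death_lat[i] <- d$lat
        break
      }
    }
    if (death_lon[i] == origin_lon[i] && death_lat[i] == origin_lat[i]) {
      stop("could not place displaced death site on land for individual ", i,
           call. = FALSE)
    }
  }

  tissue <- ifelse(stats::runif(n) < antler_frac, "antler", "bone")
  sex <- sample(c("M", "F", "unknown"), n, replace = TRUE,
                prob = c(29, 17, 19) / 65)
  year <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
  o_offset <- ifelse(tissue == "antler", antler_o_offset, bone_o_offset)

  out <- tibble::tibble(
    sample_id = sprintf("SIM_%03d", seq_len(n)),
    tissue = tissue, sex = sex, year = year,
    true_origin_lon = origin_lon, true_origin_lat = origin_lat,
    lon = death_lon, lat = death_lat,
    displacement_km = ifelse(nonlocal, displacement_km, 0),
    local = !nonlocal,
    sr87_86 = rg_extract(truth$sr_field, origin_lon, origin_lat) +
      stats::rnorm(n, 0, tissue_sr_sd),
    d18o_water = rg_extract(truth$o_field, origin_lon, origin_lat) +
      o_offset + stats::rnorm(n, 0, tissue_o_sd)
  )
  if (!is.null(atm_record)) {
    fit <- suess_fit(atm_record)
    trend <- suess_level(fit, out$year) - suess_level(fit, d13c_ref_year)
    out$d13c_vpdb_raw <- d13c_base +
      ifelse(tissue == "antler", antler_c_offset, 0) + trend +
      stats::rnorm(n, 0, d13c_sd)
  }
  out
}

#' Synthetic atmospheric CO2 carbon-isotope record
#'
#' A smooth, monotone decline emulating the industrial-era Suess effect:
#' \eqn{\delta^{13}C_{atm}(y) = base - decline \cdot t^2} with
#' \eqn{t = (y - y_0)/(y_1 - y_0)}, i.e. slow early decline accelerating
#' toward the present. By construction
#' `record(year_start) - record(year_end) = total_decline`.
#'
#' @param year_start,year_end Span (annual resolution); start < end.
#' @param total_decline Total decline in permil over the span.
#' @param base \eqn{\delta^{13}C} at `year_start` (permil VPDB).
#' @return Tibble with `year`, `d13c_atm`.
#' @export
make_atmosphere_record <- function(year_start = 1800, year_end = 1994,
                                   total_decline = 1.5, base = -6.4) {
  if (year_start >= year_end) stop("year_start must precede year_end", call. = FALSE)
  year <- seq(year_start, year_end)
  t <- (year - year_start) / (year_end - year_start)
  tibble::tibble(year = year, d13c_atm = base - total_decline * t^2)
}
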