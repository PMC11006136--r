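# Local vs non-local analysis: buffered raster extraction at death sites,
# sample-minus-isoscape deltas, buffer-radius scan, the 1-sigma rule,
# group-difference tests, and the d13C vs forest-cover regression.

#' Buffered raster extraction around a point
#'
#' Unweighted mean over non-nodata cells whose centers lie within
#' `radius_km` (great-circle, 6371-km sphere) of the point. If no cell
#' center falls inside the buffer, falls back to the single containing cell.
#'
#' @param raster A [raster_grid()].
#' @param lon,lat Point inside the raster footprint.
#' @param radius_km Buffer radius in km.
#' @return Scalar mean; `NA` (with a warning) if all buffered cells are
#'   nodata.
#' @export
extract_buffered <- function(raster, lon, lat, radius_km) {
  stopifnot(inherits(raster, "raster_grid"), length(lon) == 1, length(lat) == 1)
  rc <- rg_cell_of(raster, lon, lat)
  if (is.na(rc$row)) stop("point is outside the raster footprint", call. = FALSE)
  lons <- rg_lon_centers(raster)
  lats <- rg_lat_centers(raster)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  d <- haversine_km(rep(lons, each = nr), rep(lats, times = nc), lon, lat)
  inside <- d <= radius_km
  if (!any(inside)) {
    v <- raster$values[rc$row, rc$col]
  } else {
    v <- raster$values[inside]
  }
  v <- v[is.finite(v)]
  if (!length(v)) {
    warning("all cells in the buffer are nodata", call. = FALSE)
    return(NA_real_)
  }
  mean(v)
}

# vectorized over points
extract_buffered_many <- function(raster, lon, lat, radius_km) {
  purrr::map2_dbl(lon, lat, function(x, y) extract_buffered(raster, x, y, radius_km))
}

#' Sample-minus-isoscape deltas at death locations
#'
#' For every sample, extracts the buffered isoscape means at its location
#' and computes \eqn{\Delta = sample - isoscape} for Sr and for O (on the
#' drinking-water-equivalent scale, so [convert_samples()] must have been
#' applied first when starting from carbonate values).
#'
#' @param samples Tibble with `sample_id`, `lon`, `lat`, `sr87_86`,
#'   `d18o_water`.
#' @param sr_surface,o_surface Isoscape [raster_grid()]s.
#' @param radius_km Buffer radius (default 10 km).
#' @return A `delta_table` tibble: input columns plus `buffered_sr`,
#'   `buffered_o`, `delta_sr`, `delta_o`; distribution statistics and the
#'   radius are attached as attributes and reported by
#'   [glance.delta_table()].
#' @export
compute_deltas <- function(samples, sr_surface, o_surface, radius_km = 10) {
  stopifnot(all(c("sample_id", "lon", "lat", "sr87_86", "d18o_water") %in%
                  names(samples)))
  out <- dplyr::mutate(
    samples,
    buffered_sr = extract_buffered_many(sr_surface, .data$lon, .data$lat, radius_km),
    buffered_o = extract_buffered_many(o_surface, .data$lon, .data$lat, radius_km),
    delta_sr = .data$sr87_86 - .data$buffered_sr,
    delta_o = .data$d18o_water - .data$buffered_o
  )
  attr(out, "radius_km") <- radius_km
  attr(out, "delta_stats") <- list(
    mean_sr = mean(out$delta_sr, na.rm = TRUE),
    sd_sr = stats::sd(out$delta_sr, na.rm = TRUE),
    mean_o = mean(out$delta_o, na.rm = TRUE),
    sd_o = stats::sd(out$delta_o, na.rm = TRUE)
  )
  class(out) <- c("delta_table", class(out))
  out
}

#' @exportS3Method generics::glance
glance.delta_table <- function(x, ...) {
  s <- attr(x, "delta_stats")
  tibble::tibble(
    n = nrow(x), radius_km = attr(x, "radius_km"),
    mean_delta_sr = s$mean_sr, sd_delta_sr = s$sd_sr,
    median_delta_sr = stats::median(x$delta_sr, na.rm = TRUE),
    mean_delta_o = s$mean_o, sd_delta_o = s$sd_o,
    median_delta_o = stats::median(x$delta_o, na.rm = TRUE),
    n_local = if ("local_flag" %in% names(x)) sum(x$local_flag) else NA_integer_
  )
}

#' Classify samples as local or non-local with the 1-sigma rule
#'
#' Mean and SD of each delta distribution are computed once over all samples
#' (outliers included, no iterative re-trimming). A sample is local iff its
#' `delta_sr` and `delta_o` both lie within `sigma` standard deviations of
#' the respective mean; outside on either axis makes it non-local.
#'
#' @param deltas A [compute_deltas()] table with >= 3 samples.
#' @param sigma Width of the acceptance band in SDs (default 1).
#' @return The table with a `local_flag` column; updated statistics kept in
#'   attributes.
#' @export
classify_local <- function(deltas, sigma = 1) {
  stopifnot(inherits(deltas, "delta_table"))
  if (nrow(deltas) < 3) stop("need at least 3 samples to classify", call. = FALSE)
  s <- attr(deltas, "delta_stats")
  if ((is.na(s$sd_sr) || s$sd_sr == 0) && (is.na(s$sd_o) || s$sd_o == 0)) {
    warning("zero spread in the delta distributions; all samples local",
            call. = FALSE)
    deltas$local_flag <- TRUE
    return(deltas)
  }
  within <- function(d, m, sd) {
    if (is.na(sd) || sd == 0) rep(TRUE, length(d)) else abs(d - m) <= sigma * sd
  }
  deltas$local_flag <- within(deltas$delta_sr, s$mean_sr, s$sd_sr) &
    within(deltas$delta_o, s$mean_o, s$sd_o)
  deltas
}

#' Choose the buffer radius by maximizing sample-isoscape agreement
#'
#' For each candidate radius, regresses the sample values on the buffered
#' isoscape values (OLS) and records \eqn{R^2}; returns the radius with the
#' highest \eqn{R^2}, ties broken toward the smallest radius.
#'
#' @param samples Sample tibble (`lon`, `lat` and `value_col`).
#' @param surface Isoscape [raster_grid()].
#' @param radii Candidate radii in km (>= 2 unless a single value).
#' @param value_col Sample column regressed on the buffered extraction.
#' @return List with `best_radius` and `table` (tibble radius_km, r2, n).
#' @export
scan_buffer_radius <- function(samples, surface, radii,
                               value_col = "sr87_86") {
  stopifnot(length(radii) >= 1)
  rows <- purrr::map(radii, function(r) {
    buf <- extract_buffered_many(surface, samples$lon, samples$lat, r)
    ok <- stats::complete.cases(buf, samples[[value_col]])
    if (sum(ok) < 3) {
      warning("radius ", r, " km yields fewer than 3 valid pairs; skipped",
              call. = FALSE)
      return(tibble::tibble(radius_km = r, r2 = NA_real_, n = sum(ok)))
    }
    fit <- stats::lm(samples[[value_col]][ok] ~ buf[ok])
    tibble::tibble(radius_km = r, r2 = summary(fit)$r.squared, n = sum(ok))
  })
  tab <- dplyr::bind_rows(rows)
  valid <- dplyr::filter(tab, is.finite(.data$r2))
  if (nrow(valid) == 0) stop("no radius yielded enough valid pairs", call. = FALSE)
  best <- valid$radius_km[order(-valid$r2, valid$radius_km)][1]
  list(best_radius = best, table = tab)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. With both group sizes at most
#' `exact_max`, the p-value is computed by exhaustive enumeration of all
#' group assignments of the (tie-averaged) pooled ranks; otherwise the
#' normal approximation with tie-corrected variance is used.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector with exactly two distinct levels.
#' @param exact_max Enumeration threshold per group (default 8).
#' @return Tibble with `u` (U of the first level, sorted order), `p`,
#'   `method`, and the group sizes.
#' @export
group_difference_test <- function(values, groups, exact_max = 8) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("need exactly two groups", call. = FALSE)
  na <- sum(groups == lev[1]); nb <- sum(groups == lev[2])
  if (na == 0 || nb == 0) stop("one group is empty", call. = FALSE)
  r <- rank(values)
  u_of <- function(rank_sum_a) rank_sum_a - na * (na + 1) / 2
  u_obs <- u_of(sum(r[groups == lev[1]]))
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    sets <- utils::combn(na + nb, na)
    u_all <- u_of(colSums(matrix(r[sets], nrow = na)))
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
    method <- "normal approximation (tie-corrected)"
  }
  tibble::tibble(u = u_obs, p = p, method = method,
                 n1 = na, n2 = nb, group1 = lev[1], group2 = lev[2])
}

#' Sex and tissue comparisons of the delta distributions
#'
#' Runs the Mann-Whitney comparisons the workflow reports: male vs female
#' deltas on all samples and on bones only (unknown sex excluded), and
#' antler vs bone deltas.
#'
#' @param deltas A [compute_deltas()] table with `sex` and `tissue` columns.
#' @return Tibble of test results, one row per comparison and axis.
#' @export
group_comparisons <- function(deltas) {
  stopifnot(all(c("sex", "tissue", "delta_sr", "delta_o") %in% names(deltas)))
  runs <- list(
    list(name = "sex_all", data = dplyr::filter(deltas, .data$sex %in% c("M", "F")),
         g = "sex"),
    list(name = "sex_bone", data = dplyr::filter(deltas, .data$sex %in% c("M", "F"),
                                                 .data$tissue == "bone"),
         g = "sex"),
    list(name = "tissue_all", data = deltas, g = "tissue")
  )
  purrr::map_dfr(runs, function(run) {
    purrr::map_dfr(c(sr = "delta_sr", o = "delta_o"), function(col) {
      if (length(unique(run$data[[run$g]])) != 2 || nrow(run$data) < 2) {
        return(tibble::tibble())
      }
      res <- group_difference_test(run$data[[col]], run$data[[run$g]])
      dplyr::mutate(res, comparison = run$name,
                    axis = sub("delta_", "", col), .before = 1)
    })
  })
}

#' Regress tissue d13C on buffered forest cover
#'
#' OLS of (Suess-corrected) \eqn{\delta^{13}C} on percent forest cover
#' extracted with the standard buffer, reported separately for bone, antler
#' and combined. Samples flagged non-local must be excluded beforehand (a
#' `local_flag` column, if present, is applied).
#'
#' @param samples Tibble with `lon`, `lat`, `tissue` and the response column.
#' @param cover_raster Forest-cover [raster_grid()] (percent).
#' @param radius_km Buffer radius (default 10 km).
#' @param response Response column (default `d13c_suess`).
#' @return Tibble: group, n, slope, r2, p.
#' @export
forest_cover_regression <- function(samples, cover_raster, radius_km = 10,
                                    response = "d13c_suess") {
  stopifnot(all(c("lon", "lat", "tissue", response) %in% names(samples)))
  if ("local_flag" %in% names(samples)) {
    samples <- dplyr::filter(samples, .data$local_flag)
  }
  samples$cover <- extract_buffered_many(cover_raster, samples$lon,
                                         samples$lat, radius_km)
  fit_one <- function(d, label) {
    d <- d[stats::complete.cases(d$cover, d[[response]]), ]
    if (nrow(d) < 3) return(tibble::tibble())
    if (stats::sd(d$cover) == 0) {
      stop("forest cover is constant across samples (", label,
           "); slope undefined", call. = FALSE)
    }
    fit <- stats::lm(d[[response]] ~ d$cover)
    s <- summary(fit)
    tibble::tibble(group = label, n = nrow(d),
                   slope = unname(stats::coef(fit)[2]), r2 = s$r.squared,
                   p = s$coefficients[2, 4])
  }
  dplyr::bind_rows(
    fit_one(dplyr::filter(samples, .data$tissue == "bone"), "bone"),
    fit_one(dplyr::filter(samples, .data$tissue == "antler"), "antler"),
    fit_one(samples, "combined")
  )
}
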