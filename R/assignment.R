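# Bayesian continuous-surface assignment of origin: per-cell Normal
# likelihood of the observed tissue value against the calibrated isoscape
# mean and uncertainty under a flat prior over the raster footprint.

#' Posterior probability-of-origin surface for one observation
#'
#' Per-cell unnormalized density \eqn{\phi(observed;\ mean_{cell},
#' sd_{cell})}, normalized to unit total mass over the non-nodata footprint
#' (flat prior). Computed in log space so distant observations cannot
#' underflow to an all-zero surface. Masses are per cell; optional
#' cos(latitude) weighting converts the flat prior to per-area.
#'
#' @param observed Observed tissue value (calibrated-isoscape scale).
#' @param mean_surface,sd_surface Co-registered mean and uncertainty
#'   [raster_grid()]s; `sd > 0` on every non-nodata cell.
#' @param sample_id Optional id stored on the result.
#' @param system Evidence label (`"Sr"`, `"O"`, or `"joint"`).
#' @param area_weight Weight cell priors by cos(latitude) (default off:
#'   masses are per cell).
#' @return A `posterior_surface`: a [raster_grid()] of per-cell masses
#'   summing to 1, with `sample_id` and `system` attributes.
#' @export
posterior_surface <- function(observed, mean_surface, sd_surface,
                              sample_id = NULL, system = "Sr",
                              area_weight = FALSE) {
  stopifnot(is.finite(observed))
  if (!rg_same_grid(mean_surface, sd_surface)) {
    stop("mean and sd surfaces are not co-registered", call. = FALSE)
  }
  m <- mean_surface$values
  s <- sd_surface$values
  valid <- is.finite(m) & is.finite(s)
  if (!any(valid)) stop("no valid cells", call. = FALSE)
  bad_sd <- valid & s <= 0
  if (any(bad_sd)) {
    idx <- which(bad_sd, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive sd at cell (row %d, col %d)", idx[1], idx[2]),
         call. = FALSE)
  }
  logd <- matrix(NA_real_, nrow(m), ncol(m))
  logd[valid] <- stats::dnorm(observed, m[valid], s[valid], log = TRUE)
  if (area_weight) {
    w <- matrix(cos(rg_lat_centers(mean_surface) * pi / 180),
                nrow(m), ncol(m))
    logd[valid] <- logd[valid] + log(w[valid])
  }
  logd[valid] <- logd[valid] - max(logd[valid])
  mass <- matrix(NA_real_, nrow(m), ncol(m))
  mass[valid] <- exp(logd[valid])
  mass[valid] <- mass[valid] / sum(mass[valid])
  out <- raster_grid(mass, mean_surface$xmin, mean_surface$ymax,
                     mean_surface$xres, mean_surface$yres,
                     crs = mean_surface$crs)
  structure(c(out, list(sample_id = sample_id, system = system)),
            class = c("posterior_surface", "raster_grid"))
}

#' Combine two posterior surfaces assuming independence
#'
#' Per-cell product of the two masses, renormalized (the
#' conditional-independence combination of Sr and O evidence). Commutative;
#' a uniform input leaves the other unchanged.
#'
#' @param p_a,p_b `posterior_surface`s on the same footprint.
#' @return A joint `posterior_surface`.
#' @export
joint_posterior <- function(p_a, p_b) {
  stopifnot(inherits(p_a, "posterior_surface"), inherits(p_b, "posterior_surface"))
  if (!rg_same_grid(p_a, p_b)) stop("footprint mismatch", call. = FALSE)
  prod <- p_a$values * p_b$values
  valid <- is.finite(prod)
  if (!any(valid) || sum(prod[valid]) <= 0) {
    stop("joint posterior has zero total mass", call. = FALSE)
  }
  prod[valid] <- prod[valid] / sum(prod[valid])
  out <- raster_grid(prod, p_a$xmin, p_a$ymax, p_a$xres, p_a$yres, crs = p_a$crs)
  structure(c(out, list(sample_id = p_a$sample_id, system = "joint")),
            class = c("posterior_surface", "raster_grid"))
}

#' Top-quantile origin region
#'
#' Marks the most probable origin cells. In `"area"` mode (default) the mask
#' holds the top \eqn{\lceil q N_{valid} \rceil} cells by posterior mass; in
#' `"probability"` mode, the smallest set of top cells whose cumulative mass
#' reaches `q`. Ties at the threshold are all included.
#'
#' @param p A `posterior_surface`.
#' @param q Quantile fraction in (0, 1) (default 0.05).
#' @param mode `"area"` or `"probability"`.
#' @return A logical-valued [raster_grid()] (1 = in region, 0 = out, `NA` =
#'   nodata).
#' @export
top_quantile_region <- function(p, q = 0.05, mode = c("area", "probability")) {
  stopifnot(inherits(p, "posterior_surface"), q > 0, q < 1)
  mode <- match.arg(mode)
  v <- p$values
  valid <- which(is.finite(v))
  vals <- v[valid]
  ord <- order(vals, decreasing = TRUE)
  if (mode == "area") {
    k <- ceiling(q * length(valid))
  } else {
    k <- which(cumsum(vals[ord]) >= q - 1e-12)[1]
  }
  threshold <- vals[ord[k]]
  mask <- matrix(NA_real_, nrow(v), ncol(v))
  mask[valid] <- as.numeric(vals >= threshold)
  raster_grid(mask, p$xmin, p$ymax, p$xres, p$yres, crs = p$crs)
}

#' Distance-of-origin density from a posterior surface
#'
#' Great-circle distance from the death site to every cell center;
#' posterior mass accumulated into half-open distance bins
#' `[lo, hi)` of width `bin_width_km`, normalized to unit mass.
#'
#' @param p A `posterior_surface`.
#' @param death_lon,death_lat Death-site coordinates.
#' @param bin_width_km Bin width in km (default 10).
#' @param cutoff_km Annotation-only reference distance stored on the result
#'   (default 100 km).
#' @return A `distance_density` tibble: `bin_lo_km`, `bin_hi_km`, `mass`.
#' @export
distance_density <- function(p, death_lon, death_lat, bin_width_km = 10,
                             cutoff_km = 100) {
  stopifnot(inherits(p, "posterior_surface"),
            is.finite(death_lon), is.finite(death_lat))
  nr <- nrow(p$values); nc <- ncol(p$values)
  lons <- rep(rg_lon_centers(p), each = nr)
  lats <- rep(rg_lat_centers(p), times = nc)
  d <- haversine_km(lons, lats, death_lon, death_lat)
  mass <- as.vector(p$values)
  ok <- is.finite(mass)
  bin <- floor(d[ok] / bin_width_km)
  agg <- tapply(mass[ok], bin, sum)
  out <- tibble::tibble(
    bin_lo_km = as.numeric(names(agg)) * bin_width_km,
    bin_hi_km = (as.numeric(names(agg)) + 1) * bin_width_km,
    mass = as.numeric(agg)
  ) |> dplyr::arrange(.data$bin_lo_km)
  attr(out, "death_lon") <- death_lon
  attr(out, "death_lat") <- death_lat
  attr(out, "cutoff_km") <- cutoff_km
  class(out) <- c("distance_density", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
#' @rdname distance_density
#' @param object A `distance_density`.
#' @param ... Unused.
autoplot.distance_density <- function(object, ...) {
  df <- tibble::tibble(mid = (object$bin_lo_km + object$bin_hi_km) / 2,
                       mass = object$mass)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mass)) +
    ggplot2::geom_col(width = object$bin_hi_km[1] - object$bin_lo_km[1],
                      fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff_km"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Distance from death site (km)",
                  y = "Posterior mass") +
    ggplot2::theme_minimal()
}

#' Batch assignment of non-local samples
#'
#' For every sample flagged non-local, computes the Sr posterior, the O
#' posterior, their joint combination, and the distance-of-origin density of
#' the joint surface (Sr-only if no O surfaces are given).
#'
#' @param samples Tibble with `sample_id`, `lon`, `lat`, `sr87_86`,
#'   `d18o_water` and (optionally) `local_flag`; rows with
#'   `local_flag = FALSE` are assigned. Without a `local_flag` column all
#'   rows are assigned.
#' @param sr_mean,sr_sd Calibrated Sr isoscape and uncertainty rasters.
#' @param o_mean,o_sd Calibrated O isoscape and uncertainty rasters
#'   (optional).
#' @param bin_width_km Distance-density bin width.
#' @param area_weight Passed to [posterior_surface()].
#' @return Named list (by sample id) of lists with elements `sr`, `o`,
#'   `joint` (posterior surfaces) and `distance` (a [distance_density()]).
#'   Empty list if no sample is non-local.
#' @export
assign_outliers <- function(samples, sr_mean, sr_sd, o_mean = NULL,
                            o_sd = NULL, bin_width_km = 10,
                            area_weight = FALSE) {
  if ("local_flag" %in% names(samples)) {
    samples <- dplyr::filter(samples, !.data$local_flag)
  }
  if (nrow(samples) == 0) return(list())
  out <- purrr::map(seq_len(nrow(samples)), function(i) {
    row <- samples[i, ]
    p_sr <- posterior_surface(row$sr87_86, sr_mean, sr_sd,
                              sample_id = row$sample_id, system = "Sr",
                              area_weight = area_weight)
    res <- list(sr = p_sr, o = NULL, joint = p_sr)
    if (!is.null(o_mean) && "d18o_water" %in% names(row) &&
        is.finite(row$d18o_water)) {
      p_o <- posterior_surface(row$d18o_water, o_mean, o_sd,
                               sample_id = row$sample_id, system = "O",
                               area_weight = area_weight)
      res$o <- p_o
      res$joint <- joint_posterior(p_sr, p_o)
    }
    res$distance <- distance_density(res$joint, row$lon, row$lat,
                                     bin_width_km = bin_width_km)
    res
  })
  stats::setNames(out, samples$sample_id)
}
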