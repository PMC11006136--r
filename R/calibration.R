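# Linear calibration of an isoscape against "local" tissue samples:
# classical calibration (sample regressed on isoscape, fitted map applied to
# the raster), with residual scatter propagated into the uncertainty map.

#' Fit the sample-vs-isoscape linear calibration
#'
#' OLS of the sample value (response) on the buffered isoscape value
#' (predictor), fitted on samples classified local. The residual SD
#' \eqn{\sqrt{SS_{res}/(n-2)}} captures calibration scatter and is later
#' combined with the spatial uncertainty map.
#'
#' @param pairs Tibble of local samples.
#' @param isoscape_col,sample_col Column names of the isoscape and sample
#'   values (defaults `buffered_sr`, `sr87_86`).
#' @param system Label stored with the fit (`"Sr"` or `"O"`).
#' @param excluded_ids Ids excluded upstream (bookkeeping only).
#' @return A `calibration_fit`: slope/intercept with SEs, `r2`, `p`,
#'   `residual_sd`, `n_used`, `system`, `excluded_ids`, and the underlying
#'   `lm` fit.
#' @export
fit_calibration <- function(pairs, isoscape_col = "buffered_sr",
                            sample_col = "sr87_86", system = "Sr",
                            excluded_ids = character()) {
  x <- pairs[[isoscape_col]]
  y <- pairs[[sample_col]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 local pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: isoscape values constant",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    slope_se = s$coefficients[2, 2],
    intercept = unname(stats::coef(fit)[1]),
    intercept_se = s$coefficients[1, 2],
    r2 = s$r.squared,
    p = s$coefficients[2, 4],
    residual_sd = sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2)),
    n_used = length(x),
    system = system,
    excluded_ids = excluded_ids,
    lm = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> %s: slope %.3g +/- %.2g, intercept %.3g +/- %.2g, R2 %.3f (n = %d, residual SD %.3g)\n",
    x$system, x$slope, x$slope_se, x$intercept, x$intercept_se,
    x$r2, x$n_used, x$residual_sd
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(system = x$system, r.squared = x$r2, p.value = x$p,
                 residual_sd = x$residual_sd, n_used = x$n_used)
}

#' Apply a calibration fit to an isoscape raster
#'
#' Per-cell affine map `intercept + slope * value`; nodata preserved.
#'
#' @param surface Isoscape [raster_grid()].
#' @param fit A [fit_calibration()] result.
#' @return Calibrated [raster_grid()].
#' @export
apply_calibration <- function(surface, fit) {
  stopifnot(inherits(fit, "calibration_fit"), inherits(surface, "raster_grid"))
  rg_map(surface, function(v) fit$intercept + fit$slope * v)
}

#' Propagate spatial and calibration uncertainty
#'
#' Per-cell \eqn{\sqrt{(slope \cdot sd)^2 + residual\_sd^2}}: the spatial
#' uncertainty scaled through the calibration, combined in quadrature with
#' the calibration residual scatter.
#'
#' @param surface_sd Uncertainty [raster_grid()] (nonnegative).
#' @param fit A [fit_calibration()] result.
#' @return Calibrated uncertainty [raster_grid()].
#' @export
calibrated_uncertainty <- function(surface_sd, fit) {
  stopifnot(inherits(fit, "calibration_fit"), inherits(surface_sd, "raster_grid"))
  if (any(surface_sd$values < 0, na.rm = TRUE)) {
    stop("uncertainty raster has negative cells", call. = FALSE)
  }
  rg_map(surface_sd, function(v) sqrt((fit$slope * v)^2 + fit$residual_sd^2))
}
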