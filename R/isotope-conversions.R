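# Tissue isotope conversions. All conversions are affine; published constants
# live in iso_constants() with citation strings rather than inside operations,
# so alternative calibrations can be swapped in from configuration.

#' Conversion constants with provenance
#'
#' Default constants used by the conversion operations. Each entry records the
#' source publication the numbers were transcribed from:
#' \describe{
#'   \item{carb_phos}{Carbonate-phosphate relation for mammal bioapatite,
#'     \eqn{\delta^{18}O_c = 1.037\,\delta^{18}O_{PO_4} + 8.57}
#'     (Iacumin et al. 1996, all mammals).}
#'   \item{phos_water}{Cervid drinking-water relation
#'     \eqn{\delta^{18}O_w = 1.23\,\delta^{18}O_{PO_4} - 27.76}
#'     (D'Angela & Longinelli 1990, deer), stored in forward form
#'     \eqn{\delta^{18}O_{PO_4} = slope\,\delta^{18}O_w + intercept}.}
#'   \item{vpdb_vsmow}{IAEA inter-scale relation
#'     \eqn{\delta^{18}O_{VSMOW} = 1.03091\,\delta^{18}O_{VPDB} + 30.91}
#'     (Coplen et al. 1983).}
#' }
#'
#' @return Nested list of constants, each with a `citation` string.
#' @export
iso_constants <- function() {
  list(
    carb_phos = list(slope = 1.037, intercept = 8.57,
                     citation = "Iacumin et al. 1996 (all mammals)"),
    phos_water = list(slope = 1 / 1.23, intercept = 27.76 / 1.23,
                      citation = "D'Angela & Longinelli 1990 (deer)"),
    vpdb_vsmow = list(slope = 1.03091, intercept = 30.91,
                      citation = "Coplen, Kendall & Hopple 1983 (IAEA)")
  )
}

check_finite <- function(x, name) {
  if (any(!is.finite(x))) {
    stop(name, " must be finite", call. = FALSE)
  }
  invisible(x)
}

#' Convert carbonate d18O to phosphate d18O
#'
#' Inverts the forward carbonate-phosphate relation
#' \eqn{\delta^{18}O_c = slope \cdot \delta^{18}O_{PO_4} + intercept},
#' i.e. returns \eqn{(\delta^{18}O_c - intercept)/slope}. Both scales VSMOW.
#'
#' @param d18o_carb Carbonate \eqn{\delta^{18}O} (permil VSMOW), vectorized.
#' @param slope,intercept Forward-relation constants; defaults from
#'   [iso_constants()].
#' @return Phosphate \eqn{\delta^{18}O} (permil VSMOW).
#' @export
#' @examples
#' carbonate_to_phosphate(21.6) # ~12.57 permil
carbonate_to_phosphate <- function(d18o_carb,
                                   slope = iso_constants()$carb_phos$slope,
                                   intercept = iso_constants()$carb_phos$intercept) {
  check_finite(d18o_carb, "d18o_carb")
  (d18o_carb - intercept) / slope
}

#' Convert phosphate d18O to drinking-water d18O
#'
#' The forward relation is \eqn{\delta^{18}O_{PO_4} = slope \cdot
#' \delta^{18}O_w + intercept}; this returns its inverse
#' \eqn{(\delta^{18}O_{PO_4} - intercept)/slope}. Defaults encode the cervid
#' calibration (see [iso_constants()]).
#'
#' @param d18o_phos Phosphate \eqn{\delta^{18}O} (permil VSMOW), vectorized.
#' @param slope,intercept Forward-relation constants; `slope` must be nonzero.
#' @return Ingested-water \eqn{\delta^{18}O} (permil VSMOW).
#' @export
phosphate_to_water <- function(d18o_phos,
                               slope = iso_constants()$phos_water$slope,
                               intercept = iso_constants()$phos_water$intercept) {
  check_finite(d18o_phos, "d18o_phos")
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  (d18o_phos - intercept) / slope
}

#' Inter-convert d18O between the VPDB and VSMOW scales
#'
#' Standard IAEA linear relation
#' \eqn{\delta^{18}O_{VSMOW} = slope \cdot \delta^{18}O_{VPDB} + intercept}.
#'
#' @param d18o Input value(s), permil.
#' @param slope,intercept Scale-conversion constants from [iso_constants()].
#' @return Converted value(s), permil.
#' @export
vpdb_to_vsmow <- function(d18o,
                          slope = iso_constants()$vpdb_vsmow$slope,
                          intercept = iso_constants()$vpdb_vsmow$intercept) {
  check_finite(d18o, "d18o")
  slope * d18o + intercept
}

#' @rdname vpdb_to_vsmow
#' @export
vsmow_to_vpdb <- function(d18o,
                          slope = iso_constants()$vpdb_vsmow$slope,
                          intercept = iso_constants()$vpdb_vsmow$intercept) {
  check_finite(d18o, "d18o")
  (d18o - intercept) / slope
}

#' Fit a smooth trend to an atmospheric CO2 d13C record
#'
#' LOESS fit (span 0.3, degree 2 by default) of \eqn{\delta^{13}C_{atm}}
#' against year at the record's native resolution. The fitted trend is the
#' basis of the Suess-effect correction.
#'
#' @param atm_record Data frame with columns `year` and `d13c_atm`.
#' @param span,degree LOESS parameters; the defaults smooth the secular trend
#'   without chasing interannual noise.
#' @return A `suess_fit` object (LOESS fit + record span).
#' @export
suess_fit <- function(atm_record, span = 0.3, degree = 2) {
  stopifnot(all(c("year", "d13c_atm") %in% names(atm_record)))
  fit <- stats::loess(d13c_atm ~ year, data = atm_record, span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  structure(list(fit = fit,
                 year_min = min(atm_record$year),
                 year_max = max(atm_record$year)),
            class = "suess_fit")
}

# fitted atmospheric level at given years, with optional constant
# continuation of the terminal fitted values beyond the record span
suess_level <- function(sf, years, extrapolate = FALSE) {
  stopifnot(inherits(sf, "suess_fit"))
  outside <- years < sf$year_min | years > sf$year_max
  if (any(outside) && !extrapolate) {
    stop("year(s) outside the atmospheric record span (",
         sf$year_min, "-", sf$year_max, "); extrapolation is disabled",
         call. = FALSE)
  }
  clamped <- pmin(pmax(years, sf$year_min), sf$year_max)
  as.numeric(stats::predict(sf$fit, newdata = data.frame(year = clamped)))
}

#' Suess-correct tissue d13C to a reference year
#'
#' Removes the anthropogenic atmospheric \eqn{\delta^{13}C} trend:
#' returns \eqn{\delta^{13}C_{measured} - [L(year_{death}) - L(year_{ref})]}
#' where \eqn{L} is the LOESS trend of the atmospheric record. The default
#' reference year is 1994; 1800 is the usual pre-industrial alternative.
#'
#' @param d13c_measured Measured \eqn{\delta^{13}C} (permil VPDB), vectorized.
#' @param year_death Calendar year(s) of death (recycled against values).
#' @param ref_year Reference year the values are reported to.
#' @param atm_record Atmospheric record (data frame `year`, `d13c_atm`) or a
#'   prefitted [suess_fit()].
#' @param extrapolate Continue the terminal fitted value beyond the record
#'   span instead of erroring (off by default).
#' @inheritParams suess_fit
#' @return Corrected \eqn{\delta^{13}C} (permil VPDB).
#' @export
suess_correct <- function(d13c_measured, year_death, ref_year = 1994,
                          atm_record, span = 0.3, degree = 2,
                          extrapolate = FALSE) {
  check_finite(d13c_measured, "d13c_measured")
  sf <- if (inherits(atm_record, "suess_fit")) {
    atm_record
  } else {
    suess_fit(atm_record, span = span, degree = degree)
  }
  d13c_measured - (suess_level(sf, year_death, extrapolate) -
                     suess_level(sf, ref_year, extrapolate))
}

#' Apply all tissue conversions to a sample table
#'
#' Adds the derived columns the downstream workflow needs:
#' `d18o_phos_vsmow`, `d18o_water` (carbonate to phosphate to drinking
#' water) and, when a `d13c_vpdb` (or `d13c_vpdb_raw`) column and an
#' atmospheric record are present, Suess-corrected `d13c_suess`.
#'
#' @param samples Sample tibble with at least `d18o_carb_vsmow`; `year` and a
#'   raw \eqn{\delta^{13}C} column enable the Suess correction.
#' @param atm_record Optional atmospheric record for the Suess correction.
#' @param ref_year Reference year for the Suess correction.
#' @param constants Constant set, defaults [iso_constants()].
#' @return The input tibble with derived columns appended.
#' @export
convert_samples <- function(samples, atm_record = NULL, ref_year = 1994,
                            constants = iso_constants()) {
  stopifnot("d18o_carb_vsmow" %in% names(samples))
  out <- dplyr::mutate(
    samples,
    d18o_phos_vsmow = carbonate_to_phosphate(
      .data$d18o_carb_vsmow,
      slope = constants$carb_phos$slope,
      intercept = constants$carb_phos$intercept),
    d18o_water = phosphate_to_water(
      .data$d18o_phos_vsmow,
      slope = constants$phos_water$slope,
      intercept = constants$phos_water$intercept)
  )
  c_col <- intersect(c("d13c_vpdb", "d13c_vpdb_raw"), names(samples))[1]
  if (!is.null(atm_record) && !is.na(c_col)) {
    stopifnot("year" %in% names(samples))
    out$d13c_suess <- suess_correct(out[[c_col]], out$year,
                                    ref_year = ref_year,
                                    atm_record = atm_record)
  }
  out
}
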