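# Random-forest Sr isoscape: predictor selection by permutation importance,
# quantile-forest fit, 10-fold CV, spatial prediction and uncertainty map.
# Coordinates are never predictors; only the environmental stack is.

# predictor values at point locations; errors name the offending rows
extract_stack <- function(stack, lon, lat, ids = seq_along(lon)) {
  stopifnot(length(stack) >= 1, !is.null(names(stack)))
  df <- purrr::map_dfc(stack, function(g) rg_extract(g, lon, lat))
  bad <- !stats::complete.cases(df)
  if (any(bad)) {
    stop("training point(s) off-grid or on nodata cells: ",
         paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
  }
  df
}

training_frame <- function(training, stack, predictors = NULL,
                           response = "sr87_86") {
  stopifnot(all(c("lon", "lat", response) %in% names(training)))
  if (is.null(predictors)) predictors <- names(stack)
  missing <- setdiff(predictors, names(stack))
  if (length(missing)) {
    stop("predictor(s) missing from the stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- if ("sample_id" %in% names(training)) training$sample_id else seq_len(nrow(training))
  x <- extract_stack(stack[predictors], training$lon, training$lat, ids)
  dplyr::bind_cols(tibble::tibble(.response = training[[response]]), x)
}

#' Select informative predictors by permutation importance
#'
#' Fits a preliminary forest on all candidates and retains predictors whose
#' permutation importance is at least `threshold_frac` of the maximum
#' importance. At least one predictor (the most important) is always kept.
#'
#' @param training Tibble with `lon`, `lat` and the response column.
#' @param stack Named list of co-registered [raster_grid()] predictors.
#' @param threshold_frac Retention threshold as a fraction of the top
#'   importance (default 0.05).
#' @param n_trees Trees in the screening forest.
#' @param seed Integer RNG seed.
#' @param response Response column name.
#' @return Character vector of retained predictor names, importance-ordered.
#' @export
select_predictors <- function(training, stack, threshold_frac = 0.05,
                              n_trees = 500, seed = 1,
                              response = "sr87_86") {
  if (length(stack) < 1) stop("empty predictor stack", call. = FALSE)
  df <- training_frame(training, stack, response = response)
  if (nrow(df) < 5 * (ncol(df) - 1)) {
    warning("fewer than 5 training points per candidate predictor; ",
            "importance ranking may be unstable", call. = FALSE)
  }
  if (length(stack) == 1) return(names(stack))
  rf <- ranger::ranger(
    dependent.variable.name = ".response", data = df,
    num.trees = n_trees, importance = "permutation",
    seed = as.integer(seed), num.threads = 1
  )
  imp <- sort(rf$variable.importance, decreasing = TRUE)
  keep <- imp >= threshold_frac * max(imp, 0)
  keep[1] <- TRUE
  names(imp)[keep]
}

#' Fit a quantile random-forest isoscape model
#'
#' Random-forest regression of the point response on the environmental
#' predictor stack (quantile-forest mode, so terminal-node response
#' distributions are retained for the uncertainty map). Defaults follow
#' common regression-forest convention: 1000 trees, `mtry = ceiling(p/3)`.
#' A 10-fold cross-validation is run on fit and its pooled RMSE and
#' \eqn{R^2} stored on the model.
#'
#' @inheritParams select_predictors
#' @param predictors Predictor names to use; default all of `stack`.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Predictors tried per split; default `ceiling(p/3)`.
#' @param cv_folds Folds for the attached cross-validation; 0 skips it.
#' @return An `isoscape_model` with elements `forest`, `predictor_names`,
#'   `training_n`, `seed`, `cv` (a `cv_report` or `NULL`), `cv_rmse`,
#'   `cv_r2`, `oob_rmse`.
#' @export
fit_isoscape <- function(training, stack, predictors = NULL, n_trees = 1000,
                         seed = 1, mtry = NULL, cv_folds = 10,
                         response = "sr87_86") {
  if (is.null(predictors)) predictors <- names(stack)
  df <- training_frame(training, stack, predictors, response)
  p <- length(predictors)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  # quantile-mode node-value sampling draws from R's RNG, so pin it too
  set.seed(as.integer(seed))
  rf <- ranger::ranger(
    dependent.variable.name = ".response", data = df,
    num.trees = n_trees, mtry = min(mtry, p), quantreg = TRUE,
    seed = as.integer(seed), num.threads = 1
  )
  cv <- NULL
  if (cv_folds >= 2) {
    cv <- cross_validate(training, stack, predictors, k = cv_folds,
                         seed = seed, n_trees = n_trees, mtry = mtry,
                         response = response)
  }
  structure(list(
    forest = rf,
    predictor_names = predictors,
    training_n = nrow(df),
    seed = as.integer(seed),
    n_trees = n_trees,
    cv = cv,
    cv_rmse = if (!is.null(cv)) cv$rmse else NA_real_,
    cv_r2 = if (!is.null(cv)) cv$r2 else NA_real_,
    oob_rmse = sqrt(rf$prediction.error),
    response_range = range(df$.response)
  ), class = "isoscape_model")
}

#' @export
print.isoscape_model <- function(x, ...) {
  cat(sprintf(
    "<isoscape_model> %d trees, %d training points, predictors: %s\n  CV RMSE %.4g, CV R2 %.3f (OOB RMSE %.4g)\n",
    x$n_trees, x$training_n, paste(x$predictor_names, collapse = ", "),
    x$cv_rmse, x$cv_r2, x$oob_rmse
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.isoscape_model <- function(x, ...) {
  tibble::tibble(training_n = x$training_n, n_trees = x$n_trees,
                 n_predictors = length(x$predictor_names),
                 cv_rmse = x$cv_rmse, cv_r2 = x$cv_r2,
                 oob_rmse = x$oob_rmse, seed = x$seed)
}

#' K-fold cross-validation of the isoscape regression
#'
#' Random partition of the training points into `k` folds (every point
#' out-of-fold exactly once); a forest is refitted on each training split and
#' the pooled out-of-fold residuals give RMSE and \eqn{R^2 = 1 -
#' SS_{res}/SS_{tot}}.
#'
#' @inheritParams fit_isoscape
#' @param k Number of folds (default 10; must be >= 2 and <= n).
#' @return A `cv_report`: `fold_assignments`, `predictions` (tibble with
#'   observed, predicted, fold), `per_fold_rmse`, pooled `rmse` and `r2`.
#' @export
cross_validate <- function(training, stack, predictors = NULL, k = 10,
                           seed = 1, n_trees = 1000, mtry = NULL,
                           response = "sr87_86") {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(training)) stop("k exceeds the number of training points", call. = FALSE)
  if (is.null(predictors)) predictors <- names(stack)
  df <- training_frame(training, stack, predictors, response)
  p <- length(predictors)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(k), length.out = nrow(df)))
  pred <- rep(NA_real_, nrow(df))
  for (f in seq_len(k)) {
    rf <- ranger::ranger(
      dependent.variable.name = ".response", data = df[folds != f, ],
      num.trees = n_trees, mtry = min(mtry, p),
      seed = as.integer(seed) + f, num.threads = 1
    )
    pred[folds == f] <- stats::predict(rf, df[folds == f, ])$predictions
  }
  res <- df$.response - pred
  per_fold <- purrr::map_dbl(seq_len(k), function(f) sqrt(mean(res[folds == f]^2)))
  structure(list(
    fold_assignments = folds,
    predictions = tibble::tibble(observed = df$.response, predicted = pred,
                                 fold = folds),
    per_fold_rmse = per_fold,
    rmse = sqrt(mean(res^2)),
    r2 = 1 - sum(res^2) / sum((df$.response - mean(df$.response))^2)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds: pooled RMSE %.4g, R2 %.3f\n",
              length(x$per_fold_rmse), x$rmse, x$r2))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble::tibble(k = length(x$per_fold_rmse), rmse = x$rmse, r2 = x$r2)
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$per_fold_rmse), rmse = x$per_fold_rmse)
}

# stack cells valid in every layer -> prediction frame + index
stack_frame <- function(stack, predictors) {
  missing <- setdiff(predictors, names(stack))
  if (length(missing)) {
    stop("predictor(s) missing from the stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- stack[[predictors[1]]]
  for (nm in predictors[-1]) {
    if (!rg_same_grid(ref, stack[[nm]])) {
      stop("stack layers are not co-registered: ", nm, call. = FALSE)
    }
  }
  x <- purrr::map_dfc(stack[predictors], function(g) as.vector(g$values))
  valid <- stats::complete.cases(x)
  list(ref = ref, x = x[valid, , drop = FALSE], valid = which(valid))
}

#' Predict the isoscape surface over a predictor stack
#'
#' Ensemble-mean prediction at every cell valid in all predictor layers;
#' nodata propagated.
#'
#' @param model An [fit_isoscape()] model.
#' @param stack Named list of co-registered predictor rasters containing all
#'   model predictors.
#' @return A [raster_grid()] of predicted values.
#' @export
predict_surface <- function(model, stack) {
  stopifnot(inherits(model, "isoscape_model"))
  sf <- stack_frame(stack, model$predictor_names)
  pred <- stats::predict(model$forest, sf$x, num.threads = 1)$predictions
  out <- matrix(NA_real_, nrow(sf$ref$values), ncol(sf$ref$values))
  out[sf$valid] <- pred
  raster_grid(out, sf$ref$xmin, sf$ref$ymax, sf$ref$xres, sf$ref$yres,
              crs = sf$ref$crs)
}

#' Quantile-forest spatial uncertainty map
#'
#' Per-cell half-width of the central ~68% prediction interval:
#' \eqn{(q_{high} - q_{low})/2} from the quantile forest's terminal-node
#' response distributions. For homoscedastic Normal noise this approximates
#' the noise SD.
#'
#' @inheritParams predict_surface
#' @param q_low,q_high Quantile levels (defaults 0.16 and 0.84).
#' @return A nonnegative [raster_grid()] of uncertainty values.
#' @export
uncertainty_surface <- function(model, stack, q_low = 0.16, q_high = 0.84) {
  stopifnot(inherits(model, "isoscape_model"))
  if (is.null(model$forest$random.node.values)) {
    stop("model was not fitted in quantile mode", call. = FALSE)
  }
  stopifnot(q_low < q_high)
  sf <- stack_frame(stack, model$predictor_names)
  q <- stats::predict(model$forest, sf$x, type = "quantiles",
                      quantiles = c(q_low, q_high), num.threads = 1,
                      seed = model$seed)$predictions
  out <- matrix(NA_real_, nrow(sf$ref$values), ncol(sf$ref$values))
  out[sf$valid] <- (q[, 2] - q[, 1]) / 2
  raster_grid(out, sf$ref$xmin, sf$ref$ymax, sf$ref$xres, sf$ref$yres,
              crs = sf$ref$crs)
}

#' Per-site variability diagnostics of the training compilation
#'
#' Groups training points sharing coordinates (to a float-round-trip
#' tolerance), computes each replicated site's mean and SD, optionally
#' extracts the model error map at the sites, and reports the OLS \eqn{R^2}
#' of SD vs mean, error vs mean, and SD vs error, plus the mean difference
#' between observed SD and mapped error.
#'
#' @param training Tibble with `lon`, `lat` and the response column.
#' @param error_surface Optional uncertainty [raster_grid()] to extract.
#' @param tol Coordinate-equality tolerance in degrees.
#' @param response Response column name.
#' @return List with `sites` (tibble: lon, lat, n, site_mean, site_sd,
#'   extracted_error) and `stats` (tibble of regression \eqn{R^2}s and the
#'   SD-minus-error summary); both empty (with a warning) if no site has
#'   replicates.
#' @export
site_variability_diagnostics <- function(training, error_surface = NULL,
                                         tol = 1e-6, response = "sr87_86") {
  sites <- training |>
    dplyr::mutate(.lon = round(.data$lon / tol) * tol,
                  .lat = round(.data$lat / tol) * tol) |>
    dplyr::group_by(.data$.lon, .data$.lat) |>
    dplyr::summarise(n = dplyr::n(),
                     site_mean = mean(.data[[response]]),
                     site_sd = stats::sd(.data[[response]]),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::rename(lon = ".lon", lat = ".lat")
  if (nrow(sites) == 0) {
    warning("no sites with replicate samples", call. = FALSE)
    return(list(sites = sites, stats = tibble::tibble()))
  }
  if (!is.null(error_surface)) {
    sites$extracted_error <- rg_extract(error_surface, sites$lon, sites$lat)
  } else {
    sites$extracted_error <- NA_real_
  }
  r2_of <- function(y, x) {
    if (sum(stats::complete.cases(y, x)) < 3) return(NA_real_)
    summary(stats::lm(y ~ x))$r.squared
  }
  stats <- tibble::tibble(
    r2_sd_vs_mean = r2_of(sites$site_sd, sites$site_mean),
    r2_error_vs_mean = r2_of(sites$extracted_error, sites$site_mean),
    r2_sd_vs_error = r2_of(sites$site_sd, sites$extracted_error),
    mean_sd_minus_error = mean(sites$site_sd - sites$extracted_error),
    sd_sd_minus_error = stats::sd(sites$site_sd - sites$extracted_error)
  )
  list(sites = sites, stats = stats)
}

#' Load a precipitation d18O isoscape with constant uncertainty
#'
#' Pass-through of the value raster plus a constant-valued uncertainty
#' raster on the same footprint (same nodata cells). The conservative default
#' of 1 permil is an order of magnitude above typical model median errors.
#'
#' @param raster The \eqn{\delta^{18}O} [raster_grid()] (permil VSMOW).
#' @param constant_sd Constant per-cell uncertainty in permil (> 0).
#' @return List with `mean` and `sd` rasters.
#' @export
load_oxygen_isoscape <- function(raster, constant_sd = 1.0) {
  stopifnot(inherits(raster, "raster_grid"))
  if (!is.finite(constant_sd) || constant_sd <= 0) {
    stop("constant_sd must be positive", call. = FALSE)
  }
  sd_r <- rg_map(raster, function(v) ifelse(is.finite(v), constant_sd, NA_real_))
  list(mean = raster, sd = sd_r)
}
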