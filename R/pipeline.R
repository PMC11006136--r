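# Sample-table I/O, validated configuration, and the end-to-end driver:
# convert -> isoscape -> deltas -> classify -> calibrate -> assign -> distance.

SAMPLE_COLUMNS <- c("sample_id", "tissue", "sex", "year", "lon", "lat",
                    "sr87_86", "d18o_carb_vsmow", "d13c_vpdb")

#' Read a tissue sample table from CSV
#'
#' Comma-separated, UTF-8, "." decimal. Required columns: `sample_id`,
#' `tissue`, `sex`, `year`, `lon`, `lat`, `sr87_86`, `d18o_carb_vsmow`,
#' `d13c_vpdb`. Blank sex becomes `"unknown"`; rows with missing coordinates
#' or isotope values are flagged in a `complete` column, never dropped.
#' Sr ratios outside (0.60, 0.90) are rejected as physically impossible.
#'
#' @param path CSV file path.
#' @return Tibble of typed sample records.
#' @export
read_sample_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("no rows in ", path, call. = FALSE)
  missing <- setdiff(SAMPLE_COLUMNS, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    sample_id = trimws(raw$sample_id),
    tissue = tolower(trimws(raw$tissue)),
    sex = dplyr::if_else(trimws(raw$sex) == "" | is.na(raw$sex),
                         "unknown", trimws(raw$sex)),
    year = num("year"),
    lon = num("lon"), lat = num("lat"),
    sr87_86 = num("sr87_86"),
    d18o_carb_vsmow = num("d18o_carb_vsmow"),
    d13c_vpdb = num("d13c_vpdb")
  )
  bad_sr <- which(is.finite(out$sr87_86) &
                    (out$sr87_86 <= 0.60 | out$sr87_86 >= 0.90))
  if (length(bad_sr)) {
    stop("implausible 87Sr/86Sr ratio at row ", bad_sr[1],
         " (must lie in (0.60, 0.90))", call. = FALSE)
  }
  out$complete <- stats::complete.cases(
    out[, c("lon", "lat", "sr87_86", "d18o_carb_vsmow")])
  out
}

#' @rdname read_sample_table
#' @param samples Sample tibble to write.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validated pipeline configuration
#'
#' Assembles and validates every knob of the end-to-end workflow. Unknown
#' arguments are rejected; the configuration (with a hash) is echoed into
#' every output's metadata sidecar.
#'
#' @param radius_km Buffer radius for extraction (km).
#' @param scan_radii Optional radii (km) to scan before fixing `radius_km`.
#' @param sigma_threshold Width of the local acceptance band in SDs.
#' @param ref_year Suess-correction reference year.
#' @param o_constant_sd Constant O-isoscape uncertainty (permil).
#' @param n_trees,rf_seed Random-forest settings.
#' @param cv_folds Cross-validation folds.
#' @param q_low,q_high Uncertainty-map quantile levels.
#' @param top_q Top-quantile fraction for origin regions.
#' @param top_q_mode `"area"` or `"probability"`.
#' @param area_weight cos(latitude) prior weighting for posteriors.
#' @param bin_width_km Distance-density bin width (km).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(radius_km = 10, scan_radii = NULL,
                            sigma_threshold = 1, ref_year = 1994,
                            o_constant_sd = 1, n_trees = 1000, rf_seed = 1,
                            cv_folds = 10, q_low = 0.16, q_high = 0.84,
                            top_q = 0.05, top_q_mode = "area",
                            area_weight = FALSE, bin_width_km = 10) {
  cfg <- list(radius_km = radius_km, scan_radii = scan_radii,
              sigma_threshold = sigma_threshold, ref_year = ref_year,
              o_constant_sd = o_constant_sd, n_trees = n_trees,
              rf_seed = rf_seed, cv_folds = cv_folds,
              q_low = q_low, q_high = q_high, top_q = top_q,
              top_q_mode = top_q_mode, area_weight = area_weight,
              bin_width_km = bin_width_km)
  stopifnot(radius_km > 0, sigma_threshold > 0, o_constant_sd > 0,
            n_trees >= 1, cv_folds >= 0, q_low < q_high,
            top_q > 0, top_q < 1, bin_width_km > 0,
            top_q_mode %in% c("area", "probability"),
            is.logical(area_weight))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected by name; values are validated by
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full dual-isotope provenance pipeline
#'
#' Seven stages: (1) tissue conversions and Suess correction; (2) Sr isoscape
#' fit + uncertainty map and O isoscape ingestion; (3) buffered deltas
#' (radius from config, or chosen by [scan_buffer_radius()]); (4) 1-sigma
#' classification; (5) linear calibration of both isoscapes on locals;
#' (6) Bayesian assignment of non-locals; (7) distance densities. Every
#' artifact is written under `out_dir` and listed in a manifest with MD5
#' checksums; a JSON sidecar records the configuration, its hash, seeds and
#' package version.
#'
#' @param samples Sample tibble (shape of [read_sample_table()] or
#'   [simulate_individuals()]; needs `d18o_carb_vsmow` or `d18o_water`).
#' @param training Sr training tibble (`lon`, `lat`, `sr87_86`).
#' @param stack Named list of predictor [raster_grid()]s.
#' @param o_raster Precipitation \eqn{\delta^{18}O} [raster_grid()].
#' @param atm_record Atmospheric CO2 record (tibble `year`, `d13c_atm`), or
#'   `NULL` to skip the Suess stage's correction.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list: `manifest` (tibble stage/path/md5), `samples`
#'   (classified delta table), `sr_model`, `fits`, `assignments`,
#'   `best_radius`.
#' @export
run_pipeline <- function(samples, training, stack, o_raster,
                         atm_record = NULL, config = pipeline_config(),
                         out_dir = tempfile("isorigin_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  note <- function(stage, path) {
    artifacts[[length(artifacts) + 1L]] <<- tibble::tibble(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  }

  # 1. conversions
  if (!"d18o_water" %in% names(samples)) {
    samples <- convert_samples(samples, atm_record = atm_record,
                               ref_year = config$ref_year)
  } else if (!is.null(atm_record) &&
             any(c("d13c_vpdb", "d13c_vpdb_raw") %in% names(samples)) &&
             !"d13c_suess" %in% names(samples)) {
    c_col <- intersect(c("d13c_vpdb", "d13c_vpdb_raw"), names(samples))[1]
    samples$d13c_suess <- suess_correct(samples[[c_col]], samples$year,
                                        ref_year = config$ref_year,
                                        atm_record = atm_record)
  }
  p <- file.path(out_dir, "samples_converted.csv")
  write_sample_table(samples, p); note("convert", p)

  # 2. isoscapes
  sr_model <- fit_isoscape(training, stack, n_trees = config$n_trees,
                           seed = config$rf_seed, cv_folds = config$cv_folds)
  sr_mean <- predict_surface(sr_model, stack)
  sr_sd <- uncertainty_surface(sr_model, stack, config$q_low, config$q_high)
  o_iso <- load_oxygen_isoscape(o_raster, config$o_constant_sd)
  p1 <- file.path(out_dir, "sr_isoscape.asc")
  p2 <- file.path(out_dir, "sr_error.asc")
  write_esri_ascii(sr_mean, p1); note("isoscape", p1)
  write_esri_ascii(sr_sd, p2); note("isoscape", p2)

  # 3. deltas
  radius <- config$radius_km
  best_radius <- NULL
  if (!is.null(config$scan_radii) && length(config$scan_radii) >= 2) {
    scan <- scan_buffer_radius(samples, sr_mean, config$scan_radii)
    best_radius <- scan$best_radius
    radius <- best_radius
  }
  deltas <- compute_deltas(samples, sr_mean, o_iso$mean, radius_km = radius)
  p <- file.path(out_dir, "deltas.csv")
  write_sample_table(deltas, p); note("deltas", p)

  # 4. classification
  deltas <- classify_local(deltas, sigma = config$sigma_threshold)
  p <- file.path(out_dir, "classified.csv")
  write_sample_table(deltas, p); note("classify", p)

  # 5. calibration on locals
  locals <- dplyr::filter(deltas, .data$local_flag)
  excluded <- deltas$sample_id[!deltas$local_flag]
  sr_fit <- fit_calibration(locals, "buffered_sr", "sr87_86", system = "Sr",
                            excluded_ids = excluded)
  o_fit <- fit_calibration(locals, "buffered_o", "d18o_water", system = "O",
                           excluded_ids = excluded)
  sr_cal <- apply_calibration(sr_mean, sr_fit)
  sr_cal_sd <- calibrated_uncertainty(sr_sd, sr_fit)
  o_cal <- apply_calibration(o_iso$mean, o_fit)
  o_cal_sd <- calibrated_uncertainty(o_iso$sd, o_fit)
  p <- file.path(out_dir, "calibration_fits.json")
  jsonlite::write_json(
    list(sr = glance.calibration_fit(sr_fit), o = glance.calibration_fit(o_fit),
         sr_coef = tidy.calibration_fit(sr_fit),
         o_coef = tidy.calibration_fit(o_fit)),
    p, auto_unbox = TRUE, digits = NA)
  note("calibrate", p)
  p <- file.path(out_dir, "sr_isoscape_calibrated.asc")
  write_esri_ascii(sr_cal, p); note("calibrate", p)

  # 6. assignment of non-locals
  assignments <- assign_outliers(deltas, sr_cal, sr_cal_sd, o_cal, o_cal_sd,
                                 bin_width_km = config$bin_width_km,
                                 area_weight = config$area_weight)
  for (id in names(assignments)) {
    p <- file.path(out_dir, paste0("posterior_joint_", id, ".asc"))
    write_esri_ascii(assignments[[id]]$joint, p); note("assign", p)
  }
  if (length(assignments) == 0) {
    p <- file.path(out_dir, "assignments_empty.json")
    jsonlite::write_json(list(n_nonlocal = 0), p, auto_unbox = TRUE)
    note("assign", p)
  }

  # 7. distance densities
  dist_tab <- purrr::imap_dfr(assignments, function(a, id) {
    dplyr::mutate(tibble::as_tibble(a$distance), sample_id = id, .before = 1)
  })
  p <- file.path(out_dir, "distance_densities.csv")
  utils::write.csv(dist_tab, p, row.names = FALSE); note("distance", p)

  manifest <- dplyr::bind_rows(artifacts)
  meta <- list(
    package = "isorigin",
    version = as.character(utils::packageVersion("isorigin")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    radius_used_km = radius,
    n_samples = nrow(deltas), n_local = sum(deltas$local_flag),
    n_training = nrow(training),
    stages = unique(manifest$stage)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, samples = deltas, sr_model = sr_model,
                 fits = list(sr = sr_fit, o = o_fit),
                 surfaces = list(sr = sr_cal, sr_sd = sr_cal_sd,
                                 o = o_cal, o_sd = o_cal_sd),
                 assignments = assignments, best_radius = best_radius,
                 out_dir = out_dir, metadata = meta))
}
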