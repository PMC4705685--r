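#' Write a scan trajectory as tab-separated text
#'
#' Canonical trajectory format: a header line with columns `time_s`,
#' `piezo_nm`, `x_nm`, `y_nm`, `direction`, one sample per row. Additional
#' columns are preserved.
#'
#' @param traj A trajectory `data.frame` (or a `pulley_scan`, whose
#'   trajectory is written and whose truth sidecar goes to
#'   `paste0(path, ".truth.json")`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "pulley_scan")) {
    jsonlite::write_json(traj$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    traj <- traj$trajectory
  }
  stopifnot(is.data.frame(traj))
  write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan trajectory from tab-separated text
#'
#' Requires header columns `time_s`, `piezo_nm`, `x_nm`, `y_nm`
#' (`direction` and any extra columns are preserved as-is). Malformed
#' numeric entries and non-increasing times are reported with their line
#' numbers.
#'
#' @param path Input path.
#' @return A trajectory `data.frame`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("empty trajectory file: ", path, call. = FALSE)
  }
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("time_s", "piezo_nm", "x_nm", "y_nm")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("trajectory file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0L) stop("trajectory file has no samples: ", path,
                          call. = FALSE)
  for (col in required) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at data line %d of %s",
                   col, which(is.na(v))[1], path), call. = FALSE)
    }
    d[[col]] <- v
  }
  bad_t <- which(diff(d$time_s) <= 0)
  if (length(bad_t)) {
    stop(sprintf("time not strictly increasing at data line %d of %s",
                 bad_t[1] + 1L, path), call. = FALSE)
  }
  d
}

pipeline_defaults <- function() {
  list(
    constants = list(persistence_length_nm = 50, thermal_energy_pNnm = 4.114,
                     viscosity_pNs_nm2 = 1e-9, bead_radius_nm = 500,
                     rise_per_bp_nm = 0.34),
    calibration = list(max_lag = 100, tracking_noise_nm = 0.13,
                       tau_uncertainty_s = 0.005),
    geometry = list(extension_fraction = 0.85, thetaF_init_rad = pi / 4),
    detection = list(threshold_sigmas = 4, min_duration_s = 0.05,
                     cluster_gap_bp = 500, match_tolerance_bp = 300),
    elastica = list(enabled = FALSE, F_grid_pN = c(0.5, 1, 2),
                    theta_grid_deg = c(30, 45, 60), n_segments = 2000),
    ramp_fit = list(enabled = FALSE),
    seed = 1L
  )
}

check_known_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(cfg[[nm]])) {
        stop("configuration block '", path, nm, "' must be a list",
             call. = FALSE)
      }
      check_known_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected. Blocks: `constants` (persistence length, kBT, viscosity, bead
#' radius, rise per bp), `calibration` (ACF lags, tracking noise, tau
#' uncertainty), `geometry` (extension fraction, initial force angle),
#' `detection` (threshold, minimum duration, cluster gap, match tolerance),
#' `elastica` and `ramp_fit` (optional stages), and the `seed`.
#'
#' @param ... Named blocks overriding the defaults, e.g.
#'   `detection = list(threshold_sigmas = 5)`.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- pipeline_defaults()
  check_known_keys(user, defaults)
  cfg <- modifyList(defaults, user)
  stopifnot(cfg$constants$persistence_length_nm > 0,
            cfg$constants$thermal_energy_pNnm > 0,
            cfg$geometry$extension_fraction > 0,
            cfg$geometry$extension_fraction < 1,
            cfg$detection$threshold_sigmas > 0,
            cfg$detection$min_duration_s >= 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a scan
#'
#' Executes calibrate -> fit geometry -> detect bumps -> localize -> match
#' sites (optionally ramp fit and elastica map) on a scan trajectory, and
#' collects each stage's machine-readable report. Stage failures propagate
#' as errors naming the stage.
#'
#' @param scan A `pulley_scan` from [simulate_scan()], or a trajectory
#'   `data.frame` (e.g. from [read_trajectory()]).
#' @param config A [pipeline_config()].
#' @param sites Optional [site_map()] of expected recognition sites (bp on
#'   the tether) for the matching stage.
#' @param origin Blade-tip position (nm) for the geometry fit; defaults to
#'   the truth sidecar's origin when `scan` is a `pulley_scan`.
#' @param calibration Optional precomputed [calibrate_thermal()] result for
#'   the bead (a scan trajectory's fluctuations are non-stationary, so a
#'   dedicated tethered-bead recording is the normal calibration input).
#' @param geometry Optional precomputed [pulley_geometry()] (e.g. fitted to
#'   a protein-free scan of the same pulley, the usual experimental
#'   practice); if supplied, the geometry-fit stage is skipped.
#' @param out_dir Optional directory; if given, per-stage JSON reports and
#'   the bump table are written there.
#' @return A list of per-stage reports (`calibration`, `geometry`, `bumps`,
#'   `localization`, `matching`, optionally `ramp_fit`, `elastica`), each
#'   carrying the package version and the resolved configuration hash.
#' @export
run_pipeline <- function(scan, config = pipeline_config(), sites = NULL,
                         origin = NULL, calibration = NULL,
                         geometry = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  if (inherits(scan, "pulley_scan")) {
    truth <- scan$truth
    traj <- scan$trajectory
  } else {
    traj <- scan
  }
  if (is.null(origin) && !is.null(truth)) origin <- truth$geometry$origin
  cst <- config$constants
  meta <- list(package_version = as.character(packageVersion("dnapulley")),
               config_hash = config_hash(config))
  reports <- list(meta = meta)

  if (is.null(geometry)) {
    if (is.null(origin)) {
      stop("pipeline stage 'fit-geometry' failed: blade-tip origin required",
           call. = FALSE)
    }
    fit <- stage("fit-geometry", fit_geometry(
      traj, origin = origin,
      extension_fraction = config$geometry$extension_fraction,
      thetaF_init = config$geometry$thetaF_init_rad))
    reports$geometry <- c(geometry_report(fit), meta)
  } else {
    stopifnot(inherits(geometry, "pulley_geometry"))
    fit <- list(geometry = geometry)
  }

  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "thermal_calibration"))
    wlc <- wlc_params(
      contour_length = fit$geometry$l0 / fit$geometry$extension_fraction,
      persistence_length = cst$persistence_length_nm,
      thermal_energy = cst$thermal_energy_pNnm)
    bead <- bead_params(radius = cst$bead_radius_nm,
                        viscosity = cst$viscosity_pNs_nm2)
    tens <- stage("calibrate", calibrated_tension(
      calibration, bead, wlc,
      tau_uncertainty = config$calibration$tau_uncertainty_s))
    reports$calibration <- c(
      calibration_report(calibration),
      list(tension_pN = tens$tension, tension_unc_pN = tens$uncertainty,
           extension_fraction = tens$extension_fraction), meta)
  }

  # residual noise scale from the calibration when available (observed,
  # blur-included, since the scan residuals are equally blurred)
  sigma_res <- if (!is.null(calibration)) {
    contour_nm_to_bp(calibration$sigma_r_raw,
                     fit$geometry$extension_fraction,
                     cst$rise_per_bp_nm)
  } else NULL
  ev <- stage("detect-bumps", detect_pauses(
    traj, fit$geometry,
    threshold_sigmas = config$detection$threshold_sigmas,
    min_duration = config$detection$min_duration_s,
    sigma_residual = sigma_res))
  reports$bumps <- c(list(n_events = nrow(ev),
                          events = if (nrow(ev)) ev else NULL), meta)

  loc <- stage("localize", localize_bumps(
    ev, fit$geometry, cluster_gap = config$detection$cluster_gap_bp))
  reports$localization <- c(list(clusters = loc), meta)

  if (!is.null(sites)) {
    mm <- stage("map-sites", match_bumps_to_sites(
      loc$mean_bp, sites,
      tolerance = config$detection$match_tolerance_bp))
    reports$matching <- c(mm, meta)
  }

  if (isTRUE(config$elastica$enabled)) {
    reports$elastica <- c(list(map = stage("elastica-map", resolvability_map(
      config$elastica$F_grid_pN,
      config$elastica$theta_grid_deg * pi / 180,
      sigma_r = if (!is.null(calibration)) calibration$sigma_r else 32,
      Lp = cst$persistence_length_nm,
      thermal_energy = cst$thermal_energy_pNnm,
      n_segments = config$elastica$n_segments))), meta)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(reports), "meta")) {
      jsonlite::write_json(reports[[nm]],
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
    }
    if (nrow(ev)) write_bump_table(ev, file.path(out_dir, "bumps.tsv"))
  }
  reports
}
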