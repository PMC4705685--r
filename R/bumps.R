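#' Detect pauses (protein bumps) in a scan trajectory
#'
#' The detection statistic is the residual between the blade contour
#' position measured from bead tracking and the one predicted from the
#' stage motion, `L_meas - L_pred` (bp). A pause is a maximal interval in
#' which the absolute residual exceeds `threshold_sigmas` times the
#' residual noise scale, with hysteresis (the interval is entered at the
#' full threshold and extended while the residual stays above half of it)
#' and lasting at least `min_duration`. Legs with different scan direction
#' are processed separately.
#'
#' @param traj A scan trajectory `data.frame` with columns `time_s`,
#'   `piezo_nm`, `x_nm`, `y_nm` and optionally `direction` (leg label).
#' @param geom A fitted [pulley_geometry()] (an unfitted or partial
#'   geometry is a precondition error).
#' @param threshold_sigmas Entry threshold in units of the residual noise
#'   scale. Default 4.
#' @param min_duration Minimum pause duration (s). Default 0.05.
#' @param sigma_residual Residual noise scale (bp). Defaults to a
#'   low-quantile estimate from the trajectory itself (the 25th percentile
#'   of the absolute residual, rescaled for a Gaussian), which stays
#'   anchored to the free-sliding noise floor even when pause intervals
#'   cover most of a scan.
#' @return A `data.frame` of class `bump_events` with one row per event:
#'   `direction` (`"forward"` if the bead was moving toward the blade at
#'   onset, i.e. the blade-side contour was growing), `t_start`, `t_end`,
#'   `duration` (s), `piezo_start`, `piezo_end` (nm), `delta_L_bump` (nm,
#'   absolute change of the junction-blade distance over the stuck
#'   interval), `contour_position` (bp, median measured position during the
#'   pause) and `released` (whether the bead rejoined the model trajectory
#'   before the end of the leg).
#' @export
detect_pauses <- function(traj, geom, threshold_sigmas = 4,
                          min_duration = 0.05, sigma_residual = NULL) {
  if (!inherits(geom, "pulley_geometry")) {
    stop("geom must be a fitted pulley_geometry", call. = FALSE)
  }
  empty <- data.frame(direction = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      piezo_start = numeric(0), piezo_end = numeric(0),
                      delta_L_bump = numeric(0),
                      contour_position = numeric(0),
                      released = logical(0))
  class(empty) <- c("bump_events", "data.frame")
  if (nrow(traj) == 0L) return(empty)
  stopifnot(all(c("time_s", "piezo_nm", "x_nm", "y_nm") %in% names(traj)))

  legs <- if ("direction" %in% names(traj)) {
    split(traj, cumsum(c(TRUE, diff(as.integer(factor(traj$direction))) != 0)))
  } else list(traj)

  rw_all <- to_pulley_frame(cbind(traj$x_nm, traj$y_nm), geom)
  L_meas_all <- measured_contour(pmin(rw_all[, "r"], geom$l0), geom)
  L_pred_all <- map_piezo_to_contour(traj$piezo_nm, geom)
  if (is.null(sigma_residual)) {
    # quarter-quantile of |residual|: consistent for Gaussian noise, and
    # one-sided pause excursions cannot reach it below 75% contamination
    absres <- abs(L_meas_all - L_pred_all)
    sigma_residual <- stats::quantile(absres, 0.25, na.rm = TRUE,
                                      names = FALSE) / stats::qnorm(0.625)
  }
  stopifnot(sigma_residual > 0)

  out <- list()
  offset <- 0L
  for (leg in legs) {
    n <- nrow(leg)
    idx <- offset + seq_len(n)
    offset <- offset + n
    res <- L_meas_all[idx] - L_pred_all[idx]
    hi <- abs(res) > threshold_sigmas * sigma_residual
    lo <- abs(res) > threshold_sigmas / 2 * sigma_residual
    if (!any(hi, na.rm = TRUE)) next
    hi[is.na(hi)] <- FALSE
    lo[is.na(lo)] <- FALSE
    # hysteresis: expand each high-threshold run outward over the low run
    runs <- rle(lo)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      span <- starts[k]:ends[k]
      if (!any(hi[span])) next
      t0 <- leg$time_s[span[1L]]
      t1 <- leg$time_s[span[length(span)]]
      if (t1 - t0 < min_duration) next
      q0 <- capillary_arm_length(leg$piezo_nm[span[1L]], geom)
      q1 <- capillary_arm_length(leg$piezo_nm[span[length(span)]], geom)
      released <- ends[k] < n
      dirn <- if (q1 >= q0) "forward" else "reverse"
      out[[length(out) + 1L]] <- data.frame(
        direction = dirn, t_start = t0, t_end = t1, duration = t1 - t0,
        piezo_start = leg$piezo_nm[span[1L]],
        piezo_end = leg$piezo_nm[span[length(span)]],
        delta_L_bump = abs(q1 - q0),
        contour_position = median(L_meas_all[idx][span]),
        released = released)
    }
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  class(ev) <- c("bump_events", "data.frame")
  ev
}

#' Cluster detected bumps into sites and summarize their localization
#'
#' Single-linkage clustering of the bump contour positions: sorted
#' positions are split wherever the gap between neighbors exceeds
#' `cluster_gap`. Per cluster, the mean and standard deviation of the
#' positions are reported in bp and (through the extension fraction) in nm.
#'
#' @param events A `bump_events` `data.frame` from [detect_pauses()], or any
#'   `data.frame` with a `contour_position` column (bp).
#' @param geom A [pulley_geometry()] (for the bp-to-nm conversion).
#' @param cluster_gap Gap (bp) above which neighboring bumps belong to
#'   different clusters. Default 500.
#' @return A `data.frame` with one row per cluster: `mean_bp`, `sd_bp`,
#'   `sd_nm` and `n` (single-event clusters have `sd = 0`).
#' @export
localize_bumps <- function(events, geom, cluster_gap = 500) {
  stopifnot(is.data.frame(events), "contour_position" %in% names(events),
            inherits(geom, "pulley_geometry"), cluster_gap > 0)
  pos <- sort(events$contour_position)
  if (!length(pos)) {
    return(data.frame(mean_bp = numeric(0), sd_bp = numeric(0),
                      sd_nm = numeric(0), n = integer(0)))
  }
  cl <- cumsum(c(1, as.integer(diff(pos) > cluster_gap)))
  agg <- lapply(split(pos, cl), function(p) {
    s <- if (length(p) > 1L) sd(p) else 0
    data.frame(mean_bp = mean(p), sd_bp = s,
               sd_nm = contour_bp_to_nm(s, geom$extension_fraction),
               n = length(p))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Match detected bump positions to recognition sites
#'
#' Greedy nearest-pair assignment: among all bump-site pairs within
#' `tolerance`, the closest pair is matched first and both members removed,
#' so each bump matches at most one site and each site captures at most one
#' bump. Leftover bumps are reported as unmatched rather than force-matched.
#'
#' @param bump_positions Bump contour positions (bp).
#' @param sites A [site_map()] (or numeric vector of site positions, bp).
#' @param tolerance Maximum |bump - site| distance (bp) for a match.
#' @return A list with `assignments` (`data.frame`: `bump_bp`, `site_bp`,
#'   `distance_bp`), `unmatched_bumps`, `unmatched_sites` and
#'   `matched_fraction` (of bumps).
#' @export
match_bumps_to_sites <- function(bump_positions, sites, tolerance) {
  site_pos <- if (inherits(sites, "site_map")) sites$positions else sites
  stopifnot(is.numeric(bump_positions), is.numeric(site_pos), tolerance > 0)
  nb <- length(bump_positions)
  assignments <- data.frame(bump_bp = numeric(0), site_bp = numeric(0),
                            distance_bp = numeric(0))
  bump_left <- seq_along(bump_positions)
  site_left <- seq_along(site_pos)
  while (length(bump_left) && length(site_left)) {
    dm <- abs(outer(bump_positions[bump_left], site_pos[site_left], "-"))
    if (min(dm) > tolerance) break
    ij <- arrayInd(which.min(dm), dim(dm))
    assignments <- rbind(assignments, data.frame(
      bump_bp = bump_positions[bump_left[ij[1]]],
      site_bp = site_pos[site_left[ij[2]]],
      distance_bp = dm[ij]))
    bump_left <- bump_left[-ij[1]]
    site_left <- site_left[-ij[2]]
  }
  list(assignments = assignments,
       unmatched_bumps = bump_positions[bump_left],
       unmatched_sites = site_pos[site_left],
       matched_fraction = if (nb) nrow(assignments) / nb else NA_real_)
}

#' Fraction of scans showing a bump at a given site
#'
#' Runs [detect_pauses()] on each scan and scores whether any detected bump
#' falls within `tolerance` of the site. Reports the detection fraction
#' with an exact binomial confidence interval.
#'
#' @param scans A list of scan trajectories (`data.frame`s).
#' @param site Contour position of the site (bp).
#' @param geom A [pulley_geometry()].
#' @param tolerance Match tolerance (bp). Default 300.
#' @param ... Passed to [detect_pauses()].
#' @return A list with `rate`, `n_detected`, `n_scans` and `conf_int`
#'   (95% Clopper-Pearson).
#' @export
detection_rate <- function(scans, site, geom, tolerance = 300, ...) {
  stopifnot(is.list(scans), length(scans) >= 1)
  hits <- vapply(scans, function(tr) {
    ev <- detect_pauses(tr, geom, ...)
    any(abs(ev$contour_position - site) <= tolerance)
  }, logical(1))
  bt <- binom.test(sum(hits), length(hits))
  list(rate = mean(hits), n_detected = sum(hits), n_scans = length(hits),
       conf_int = as.numeric(bt$conf.int))
}

#' Write bump events as tab-separated text
#'
#' @param events A `bump_events` `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bump_table <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
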