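#' Simulate an Ornstein-Uhlenbeck process
#'
#' Exact-discretization OU update
#' `x[k+1] = x[k] * exp(-dt/tau) + sigma * sqrt(1 - exp(-2 dt/tau)) * xi[k]`
#' with a stationary start (`x[1] ~ N(0, sigma^2)` unless `x0` is given).
#'
#' @param n Number of samples.
#' @param dt Time step (s), `> 0`.
#' @param sigma Stationary standard deviation (nm).
#' @param tau Relaxation time (s). `Inf` freezes the series at its start.
#' @param seed Optional integer seed.
#' @param x0 Optional deterministic start value.
#' @return Numeric vector of `n` samples (nm).
#' @export
simulate_ou <- function(n, dt, sigma, tau, seed = NULL, x0 = NULL) {
  stopifnot(n >= 1, dt > 0, sigma >= 0, tau > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-dt / tau)
  b <- sigma * sqrt(1 - a^2)
  start <- if (is.null(x0)) rnorm(1, 0, sigma) else x0
  if (n == 1L) return(start)
  innov <- c(start, b * rnorm(n - 1L))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# OU simulated on a fine grid and boxcar-averaged over each frame's exposure
# window; returns one value per frame. oversample fine steps span the
# exposure; if exposure < frame interval the remaining dead time is skipped
# by an exact OU decay step.
ou_blurred_frames <- function(n_frames, frame_dt, exposure, sigma, tau,
                              oversample = 8L) {
  stopifnot(exposure <= frame_dt + 1e-12)
  if (sigma == 0) return(numeric(n_frames))
  if (exposure == 0) {
    return(simulate_ou(n_frames, frame_dt, sigma, tau))
  }
  m <- as.integer(oversample)
  dt_f <- exposure / m
  dead <- frame_dt - exposure
  if (dead <= 1e-12) {
    fine <- simulate_ou(n_frames * m, dt_f, sigma, tau)
    return(colMeans(matrix(fine, nrow = m)))
  }
  a_f <- exp(-dt_f / tau); b_f <- sigma * sqrt(1 - a_f^2)
  a_d <- exp(-dead / tau); b_d <- sigma * sqrt(1 - a_d^2)
  out <- numeric(n_frames)
  x <- rnorm(1, 0, sigma)
  for (fr in seq_len(n_frames)) {
    acc <- 0
    for (j in seq_len(m)) {
      x <- x * a_f + b_f * rnorm(1)
      acc <- acc + x
    }
    out[fr] <- acc / m
    x <- x * a_d + b_d * rnorm(1)
  }
  out
}

#' Simulate a tethered-bead trajectory (no blade contact)
#'
#' Independent OU fluctuations along the radial and transverse pulley axes,
#' rotated to the camera frame, boxcar-averaged over the camera exposure,
#' with additive localization noise and a linear drift. Defaults reproduce
#' the measured statistics of a 1 um bead on a lambda-DNA tether at ~1 pN:
#' sigma_r = 32 nm, tau_r = 10 ms, sigma_w = 89 nm, tau_w = 68 ms, 200 Hz
#' acquisition with full-frame exposure, 0.13 nm tracking noise and
#' ~1 nm/min drift.
#'
#' @param duration Total duration (s); must be at least `10 * tau_w`.
#' @param frame_rate Acquisition rate (Hz). Default 200.
#' @param sigma_r,tau_r Radial fluctuation amplitude (nm) and relaxation
#'   time (s).
#' @param sigma_w,tau_w Transverse fluctuation amplitude (nm) and
#'   relaxation time (s).
#' @param exposure Camera exposure (s). Default: full frame interval.
#' @param tracking_noise Per-axis localization noise (nm). Default 0.13.
#' @param drift_nm_per_min Linear drift magnitude (nm/min). Default 1.
#' @param thetaF Force angle below the x-axis (rad). Default `pi/4`.
#' @param center Mean bead position in the camera frame (nm).
#' @param seed Optional integer seed.
#' @param oversample Fine OU steps per exposure window. Default 8.
#' @return A `data.frame` with columns `time_s`, `x_nm`, `y_nm`; the truth
#'   parameters are attached as attribute `"truth"`.
#' @export
simulate_tethered_bead <- function(duration, frame_rate = 200,
                                   sigma_r = 32, tau_r = 0.010,
                                   sigma_w = 89, tau_w = 0.068,
                                   exposure = NULL, tracking_noise = 0.13,
                                   drift_nm_per_min = 1, thetaF = pi / 4,
                                   center = c(0, 0), seed = NULL,
                                   oversample = 8L) {
  stopifnot(duration >= 10 * tau_w, frame_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  frame_dt <- 1 / frame_rate
  if (is.null(exposure)) exposure <- frame_dt
  n <- floor(duration * frame_rate)
  t_s <- (seq_len(n) - 1L) * frame_dt

  r <- ou_blurred_frames(n, frame_dt, exposure, sigma_r, tau_r, oversample)
  w <- ou_blurred_frames(n, frame_dt, exposure, sigma_w, tau_w, oversample)
  drift_angle <- runif(1, 0, 2 * pi)
  drift <- (drift_nm_per_min / 60) * t_s
  rhat <- c(cos(thetaF), -sin(thetaF))
  what <- c(sin(thetaF), cos(thetaF))
  x <- center[1] + r * rhat[1] + w * what[1] +
    drift * cos(drift_angle) + rnorm(n, 0, tracking_noise)
  y <- center[2] + r * rhat[2] + w * what[2] +
    drift * sin(drift_angle) + rnorm(n, 0, tracking_noise)
  out <- data.frame(time_s = t_s, x_nm = x, y_nm = y)
  attr(out, "truth") <- list(
    sigma_r = sigma_r, tau_r = tau_r, sigma_w = sigma_w, tau_w = tau_w,
    exposure = exposure, frame_rate = frame_rate,
    tracking_noise = tracking_noise, drift_nm_per_min = drift_nm_per_min,
    thetaF = thetaF, center = center)
  out
}

#' Configuration for a synthetic pulley scan
#'
#' Ground truth and acquisition settings for [simulate_scan()]. Defaults
#' mirror the experimental conditions: 200 Hz frames with full-frame
#' exposure, 1 um/s piezo scans spanning 12 um, radial/transverse OU
#' fluctuations of (32 nm, 10 ms) and (89 nm, 68 ms), 0.13 nm tracking
#' noise and ~1 nm/min drift, on a lambda-length tether stretched to 85%.
#'
#' @param geometry A [pulley_geometry()] truth.
#' @param tether_bp Tether length in base pairs. Default 48502 (lambda).
#' @param sigma_r,tau_r,sigma_w,tau_w Bead fluctuation parameters.
#' @param tracking_noise Localization noise (nm).
#' @param drift_nm_per_min Mean drift magnitude (nm/min); each leg draws a
#'   random slope around it.
#' @param frame_rate Acquisition rate (Hz).
#' @param exposure Exposure (s); default full frame interval.
#' @param scan_speed Piezo speed (nm/s).
#' @param scan_span Piezo span (nm).
#' @param scan_start Piezo offset of the leg start relative to `P0` (nm).
#'   The forward leg runs from `P0 + scan_start` to
#'   `P0 + scan_start + scan_span` (piezo increasing), the reverse leg back
#'   down. The default `-scan_span/2` centers the scan on the apex; `0`
#'   gives a one-sided scan on which the blade-side contour grows
#'   monotonically during the forward leg.
#' @param bump_sites Contour positions (bp, from the capillary junction) of
#'   planted protein bumps.
#' @param site_occupancy Per-site, per-crossing probability that the
#'   protein is bound. Default 1.
#' @param bond A [bond_model()] for bump rupture under load.
#' @param ambient_force Magnet tension (pN) when sliding freely.
#' @param wlc A [wlc_params()] for the full tether (persistence length and
#'   kBT are reused for stuck segments).
#' @param legs Character vector of scan legs, `"forward"` (piezo
#'   increasing) and/or `"reverse"`.
#' @param slack_force Tension (pN) below which a reverse-scan pause is
#'   released as slack. Default 0.005.
#' @param oversample Fine OU steps per exposure window.
#' @param seed Integer seed recorded in the output.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(geometry,
                        tether_bp = 48502,
                        sigma_r = 32, tau_r = 0.010,
                        sigma_w = 89, tau_w = 0.068,
                        tracking_noise = 0.13, drift_nm_per_min = 1,
                        frame_rate = 200, exposure = NULL,
                        scan_speed = 1000, scan_span = 12000,
                        scan_start = -scan_span / 2,
                        bump_sites = numeric(0), site_occupancy = 1,
                        bond = bond_model(k0 = 0.05, x_dagger = 2),
                        ambient_force = 1,
                        wlc = NULL,
                        legs = c("forward", "reverse"),
                        slack_force = 0.005,
                        oversample = 8L,
                        seed = 1L) {
  stopifnot(inherits(geometry, "pulley_geometry"),
            site_occupancy >= 0, site_occupancy <= 1,
            inherits(bond, "bond_model"),
            all(legs %in% c("forward", "reverse")),
            frame_rate > 0, scan_speed > 0, scan_span > 0)
  if (is.null(exposure)) exposure <- 1 / frame_rate
  if (is.null(wlc)) {
    wlc <- wlc_params(contour_length = tether_bp * 0.34)
  }
  ext <- geometry$extension_fraction
  offs <- c(scan_start, scan_start + scan_span)
  q_ends <- sqrt(offs^2 + geometry$d^2)
  q_max <- max(q_ends)
  q_min <- if (prod(sign(offs)) <= 0) geometry$d else min(q_ends)
  problems <- character(0)
  if (length(bump_sites)) {
    site_nm <- contour_bp_to_nm(bump_sites, ext)
    if (any(site_nm <= q_min | site_nm >= q_max)) {
      problems <- c(problems,
                    "bump_sites: site outside the scanned contour interval")
    }
    if (any(bump_sites > tether_bp)) {
      problems <- c(problems, "bump_sites: site beyond the tether length")
    }
  }
  if (geometry$l0 <= q_max) {
    problems <- c(problems,
                  "scan_span: tether unhooks before the end of the scan")
  }
  if (length(problems)) {
    stop("invalid scan configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(
    list(geometry = geometry, tether_bp = tether_bp,
         sigma_r = sigma_r, tau_r = tau_r, sigma_w = sigma_w, tau_w = tau_w,
         tracking_noise = tracking_noise,
         drift_nm_per_min = drift_nm_per_min,
         frame_rate = frame_rate, exposure = exposure,
         scan_speed = scan_speed, scan_span = scan_span,
         scan_start = scan_start,
         bump_sites = bump_sites, site_occupancy = site_occupancy,
         bond = bond, ambient_force = ambient_force, wlc = wlc,
         legs = legs, slack_force = slack_force,
         oversample = as.integer(oversample), seed = as.integer(seed)),
    class = "scan_config"
  )
}

# Deterministic + stochastic simulation of one scan leg. P moves linearly;
# the blade-side contour freezes while stuck at an occupied site.
simulate_leg <- function(config, leg, t_offset) {
  g <- config$geometry
  ext <- g$extension_fraction
  dt <- 1 / config$frame_rate
  n <- floor(config$scan_span / config$scan_speed / dt)
  dirsign <- if (leg == "forward") 1 else -1
  P_start <- if (leg == "forward") {
    g$P0 + config$scan_start
  } else {
    g$P0 + config$scan_start + config$scan_span
  }
  P <- P_start + dirsign * config$scan_speed * dt * (seq_len(n) - 1L)
  q_free <- sqrt((P - g$P0)^2 + g$d^2)

  site_q <- contour_bp_to_nm(config$bump_sites, ext)
  events <- list()
  r_model <- g$l0 - q_free
  stuck_site <- NA_integer_
  stuck_q <- NA_real_
  onset_i <- NA_integer_
  onset_loading <- NA_character_
  occupied <- if (length(site_q)) {
    runif(length(site_q)) < config$site_occupancy
  } else logical(0)

  for (i in seq_len(n)) {
    if (is.na(stuck_site)) {
      if (i > 1L && length(site_q)) {
        crossed <- which(occupied &
                           (q_free[i - 1L] - site_q) *
                           (q_free[i] - site_q) <= 0 &
                           q_free[i] != q_free[i - 1L])
        if (length(crossed)) {
          stuck_site <- crossed[1L]
          stuck_q <- site_q[stuck_site]
          onset_i <- i
          onset_loading <- if (q_free[i] > q_free[i - 1L]) {
            "increasing"
          } else "decreasing"
          # occupancy consumed for this crossing
          occupied[stuck_site] <- FALSE
        }
      }
    }
    if (!is.na(stuck_site)) {
      # frozen blade-side contour: bead radial coordinate is pinned
      r_model[i] <- g$l0 - stuck_q
      seg_contour <- contour_bp_to_nm(config$bump_sites[stuck_site], 1) # bp*0.34
      z <- q_free[i] / seg_contour
      release <- NULL
      if (z >= 0.995) {
        release <- "overstretch"
      } else {
        Fseg <- segment_tension(P[i], g, seg_contour, config$wlc)
        if (Fseg <= config$slack_force) {
          release <- "slack"
        } else {
          k <- bell_rate(Fseg, config$bond)
          if (runif(1) < 1 - exp(-k * dt)) release <- "rupture"
        }
      }
      if (!is.null(release)) {
        events[[length(events) + 1L]] <- list(
          site_bp = config$bump_sites[stuck_site],
          leg = leg, loading = onset_loading,
          t_start = t_offset + (onset_i - 1L) * dt,
          t_end = t_offset + (i - 1L) * dt,
          P_start = P[onset_i], P_end = P[i],
          delta_L_bump = abs(q_free[i] - q_free[onset_i]),
          release = release)
        stuck_site <- NA_integer_
        stuck_q <- NA_real_
        onset_i <- NA_integer_
      }
    }
  }
  if (!is.na(stuck_site)) {
    events[[length(events) + 1L]] <- list(
      site_bp = config$bump_sites[stuck_site], leg = leg,
      loading = onset_loading,
      t_start = t_offset + (onset_i - 1L) * dt,
      t_end = t_offset + (n - 1L) * dt,
      P_start = P[onset_i], P_end = P[n],
      delta_L_bump = abs(q_free[n] - q_free[onset_i]),
      release = "scan_end")
  }

  # noise: quasi-static OU about the model position, blur, drift, tracking
  r_fluct <- ou_blurred_frames(n, dt, config$exposure, config$sigma_r,
                               config$tau_r, config$oversample)
  w_fluct <- ou_blurred_frames(n, dt, config$exposure, config$sigma_w,
                               config$tau_w, config$oversample)
  slope <- rnorm(1, config$drift_nm_per_min, config$drift_nm_per_min / 4)
  drift_angle <- runif(1, 0, 2 * pi)
  t_leg <- dt * (seq_len(n) - 1L)
  drift <- (slope / 60) * t_leg
  rhat <- c(cos(g$thetaF), -sin(g$thetaF))
  what <- c(sin(g$thetaF), cos(g$thetaF))
  x <- g$origin[1] + (r_model + r_fluct) * rhat[1] + w_fluct * what[1] +
    drift * cos(drift_angle) + rnorm(n, 0, config$tracking_noise)
  y <- g$origin[2] + (r_model + r_fluct) * rhat[2] + w_fluct * what[2] +
    drift * sin(drift_angle) + rnorm(n, 0, config$tracking_noise)
  list(
    frames = data.frame(time_s = t_offset + t_leg, piezo_nm = P,
                        x_nm = x, y_nm = y,
                        direction = rep(leg, n)),
    events = events
  )
}

#' Simulate a full pulley scan with planted protein bumps
#'
#' The piezo ramps across `scan_span` at `scan_speed` (forward leg: piezo
#' increasing; reverse: decreasing), and the bead follows the pulley
#' geometry `r = l0 - sqrt((P - P0)^2 + d^2)` plus quasi-static OU
#' fluctuations, exposure blur, drift and tracking noise. When the
#' predicted blade contact crosses an occupied bump site, the blade-side
#' contour freezes: the bead's radial coordinate pins while the tension in
#' the capillary-blade segment evolves with the piezo
#' ([segment_tension()]); the pause ends by Bell-Evans rupture (hazard
#' integrated frame by frame), by slack (reverse legs, tension reaching
#' zero) or by overstretch, after which the bead snaps back to the free
#' trajectory. Each generator writes a truth sidecar sufficient to score
#' every downstream analysis stage.
#'
#' @param config A [scan_config()].
#' @return A list of class `pulley_scan` with `trajectory` (a `data.frame`
#'   with columns `time_s`, `piezo_nm`, `x_nm`, `y_nm`, `direction`) and
#'   `truth` (geometry, config parameters and the list of planted pause
#'   events with onset/release times, piezo interval and `delta_L_bump`).
#' @export
simulate_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  set.seed(config$seed)
  legs <- list()
  events <- list()
  t_offset <- 0
  for (leg in config$legs) {
    sim <- simulate_leg(config, leg, t_offset)
    legs[[length(legs) + 1L]] <- sim$frames
    events <- c(events, sim$events)
    t_offset <- sim$frames$time_s[nrow(sim$frames)] + 1 / config$frame_rate
  }
  traj <- do.call(rbind, legs)
  rownames(traj) <- NULL
  g <- config$geometry
  truth <- list(
    seed = config$seed,
    geometry = list(l0 = g$l0, d = g$d, P0 = g$P0, thetaF = g$thetaF,
                    origin = g$origin,
                    extension_fraction = g$extension_fraction),
    fluctuations = list(sigma_r = config$sigma_r, tau_r = config$tau_r,
                        sigma_w = config$sigma_w, tau_w = config$tau_w),
    acquisition = list(frame_rate = config$frame_rate,
                       exposure = config$exposure,
                       tracking_noise = config$tracking_noise,
                       drift_nm_per_min = config$drift_nm_per_min),
    scan = list(speed = config$scan_speed, span = config$scan_span,
                start = config$scan_start, legs = config$legs),
    bump_sites_bp = config$bump_sites,
    site_occupancy = config$site_occupancy,
    bond = list(k0 = config$bond$k0, x_dagger = config$bond$x_dagger),
    ambient_force = config$ambient_force,
    events = events)
  structure(list(trajectory = traj, truth = truth), class = "pulley_scan")
}

#' Generate a synthetic genome with motif copies planted at known positions
#'
#' Uniform random background sequence with copies of `motif` planted at the
#' given 1-based positions. Background occurrences of the motif (or of its
#' reverse complement, under IUPAC-aware matching) outside the planted
#' windows are re-randomized away, so [find_sites()] ground truth is exactly
#' the planted position list.
#'
#' @param length Genome length (bp).
#' @param motif Motif to plant (IUPAC string; planted copies instantiate
#'   ambiguity codes randomly).
#' @param positions 1-based start positions of the planted copies;
#'   non-overlapping, each fitting within the sequence.
#' @param seed Optional integer seed.
#' @return A single DNA sequence as a character string, with the planted
#'   positions as attribute `"planted"`.
#' @export
synth_genome <- function(length, motif, positions = integer(0),
                         seed = NULL) {
  stopifnot(length >= nchar(motif), nchar(motif) >= 1)
  if (!is.null(seed)) set.seed(seed)
  positions <- sort(as.integer(positions))
  m <- nchar(motif)
  if (any(positions < 1L | positions + m - 1L > length)) {
    stop("planted position does not fit within the sequence", call. = FALSE)
  }
  if (any(diff(positions) < m)) {
    stop("planted positions overlap", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, length, replace = TRUE)
  # instantiate the motif (resolve IUPAC codes randomly) at each plant
  iupac <- Biostrings::IUPAC_CODE_MAP
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  for (p in positions) {
    inst <- vapply(motif_chars, function(ch) {
      opts <- strsplit(iupac[[ch]], "")[[1]]
      opts[sample.int(length(opts), 1L)]
    }, character(1))
    seqv[p:(p + m - 1L)] <- inst
  }
  planted_cols <- unlist(lapply(positions, function(p) p:(p + m - 1L)))
  for (iter in seq_len(200L)) {
    s <- paste(seqv, collapse = "")
    hits <- find_sites(s, motif)$positions
    spurious <- setdiff(hits, positions)
    if (!length(spurious)) break
    for (p in spurious) {
      win <- setdiff(p:(p + m - 1L), planted_cols)
      if (!length(win)) next   # overlaps a plant entirely; leave for retry
      j <- win[sample.int(length(win), 1L)]
      seqv[j] <- sample(setdiff(bases, seqv[j]), 1L)
    }
  }
  s <- paste(seqv, collapse = "")
  if (length(setdiff(find_sites(s, motif)$positions, positions))) {
    stop("could not purge spurious motif occurrences", call. = FALSE)
  }
  attr(s, "planted") <- positions
  s
}
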