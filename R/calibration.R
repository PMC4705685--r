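#' Autocovariance / autocorrelation of a bead position series
#'
#' Biased (1/N) estimator of the autocovariance function, as returned by
#' [stats::acf()]; the series mean is removed first. `ACF(0)` equals the
#' (biased) sample variance. The normalized variant divides by `ACF(0)`.
#'
#' @param series Numeric vector of position samples (nm).
#' @param max_lag Maximum lag (in samples); the series must be longer than
#'   `2 * max_lag`.
#' @param normalize If `TRUE`, return the autocorrelation (unit at lag 0)
#'   instead of the autocovariance.
#' @return A `data.frame` with columns `lag` (samples) and `value` (nm^2, or
#'   dimensionless if normalized).
#' @export
autocorrelation <- function(series, max_lag, normalize = FALSE) {
  stopifnot(is.numeric(series), length(series) > 2 * max_lag, max_lag >= 1)
  if (var(series) == 0) {
    stop(structure(
      class = c("dnapulley_zero_variance", "error", "condition"),
      list(message = "constant series: zero variance", call = sys.call(-1))))
  }
  a <- stats::acf(series, lag.max = max_lag,
                  type = if (normalize) "correlation" else "covariance",
                  demean = TRUE, plot = FALSE)
  data.frame(lag = drop(a$lag), value = drop(a$acf))
}

#' Fit an exponential decay to an autocovariance function
#'
#' Weighted least-squares fit of `A * exp(-t / tau)` to autocovariance
#' values. Lag 0 is excluded by default: uncorrelated tracking noise and the
#' camera-blur attenuation both affect lag 0 differently from the positive
#' lags, while for lags of one frame or more the decay time of a
#' blur-averaged Ornstein-Uhlenbeck process is unchanged. An initial decay
#' time is estimated by log-linear regression; the fit is then restricted to
#' lags below `3 * tau` (at least 5 lags) and iterated once after the tau
#' estimate updates.
#'
#' @param acf_values A `data.frame` as returned by [autocorrelation()]
#'   (columns `lag`, `value`, unnormalized).
#' @param dt Sampling interval (s) between successive lags.
#' @param exclude_lag0 Drop the lag-0 value from the fit (default `TRUE`).
#' @return A list with `sigma2` (fitted amplitude at lag 0, nm^2), `tau`
#'   (decay time, s), `lags_used`, and `converged`.
#' @export
fit_exponential_acf <- function(acf_values, dt, exclude_lag0 = TRUE) {
  stopifnot(is.data.frame(acf_values),
            all(c("lag", "value") %in% names(acf_values)), dt > 0)
  d <- acf_values
  if (exclude_lag0) d <- d[d$lag > 0, , drop = FALSE]
  pos <- d$value > 0
  if (sum(pos) < 5L) {
    stop("fewer than 5 positive autocovariance lags: cannot fit a decay",
         call. = FALSE)
  }
  t_all <- d$lag * dt
  # initial estimate from log-linear regression on the leading positive run
  lead <- seq_len(match(FALSE, pos, nomatch = length(pos) + 1L) - 1L)
  if (length(lead) < 3L) lead <- which(pos)[seq_len(min(5L, sum(pos)))]
  ll <- lm(log(d$value[lead]) ~ t_all[lead])
  slope <- coef(ll)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    stop("autocovariance does not decay: fit failure", call. = FALSE)
  }
  tau <- -1 / slope
  A <- exp(coef(ll)[[1]])

  one_pass <- function(tau, A) {
    keep <- t_all <= 3 * tau
    if (sum(keep) < 5L) keep <- seq_len(min(5L, nrow(d)))
    tt <- t_all[keep]; vv <- d$value[keep]
    fit <- minpack.lm::nls.lm(
      par = c(log(A), log(tau)),
      fn = function(p) vv - exp(p[1]) * exp(-tt / exp(p[2])),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(A = exp(fit$par[1]), tau = exp(fit$par[2]),
         lags = d$lag[keep], ok = !(fit$info %in% c(0L, 5L)))
  }
  f1 <- one_pass(tau, A)
  f2 <- one_pass(f1$tau, f1$A)   # iterate once after tau updates
  list(sigma2 = f2$A, tau = f2$tau, lags_used = f2$lags,
       converged = f1$ok && f2$ok)
}

# Variance attenuation of an OU process boxcar-averaged over an exposure
# window: sigma_obs^2 = sigma_true^2 * atten(alpha), alpha = exposure / tau.
ou_blur_attenuation <- function(alpha) {
  ifelse(alpha < 1e-6,
         1 - alpha / 3,
         (2 / alpha) * (1 - (1 / alpha) * (1 - exp(-alpha))))
}

#' Correct an observed fluctuation variance for camera exposure blur
#'
#' A camera averages the bead position over its exposure window, attenuating
#' the observed variance of an Ornstein-Uhlenbeck process by
#' `(2/alpha) * (1 - (1/alpha) * (1 - exp(-alpha)))` with
#' `alpha = exposure / tau`. This function inverts that attenuation to
#' recover the true thermal variance.
#'
#' @param sigma_obs2 Observed (blurred) variance (nm^2).
#' @param tau Relaxation time of the process (s).
#' @param exposure Camera exposure time (s), `>= 0`. Zero is the identity.
#' @return The blur-corrected variance `sigma_true^2` (nm^2).
#' @export
blur_correct <- function(sigma_obs2, tau, exposure) {
  stopifnot(sigma_obs2 >= 0, tau > 0, exposure >= 0)
  if (exposure == 0) return(sigma_obs2)
  att <- ou_blur_attenuation(exposure / tau)
  if (att <= 0) stop("non-positive blur attenuation factor", call. = FALSE)
  sigma_obs2 / att
}

#' Center-of-mass localization precision after time averaging
#'
#' Averaging the position of a fluctuating bead for a time `t` reduces the
#' r.m.s. uncertainty of its center of mass to
#' `sigma_meas = sigma_therm * sqrt(tau / t)` (valid for `t >= tau`).
#'
#' @param sigma_therm Standard deviation of the thermal fluctuations (nm).
#' @param tau Relaxation time of the fluctuations (s).
#' @param t Averaging time (s).
#' @return `sigma_meas` in nm.
#' @export
averaging_precision <- function(sigma_therm, tau, t) {
  stopifnot(sigma_therm >= 0, tau > 0, t > 0)
  if (any(t < tau)) {
    warning("averaging time below the relaxation time: the sqrt(tau/t) ",
            "formula assumes t >= tau", call. = FALSE)
  }
  sigma_therm * sqrt(tau / t)
}

#' Per-bead tracking precision from a two-bead differential measurement
#'
#' Tracking two immobilized beads and measuring the fluctuations of the
#' vector joining them rejects common-mode stage noise; assuming independent
#' identically distributed localization noise on each bead, the per-bead
#' precision is the pair r.m.s. divided by `sqrt(2)`.
#'
#' @param pair_rms r.m.s. fluctuation of the inter-bead vector (nm).
#' @return Per-bead tracking precision (nm).
#' @examples
#' differential_precision(0.19)  # ~0.13 nm
#' @export
differential_precision <- function(pair_rms) {
  stopifnot(is.numeric(pair_rms), all(pair_rms >= 0))
  pair_rms / sqrt(2)
}

#' Thermal calibration of a tethered-bead trajectory
#'
#' Estimates the fluctuation amplitudes and relaxation times of a tethered
#' bead along its two principal axes. Each coordinate is linearly detrended
#' (removing slow drift), the fluctuation ellipse's principal axes are found
#' by eigendecomposition of the position covariance, and the
#' autocovariance along each axis is fit to an exponential decay
#' ([fit_exponential_acf()]). Observed variances are corrected for camera
#' exposure blur ([blur_correct()]) after subtracting the tracking-noise
#' variance. The stiffer axis (radial, along the DNA) is identified as the
#' one with the smaller relaxation time.
#'
#' @param traj A `data.frame` with columns `time_s`, `x_nm`, `y_nm`.
#' @param exposure Camera exposure time (s). Defaults to the full frame
#'   interval (the median time step).
#' @param tracking_noise Per-axis localization noise (nm), subtracted in
#'   quadrature from the observed variance. Default 0.
#' @param max_lag Maximum autocovariance lag (samples). Default 100.
#' @return An object of class `thermal_calibration` with blur-corrected
#'   `sigma_r`, `sigma_w` (nm), `tau_r`, `tau_w` (s), the raw observed
#'   values, the principal-axis directions, `exposure_time`, `frame_rate`,
#'   `n_samples` and `tracking_precision`.
#' @export
calibrate_thermal <- function(traj, exposure = NULL, tracking_noise = 0,
                              max_lag = 100L) {
  stopifnot(is.data.frame(traj),
            all(c("time_s", "x_nm", "y_nm") %in% names(traj)))
  n <- nrow(traj)
  dt <- median(diff(traj$time_s))
  stopifnot(is.finite(dt), dt > 0)
  if (is.null(exposure)) exposure <- dt

  x <- stats::residuals(lm(traj$x_nm ~ traj$time_s))
  y <- stats::residuals(lm(traj$y_nm ~ traj$time_s))
  cv <- stats::cov(cbind(x, y))
  eg <- eigen(cv, symmetric = TRUE)
  axes <- eg$vectors     # columns: major then minor principal axis

  calibrate_axis <- function(series) {
    ac <- autocorrelation(series, max_lag = max_lag)
    fit <- fit_exponential_acf(ac, dt = dt)
    s_obs2 <- max(ac$value[ac$lag == 0] - tracking_noise^2, 0)
    list(tau = fit$tau,
         sigma_obs2 = s_obs2,
         sigma2 = blur_correct(s_obs2, fit$tau, exposure))
  }
  major <- calibrate_axis(drop(cbind(x, y) %*% axes[, 1]))
  minor <- calibrate_axis(drop(cbind(x, y) %*% axes[, 2]))

  # radial axis = stiffer = faster relaxation
  if (minor$tau <= major$tau) {
    rr <- minor; ww <- major
    r_axis <- axes[, 2]; w_axis <- axes[, 1]
  } else {
    rr <- major; ww <- minor
    r_axis <- axes[, 1]; w_axis <- axes[, 2]
  }
  if (rr$sigma2 > ww$sigma2) {
    warning("radial (fast) axis has larger variance than the transverse ",
            "axis; check the trajectory", call. = FALSE)
  }
  if (n < 100 * rr$tau / dt) {
    warning("fewer than 100 correlation times of data; relaxation-time ",
            "estimates may be unreliable", call. = FALSE)
  }
  structure(
    list(sigma_r = sqrt(rr$sigma2), sigma_w = sqrt(ww$sigma2),
         tau_r = rr$tau, tau_w = ww$tau,
         sigma_r_raw = sqrt(rr$sigma_obs2), sigma_w_raw = sqrt(ww$sigma_obs2),
         r_axis = r_axis, w_axis = w_axis,
         exposure_time = exposure, frame_rate = 1 / dt,
         n_samples = n, tracking_precision = tracking_noise),
    class = "thermal_calibration"
  )
}

#' @export
print.thermal_calibration <- function(x, ...) {
  cat("Thermal calibration (blur-corrected; raw in parentheses)\n")
  cat(sprintf("  sigma_r = %.1f nm (%.1f)   tau_r = %.2f ms\n",
              x$sigma_r, x$sigma_r_raw, 1e3 * x$tau_r))
  cat(sprintf("  sigma_w = %.1f nm (%.1f)   tau_w = %.2f ms\n",
              x$sigma_w, x$sigma_w_raw, 1e3 * x$tau_w))
  cat(sprintf("  %d samples at %.0f Hz, exposure %.2f ms\n",
              x$n_samples, x$frame_rate, 1e3 * x$exposure_time))
  invisible(x)
}

#' Infer the DNA tension from a thermal calibration
#'
#' Feeds the radial relaxation time of a [calibrate_thermal()] result to
#' [tension_from_relaxation()].
#'
#' @param calib A `thermal_calibration`.
#' @param bead A [bead_params()] object.
#' @param params A [wlc_params()] object for the tether.
#' @param tau_uncertainty Optional uncertainty on `tau_r` (s).
#' @return A [force_estimate()].
#' @export
calibrated_tension <- function(calib, bead, params, tau_uncertainty = NULL) {
  stopifnot(inherits(calib, "thermal_calibration"))
  tension_from_relaxation(calib$tau_r, bead, params,
                          tau_uncertainty = tau_uncertainty)
}

#' Flatten a thermal calibration into a key-value report
#'
#' @param calib A `thermal_calibration`.
#' @return A named list suitable for JSON serialization.
#' @export
calibration_report <- function(calib) {
  list(sigma_r_nm = calib$sigma_r, sigma_w_nm = calib$sigma_w,
       tau_r_ms = 1e3 * calib$tau_r, tau_w_ms = 1e3 * calib$tau_w,
       sigma_r_raw_nm = calib$sigma_r_raw,
       sigma_w_raw_nm = calib$sigma_w_raw,
       exposure_ms = 1e3 * calib$exposure_time,
       frame_rate_hz = calib$frame_rate,
       n_samples = calib$n_samples,
       tracking_precision_nm = calib$tracking_precision)
}
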