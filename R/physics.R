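#' Worm-like-chain parameters
#'
#' Bundle the parameters of the worm-like-chain (WLC) model of a DNA tether.
#' Defaults follow standard values for double-stranded DNA in physiological
#' buffer at room temperature: persistence length 50 nm and thermal energy
#' kBT = 4.114 pN nm (298 K).
#'
#' @param contour_length Contour length of the tether (nm).
#' @param persistence_length Persistence length (nm). Default 50 nm.
#' @param thermal_energy Thermal energy kBT (pN nm). Default 4.114.
#' @return An object of class `wlc_params`.
#' @examples
#' wlc <- wlc_params(contour_length = 48502 * 0.34)
#' wlc_force(0.85, wlc)
#' @export
wlc_params <- function(contour_length, persistence_length = 50,
                       thermal_energy = 4.114) {
  stopifnot(is.numeric(contour_length), length(contour_length) == 1L,
            is.finite(contour_length), contour_length > 0,
            is.numeric(persistence_length), persistence_length > 0,
            is.numeric(thermal_energy), thermal_energy > 0)
  if (persistence_length > contour_length / 20) {
    warning("persistence length is not small compared to the contour length; ",
            "the tether is not in the flexible-chain regime", call. = FALSE)
  }
  structure(
    list(contour_length = contour_length,
         persistence_length = persistence_length,
         thermal_energy = thermal_energy),
    class = "wlc_params"
  )
}

#' Bead hydrodynamic parameters
#'
#' Stokes drag for a sphere in bulk fluid, `drag = 6 pi eta a`. No wall
#' (Faxen) correction is applied: in the pulley geometry the bead hangs from a
#' capillary far from the coverslip.
#'
#' @param radius Bead radius (nm). Default 500 nm (a 1 um superparamagnetic
#'   bead).
#' @param viscosity Dynamic viscosity (pN s / nm^2). Default `1e-9`, i.e.
#'   1 mPa s, water at room temperature.
#' @return An object of class `bead_params` with fields `radius`, `viscosity`
#'   and the derived `drag` (pN s / nm).
#' @examples
#' bead_params()$drag   # ~9.42e-6 pN s/nm
#' @export
bead_params <- function(radius = 500, viscosity = 1e-9) {
  stopifnot(is.numeric(radius), radius > 0, is.numeric(viscosity),
            viscosity > 0)
  structure(
    list(radius = radius, viscosity = viscosity,
         drag = 6 * pi * viscosity * radius),
    class = "bead_params"
  )
}

#' Marko-Siggia worm-like-chain force at a given fractional extension
#'
#' The interpolation formula
#' `F = (kBT/Lp) * (1/(4 (1 - z)^2) - 1/4 + z)` linking tension to the
#' fractional end-to-end extension `z` of a WLC.
#'
#' @param extension_fraction Fractional extension(s) in `[0, 1)`.
#' @param params A [wlc_params()] object.
#' @return Force(s) in pN; non-negative, strictly increasing in `z`.
#' @examples
#' wlc <- wlc_params(contour_length = 16200)
#' wlc_force(0.85, wlc)  # ~1 pN
#' @export
wlc_force <- function(extension_fraction, params) {
  stopifnot(inherits(params, "wlc_params"))
  z <- extension_fraction
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("extension_fraction must be finite numeric", call. = FALSE)
  }
  if (any(z < 0) || any(z >= 1)) {
    stop("extension_fraction must lie in [0, 1)", call. = FALSE)
  }
  (params$thermal_energy / params$persistence_length) *
    (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Worm-like-chain end-to-end extension at a given force
#'
#' Numerical inversion of [wlc_force()]; returns the end-to-end length (nm),
#' i.e. the fractional extension times the contour length. Round-trips with
#' [wlc_force()] to better than 1e-8 relative.
#'
#' @param force Tension(s) in pN, `>= 0`.
#' @param params A [wlc_params()] object.
#' @return End-to-end extension(s) in nm.
#' @examples
#' wlc <- wlc_params(contour_length = 16200)
#' wlc_extension(1, wlc) / 1000   # ~13.8 um
#' @export
wlc_extension <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(force) || any(!is.finite(force))) {
    stop("force must be finite numeric", call. = FALSE)
  }
  if (any(force < 0)) stop("force must be non-negative", call. = FALSE)
  z <- vapply(force, function(f) {
    if (f == 0) return(0)
    uniroot(function(zz) wlc_force(zz, params) - f,
            lower = 0, upper = 1 - 1e-12,
            tol = .Machine$double.eps^0.9, maxiter = 2000L)$root
  }, numeric(1))
  z * params$contour_length
}

#' Worm-like-chain stiffness dF/dx at a given force
#'
#' The derivative of the Marko-Siggia force-extension curve with respect to
#' end-to-end distance, evaluated at the extension corresponding to `force`:
#' `dF/dx = (kBT / (Lp L0)) * (1/(2 (1 - z)^3) + 1)`.
#'
#' @inheritParams wlc_extension
#' @return Stiffness(es) in pN/nm; positive and increasing in force. The
#'   zero-force limit is `(3/2) kBT / (Lp L0)`.
#' @examples
#' wlc <- wlc_params(contour_length = 16200)
#' wlc_stiffness(1, wlc)   # ~8e-4 pN/nm
#' @export
wlc_stiffness <- function(force, params) {
  z <- wlc_extension(force, params) / params$contour_length
  (params$thermal_energy /
     (params$persistence_length * params$contour_length)) *
    (1 / (2 * (1 - z)^3) + 1)
}

#' Force estimate container
#'
#' @param tension Tension (pN).
#' @param uncertainty Symmetric uncertainty on the tension (pN), or `NA`.
#' @param extension_fraction Fractional extension in `[0, 1)` at that tension.
#' @return An object of class `force_estimate`.
#' @export
force_estimate <- function(tension, uncertainty = NA_real_,
                           extension_fraction = NA_real_) {
  stopifnot(tension >= 0, is.na(uncertainty) || uncertainty >= 0,
            is.na(extension_fraction) ||
              (extension_fraction >= 0 && extension_fraction < 1))
  structure(list(tension = tension, uncertainty = uncertainty,
                 extension_fraction = extension_fraction),
            class = "force_estimate")
}

#' @export
print.force_estimate <- function(x, ...) {
  cat(sprintf("Tension: %.3g pN", x$tension))
  if (!is.na(x$uncertainty)) cat(sprintf(" +/- %.2g pN", x$uncertainty))
  if (!is.na(x$extension_fraction)) {
    cat(sprintf("  (extension %.1f%% of contour)",
                100 * x$extension_fraction))
  }
  cat("\n")
  invisible(x)
}

# Solve wlc_stiffness(F) = k for F. Stiffness is strictly increasing in F so
# the solution is unique when it exists.
solve_stiffness_for_force <- function(k, params) {
  f_hi <- 1
  while (wlc_stiffness(f_hi, params) < k && f_hi < 1e6) f_hi <- f_hi * 2
  uniroot(function(f) wlc_stiffness(f, params) - k,
          lower = 0, upper = f_hi, tol = 1e-12)$root
}

#' Infer DNA tension from the bead's relaxation time
#'
#' The overdamped relaxation time of the bead's thermal fluctuations along
#' the stretching axis satisfies `tau = gamma / k`, where `gamma` is the
#' Stokes drag and `k` the stiffness of the tether. The tension is obtained
#' by inverting the WLC stiffness-force relation at `k = gamma / tau`.
#'
#' If `tau_uncertainty` is given, the force uncertainty is propagated by
#' symmetric finite differencing: half the spread of the forces inferred at
#' `tau - tau_uncertainty` and `tau + tau_uncertainty`.
#'
#' @param tau Relaxation time (s), `> 0`.
#' @param bead A [bead_params()] object.
#' @param params A [wlc_params()] object for the tether.
#' @param tau_uncertainty Optional uncertainty on `tau` (s).
#' @return A [force_estimate()] with the tension, its propagated uncertainty
#'   and the fractional extension at that tension.
#' @examples
#' wlc <- wlc_params(contour_length = 16200)
#' tension_from_relaxation(0.010, bead_params(), wlc)  # ~1 pN
#' @export
tension_from_relaxation <- function(tau, bead, params,
                                    tau_uncertainty = NULL) {
  stopifnot(inherits(bead, "bead_params"), inherits(params, "wlc_params"),
            is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  k <- bead$drag / tau
  k0 <- wlc_stiffness(0, params)
  if (k <= k0) {
    stop(structure(
      class = c("dnapulley_zero_tension", "error", "condition"),
      list(message = paste0(
             "relaxation time implies a stiffness at or below the ",
             "zero-force WLC stiffness: tension indistinguishable from zero"),
           call = sys.call(-1))))
  }
  f <- solve_stiffness_for_force(k, params)
  unc <- NA_real_
  if (!is.null(tau_uncertainty)) {
    stopifnot(tau_uncertainty > 0, tau_uncertainty < tau)
    f_at <- function(t) {
      kk <- bead$drag / t
      if (kk <= k0) 0 else solve_stiffness_for_force(kk, params)
    }
    unc <- (f_at(tau - tau_uncertainty) - f_at(tau + tau_uncertainty)) / 2
  }
  force_estimate(tension = f, uncertainty = unc,
                 extension_fraction = wlc_extension(f, params) /
                   params$contour_length)
}

#' Fractional force variation of a dipolar magnet over a scan
#'
#' For a dipole field the force on the bead scales as `1/R^4` with the
#' bead-magnet distance `R`, so a distance excursion `delta_R` produces a
#' fractional force variation of `4 delta_R / R`.
#'
#' @param delta_R Variation of the bead-magnet distance (same units as `R`).
#' @param R Mean bead-magnet distance, `> 0`.
#' @return Dimensionless fractional force variation `4 delta_R / R`.
#' @examples
#' magnet_force_variation(1e4, 1e6)   # 10 um over 1 mm -> 0.04
#' @export
magnet_force_variation <- function(delta_R, R) {
  if (!is.numeric(R) || any(R <= 0)) stop("R must be positive", call. = FALSE)
  if (!is.numeric(delta_R) || any(delta_R < 0) || any(delta_R >= R)) {
    stop("delta_R must satisfy 0 <= delta_R < R", call. = FALSE)
  }
  4 * delta_R / R
}
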