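#' Pulley geometry
#'
#' The geometric model of the DNA pulley. The blade tip is the origin `O` of
#' the pulley frame; the `r`-axis points from the blade toward the magnet
#' (along the magnetic force) and the `w`-axis is orthogonal to it. With the
#' piezo coordinate `P` defined so that `P = P0` when the line joining the
#' DNA-capillary junction and the blade is along the x-axis, the stretched
#' length of the capillary-side segment is `q(P) = sqrt((P - P0)^2 + d^2)`
#' and the radial bead coordinate while the DNA is in contact with the blade
#' is `r = l0 - q(P)` (with `w = 0`).
#'
#' Lengths here are stretched (spatial) lengths at the calibrated tension;
#' `l0` is the stretched tether length, and base-pair conversion divides by
#' the fractional extension (see [contour_nm_to_bp()]).
#'
#' @param l0 Effective stretched tether length (nm).
#' @param d Blade-capillary distance (nm), `> 0` and `< l0`.
#' @param P0 Piezo reading at the apex of the scan (nm).
#' @param thetaF Angle of the force (r-axis) below the camera x-axis (rad),
#'   in `(0, pi/2)`.
#' @param origin Blade tip position in the camera frame (nm, length-2).
#' @param extension_fraction Fractional extension of the DNA at the ambient
#'   tension, in `(0, 1)`; used for nm-to-bp conversion.
#' @return An object of class `pulley_geometry`.
#' @examples
#' geom <- pulley_geometry(l0 = 13800, d = 2800, P0 = 0, thetaF = pi / 4,
#'                         extension_fraction = 0.85)
#' predict_bead_r(0, geom)  # apex: l0 - d
#' @export
pulley_geometry <- function(l0, d, P0 = 0, thetaF = pi / 4,
                            origin = c(0, 0), extension_fraction = 0.85) {
  stopifnot(is.numeric(l0), is.numeric(d), d > 0, l0 > d,
            is.numeric(P0), length(origin) == 2L, all(is.finite(origin)),
            thetaF > 0, thetaF < pi / 2,
            extension_fraction > 0, extension_fraction < 1)
  structure(
    list(l0 = l0, d = d, P0 = P0, thetaF = thetaF,
         origin = as.numeric(origin),
         extension_fraction = extension_fraction),
    class = "pulley_geometry"
  )
}

#' @export
print.pulley_geometry <- function(x, ...) {
  cat("Pulley geometry\n")
  cat(sprintf("  l0      = %.1f nm (stretched tether length)\n", x$l0))
  cat(sprintf("  d       = %.1f nm (blade-capillary distance)\n", x$d))
  cat(sprintf("  P0      = %.1f nm (piezo apex)\n", x$P0))
  cat(sprintf("  thetaF  = %.2f deg below x-axis\n", x$thetaF * 180 / pi))
  cat(sprintf("  origin  = (%.1f, %.1f) nm\n", x$origin[1], x$origin[2]))
  cat(sprintf("  extension fraction = %.3f\n", x$extension_fraction))
  invisible(x)
}

# unit vectors of the pulley frame in camera coordinates
pulley_axes <- function(geom) {
  list(r = c(cos(geom$thetaF), -sin(geom$thetaF)),
       w = c(sin(geom$thetaF), cos(geom$thetaF)))
}

# stretched capillary-side length at piezo position P
capillary_arm_length <- function(P, geom) {
  sqrt((P - geom$P0)^2 + geom$d^2)
}

#' Predicted radial bead coordinate while in contact with the blade
#'
#' Evaluates `r = l0 - sqrt((P - P0)^2 + d^2)`. A negative prediction means
#' the tether is shorter than the junction-blade distance, i.e. the DNA has
#' unhooked from the blade; such values are returned as `NA` with a warning.
#'
#' @param P Piezo coordinate(s) (nm).
#' @param geom A [pulley_geometry()] object.
#' @return Radial bead coordinate(s) r (nm).
#' @export
predict_bead_r <- function(P, geom) {
  stopifnot(inherits(geom, "pulley_geometry"), is.numeric(P))
  r <- geom$l0 - capillary_arm_length(P, geom)
  if (any(r < 0, na.rm = TRUE)) {
    warning("tether shorter than junction-blade distance (unhooked) at ",
            sum(r < 0), " piezo position(s); returning NA there",
            call. = FALSE)
    r[r < 0] <- NA_real_
  }
  r
}

#' Transform camera coordinates to the pulley (r, w) frame
#'
#' Rigid rotation and translation taking camera-frame bead positions to the
#' pulley frame: `r` along the force direction (thetaF below the x-axis),
#' `w` orthogonal, origin at the blade tip.
#'
#' @param bead_xy Numeric length-2 vector or an n x 2 matrix of camera
#'   positions (nm).
#' @param geom A [pulley_geometry()] object.
#' @return A matrix with columns `r` and `w` (nm).
#' @seealso [from_pulley_frame()] for the exact inverse.
#' @export
to_pulley_frame <- function(bead_xy, geom) {
  stopifnot(inherits(geom, "pulley_geometry"))
  xy <- if (is.matrix(bead_xy)) bead_xy else matrix(bead_xy, ncol = 2L)
  stopifnot(ncol(xy) == 2L)
  ax <- pulley_axes(geom)
  dx <- xy[, 1] - geom$origin[1]
  dy <- xy[, 2] - geom$origin[2]
  cbind(r = dx * ax$r[1] + dy * ax$r[2],
        w = dx * ax$w[1] + dy * ax$w[2])
}

#' Transform pulley-frame coordinates back to the camera frame
#'
#' @param rw Numeric length-2 vector or an n x 2 matrix of `(r, w)`
#'   coordinates (nm).
#' @inheritParams to_pulley_frame
#' @return A matrix with columns `x` and `y` (nm).
#' @export
from_pulley_frame <- function(rw, geom) {
  stopifnot(inherits(geom, "pulley_geometry"))
  m <- if (is.matrix(rw)) rw else matrix(rw, ncol = 2L)
  ax <- pulley_axes(geom)
  cbind(x = geom$origin[1] + m[, 1] * ax$r[1] + m[, 2] * ax$w[1],
        y = geom$origin[2] + m[, 1] * ax$r[2] + m[, 2] * ax$w[2])
}

#' Convert a stretched length along the tether to base pairs
#'
#' Spatial (stretched) lengths are converted to sequence coordinates by
#' dividing by the helical rise per base pair times the fractional extension:
#' `bp = length / (rise_per_bp * extension_fraction)`. At 85% extension,
#' 85 bp correspond to about 25 nm.
#'
#' @param length Stretched length(s) (nm).
#' @param extension_fraction Fractional extension in `(0, 1]`.
#' @param rise_per_bp Helical rise per base pair (nm). Default 0.34.
#' @return Position(s)/length(s) in base pairs (continuous).
#' @export
contour_nm_to_bp <- function(length, extension_fraction,
                             rise_per_bp = 0.34) {
  stopifnot(is.numeric(length),
            extension_fraction > 0, extension_fraction <= 1,
            rise_per_bp > 0)
  if (any(length < 0, na.rm = TRUE)) {
    stop("length must be non-negative", call. = FALSE)
  }
  length / (rise_per_bp * extension_fraction)
}

#' Convert base pairs to a stretched length along the tether
#'
#' Inverse of [contour_nm_to_bp()].
#'
#' @param bp Length(s) in base pairs.
#' @inheritParams contour_nm_to_bp
#' @return Stretched length(s) in nm.
#' @export
contour_bp_to_nm <- function(bp, extension_fraction, rise_per_bp = 0.34) {
  stopifnot(is.numeric(bp),
            extension_fraction > 0, extension_fraction <= 1,
            rise_per_bp > 0)
  if (any(bp < 0, na.rm = TRUE)) stop("bp must be non-negative",
                                      call. = FALSE)
  bp * rise_per_bp * extension_fraction
}

#' Contour position of the blade predicted from the stage motion
#'
#' The capillary-side stretched length `sqrt((P - P0)^2 + d^2)` converted to
#' base pairs: the position along the DNA (measured from the capillary-DNA
#' junction) at which the blade is predicted to sit, `L_pred`.
#'
#' @inheritParams predict_bead_r
#' @return Predicted contour position(s) in bp.
#' @export
map_piezo_to_contour <- function(P, geom) {
  stopifnot(inherits(geom, "pulley_geometry"))
  q <- capillary_arm_length(P, geom)
  if (any(q > geom$l0, na.rm = TRUE)) {
    warning("piezo position outside the in-contact range at ",
            sum(q > geom$l0), " sample(s); returning NA there",
            call. = FALSE)
    q[q > geom$l0] <- NA_real_
  }
  contour_nm_to_bp(q, geom$extension_fraction)
}

#' Contour position of the blade measured from the bead position
#'
#' From the radial bead coordinate `r`, the capillary-side stretched length
#' is `l0 - r`; converted to base pairs this is `L_meas`, the blade's contour
#' position as inferred from the bead tracking. When the DNA slides freely
#' over the blade, `L_meas` equals [map_piezo_to_contour()]'s `L_pred`; while
#' the DNA is stuck on a protein, `L_meas` stays constant as `L_pred`
#' advances.
#'
#' @param r Radial bead coordinate(s) (nm), `0 <= r <= l0`.
#' @inheritParams predict_bead_r
#' @return Measured contour position(s) in bp.
#' @export
measured_contour <- function(r, geom) {
  stopifnot(inherits(geom, "pulley_geometry"), is.numeric(r))
  if (any(r > geom$l0, na.rm = TRUE)) {
    stop("r exceeds the stretched tether length l0", call. = FALSE)
  }
  contour_nm_to_bp(geom$l0 - r, geom$extension_fraction)
}

# Parabola vertex through the three highest-r samples: apex initializer.
apex_parabola <- function(P, proj) {
  i <- which.max(proj)
  if (i <= 1L || i >= length(P)) return(P[i])
  idx <- (i - 1L):(i + 1L)
  fit <- lm(proj[idx] ~ P[idx] + I(P[idx]^2))
  a2 <- coef(fit)[[3]]
  if (!is.finite(a2) || a2 >= 0) return(P[i])
  -coef(fit)[[2]] / (2 * a2)
}

#' Fit the pulley geometry to a scan trajectory
#'
#' Least-squares fit of the pulley model to in-contact bead positions. The
#' bead position in the camera frame while in contact is
#' `bead(P) = A - q(P) * r_hat`, where `A = O + l0 * r_hat` is the apex
#' point (the bead position the model extrapolates to at `q = 0`),
#' `q(P) = sqrt((P - P0)^2 + d^2)` and `r_hat` is the unit vector at
#' `thetaF` below the x-axis. The five parameters `(A_x, A_y, thetaF, d,
#' P0)` are identifiable from the trajectory alone and are fitted by
#' Levenberg-Marquardt ([minpack.lm::nls.lm]), initialized from the scan
#' apex (parabola vertex through the three highest-r samples) and a default
#' 45-degree force angle.
#'
#' The split of `A` into blade-tip origin `O` and tether length `l0` is not
#' determined by the trajectory (any shift of `O` along `r_hat` can be
#' absorbed into `l0`), so exactly one of `origin` (blade tip known from
#' imaging) or `l0` (stretched tether length from the WLC calibration) must
#' be supplied to resolve it.
#'
#' @param traj A scan trajectory `data.frame` with columns `time_s`,
#'   `piezo_nm`, `x_nm`, `y_nm` (see [read_trajectory()]), assumed in
#'   contact with the blade; use `contact` to restrict to a subset.
#' @param origin Optional blade-tip position (nm, length-2).
#' @param l0 Optional stretched tether length (nm).
#' @param extension_fraction Fractional extension for bp conversion.
#' @param thetaF_init Initial force angle (rad). Default `pi/4`.
#' @param contact Optional logical vector or integer index selecting the
#'   in-contact samples.
#' @return A list of class `pulley_fit` with elements `geometry` (a
#'   [pulley_geometry()]), `residuals` (`data.frame` with per-sample `r` and
#'   `w` residuals, nm), `sigma_r`/`sigma_w` (robust residual scales, nm),
#'   `apex` (the fitted apex point), and `convergence` diagnostics.
#' @export
fit_geometry <- function(traj, origin = NULL, l0 = NULL,
                         extension_fraction = 0.85, thetaF_init = pi / 4,
                         contact = NULL) {
  stopifnot(is.data.frame(traj),
            all(c("piezo_nm", "x_nm", "y_nm") %in% names(traj)))
  if (is.null(origin) && is.null(l0)) {
    stop("supply either `origin` (blade tip from imaging) or `l0` (tether ",
         "length from calibration): the two are degenerate in the fit",
         call. = FALSE)
  }
  if (!is.null(contact)) traj <- traj[contact, , drop = FALSE]
  if (nrow(traj) < 10L) stop("too few in-contact samples to fit",
                             call. = FALSE)
  P <- traj$piezo_nm
  X <- traj$x_nm
  Y <- traj$y_nm

  # initialization: project on the initial r axis, find apex, estimate d
  # from the local curvature r ~ const - (P-P0)^2/(2 d)
  th <- thetaF_init
  proj <- X * cos(th) - Y * sin(th)
  P0_init <- apex_parabola(P, proj)
  span <- diff(range(P))
  near <- abs(P - P0_init) < span / 4
  if (sum(near) < 5L) near <- rep(TRUE, length(P))
  qfit <- lm(proj[near] ~ I((P[near] - P0_init)^2))
  a2 <- coef(qfit)[[2]]
  d_init <- if (is.finite(a2) && a2 < 0) 1 / (2 * abs(a2)) else span / 4
  A_init <- c(max(proj) + d_init, 0)
  # w-coordinate of A: mean projection on the initial w axis
  A_w <- mean(X * sin(th) + Y * cos(th))

  resid_fun <- function(par, keep = TRUE) {
    Ax <- par[1]; Ay <- par[2]; theta <- par[3]
    dd <- abs(par[4]); PP0 <- par[5]
    q <- sqrt((P - PP0)^2 + dd^2)
    rx <- cos(theta); ry <- -sin(theta)
    c((X - (Ax - q * rx))[keep], (Y - (Ay - q * ry))[keep])
  }
  # camera-frame apex from (r, w) projections in the initial frame
  A_cam <- c(A_init[1] * cos(th) + A_w * sin(th),
             -A_init[1] * sin(th) + A_w * cos(th))
  start <- c(A_cam[1], A_cam[2], th, d_init, P0_init)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000,
                                     ftol = 1e-14, ptol = 1e-14)
  # box constraints keep the fit off the degenerate branch where d and P0
  # run away together and q(P) flattens into a straight line
  lower <- c(-Inf, -Inf, 1e-3, 1, min(P) - 2 * span)
  upper <- c(Inf, Inf, pi / 2 - 1e-3, 5 * span, max(P) + 2 * span)
  start <- pmin(pmax(start, lower), upper)
  # iterated trimmed least squares: pause intervals (bead stuck on a
  # protein) are gross outliers of the free-sliding model, so each pass
  # keeps only samples within 4 robust sigma of the current model before
  # refitting (MAD of the residual radius, floored at the tracking noise
  # scale). Passes restart from the apex/45-degree initialization so a
  # contaminated early fit cannot lock in.
  par_cur <- start
  fit <- NULL
  for (pass in 1:4) {
    res2 <- matrix(resid_fun(par_cur), ncol = 2L)
    # project on the current (r, w) axes: sticking excursions live almost
    # entirely along r, so each axis is trimmed against its own scale
    thc <- par_cur[3]
    res_r <- res2[, 1] * cos(thc) - res2[, 2] * sin(thc)
    res_w <- res2[, 1] * sin(thc) + res2[, 2] * cos(thc)
    keep <- abs(res_r) <= 4 * max(mad(res_r, center = 0), 1e-9) &
      abs(res_w) <= 4 * max(mad(res_w, center = 0), 1e-9)
    if (sum(keep) < 10L) keep <- rep(TRUE, length(res_r))
    fit <- minpack.lm::nls.lm(par = start, fn = resid_fun, keep = keep,
                              lower = lower, upper = upper, control = ctrl)
    if (max(abs(fit$par - par_cur)) < 1e-8) { par_cur <- fit$par; break }
    par_cur <- fit$par
  }
  if (fit$info %in% c(0L, 5L)) {
    stop("geometry fit did not converge: ", fit$message, call. = FALSE)
  }
  par <- fit$par
  at_bound <- which(par <= lower + 1e-9 | par >= upper - 1e-9)
  if (length(at_bound)) {
    stop("geometry fit hit a parameter bound (parameter ",
         paste(c("Ax", "Ay", "thetaF", "d", "P0")[at_bound],
               collapse = ", "),
         "): fit failure", call. = FALSE)
  }
  A <- par[1:2]; theta <- par[3]; d <- abs(par[4]); P0 <- par[5]
  rhat <- c(cos(theta), -sin(theta))

  if (!is.null(origin)) {
    l0_hat <- sum((A - origin) * rhat)
    O <- as.numeric(origin)
  } else {
    l0_hat <- l0
    O <- A - l0 * rhat
  }
  if (l0_hat <= d) {
    stop("fitted geometry implies l0 <= d: fit failure (apex/origin ",
         "inconsistent)", call. = FALSE)
  }
  geom <- pulley_geometry(l0 = l0_hat, d = d, P0 = P0, thetaF = theta,
                          origin = O,
                          extension_fraction = extension_fraction)

  # residuals from the fitted model, projected on the fitted (r, w) axes
  q <- capillary_arm_length(P, geom)
  ax <- pulley_axes(geom)
  res_x <- X - (A[1] - q * ax$r[1])
  res_y <- Y - (A[2] - q * ax$r[2])
  res_r <- res_x * ax$r[1] + res_y * ax$r[2]
  res_w <- res_x * ax$w[1] + res_y * ax$w[2]
  list(
    geometry = geom,
    residuals = data.frame(piezo_nm = P, r = res_r, w = res_w),
    sigma_r = mad(res_r), sigma_w = mad(res_w),
    apex = A,
    convergence = list(info = fit$info, message = fit$message,
                       deviance = fit$deviance, niter = fit$niter)
  )
}

#' Flatten a fitted geometry into a key-value report
#'
#' @param fit A `pulley_fit` as returned by [fit_geometry()].
#' @return A named list suitable for JSON serialization.
#' @export
geometry_report <- function(fit) {
  g <- fit$geometry
  list(l0_nm = g$l0, d_nm = g$d, P0_nm = g$P0,
       thetaF_deg = g$thetaF * 180 / pi,
       origin_x_nm = g$origin[1], origin_y_nm = g$origin[2],
       extension_fraction = g$extension_fraction,
       sigma_r_nm = fit$sigma_r, sigma_w_nm = fit$sigma_w,
       n_samples = nrow(fit$residuals),
       deviance_nm2 = fit$convergence$deviance)
}
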