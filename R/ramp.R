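#' Bell-Evans bond model
#'
#' Parameters of a slip bond whose rupture rate grows exponentially with
#' force: `k(F) = k0 * exp(F * x_dagger / kBT)`.
#'
#' @param k0 Zero-force off-rate (1/s), `> 0`.
#' @param x_dagger Distance to the transition state (nm), `> 0`.
#' @param thermal_energy Thermal energy kBT (pN nm). Default 4.114.
#' @return An object of class `bond_model`.
#' @export
bond_model <- function(k0, x_dagger, thermal_energy = 4.114) {
  stopifnot(k0 > 0, x_dagger > 0, thermal_energy > 0)
  structure(list(k0 = k0, x_dagger = x_dagger,
                 thermal_energy = thermal_energy),
            class = "bond_model")
}

#' Linear force ramp specification
#'
#' The tension applied to a stuck bond as a function of time:
#' `F(t) = max(F0 + loading_rate * t, 0)`. The loading rate is signed:
#' positive for forward scans (tension building up) and negative for reverse
#' scans (tension relaxing toward zero).
#'
#' @param F0 Initial tension (pN), `>= 0`.
#' @param loading_rate Loading rate (pN/s), signed.
#' @param t_max Maximum duration considered (s). Default `Inf`.
#' @return An object of class `ramp_spec`.
#' @export
ramp_spec <- function(F0, loading_rate, t_max = Inf) {
  stopifnot(F0 >= 0, is.finite(loading_rate), t_max > 0)
  structure(list(F0 = F0, loading_rate = loading_rate, t_max = t_max),
            class = "ramp_spec")
}

# force along the ramp, clamped at zero from below
ramp_force <- function(t, ramp) pmax(ramp$F0 + ramp$loading_rate * t, 0)

#' Bell rupture rate at a given force
#'
#' `k(F) = k0 * exp(F * x_dagger / kBT)`. The exponent is capped at 500 to
#' guard against overflow; capped values carry an attribute
#' `saturated = TRUE`.
#'
#' @param F Force(s) in pN, `>= 0`.
#' @param bond A [bond_model()].
#' @return Rate(s) in 1/s.
#' @export
bell_rate <- function(F, bond) {
  stopifnot(inherits(bond, "bond_model"))
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  expo <- F * bond$x_dagger / bond$thermal_energy
  sat <- expo > 500
  expo[sat] <- 500
  out <- bond$k0 * exp(expo)
  if (any(sat)) attr(out, "saturated") <- TRUE
  out
}

#' Survival probability of a bond under a linear force ramp
#'
#' `S(t) = exp(-integral_0^t k(F(t')) dt')` for the Bell rate under the
#' linear ramp `F(t) = max(F0 + r t, 0)`. For nonzero loading rate the
#' hazard integral has the closed form
#' `(k0 kBT / (r x)) * (exp(F(t) x / kBT) - exp(F0 x / kBT))`; for rate zero
#' it reduces to constant-force exponential decay. For negative rates the
#' force clamps at zero at `t = -F0/r`, after which the hazard is the
#' constant `k0`.
#'
#' @param t Time(s) since the onset of the ramp (s), `>= 0`.
#' @param ramp A [ramp_spec()].
#' @param bond A [bond_model()].
#' @return Survival probabilities `S(t)` in `[0, 1]`, with `S(0) = 1` and
#'   `S` non-increasing.
#' @export
ramp_survival <- function(t, ramp, bond) {
  stopifnot(inherits(ramp, "ramp_spec"), inherits(bond, "bond_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-ramp_hazard_integral(t, ramp, bond))
}

# cumulative hazard H(t) = int_0^t k(F(t')) dt', closed form
ramp_hazard_integral <- function(t, ramp, bond) {
  a <- bond$x_dagger / bond$thermal_energy
  r <- ramp$loading_rate
  if (r == 0) return(bell_rate(ramp$F0, bond) * t)
  t_clamp <- if (r < 0) ramp$F0 / (-r) else Inf
  t1 <- pmin(t, t_clamp)
  # expm1 form avoids Inf - Inf for large F x/kBT and is accurate for
  # small ramp excursions
  H <- (bond$k0 / (r * a)) * exp(a * ramp$F0) * expm1(a * r * t1)
  extra <- pmax(t - t_clamp, 0)
  H + bond$k0 * extra
}

#' Tension in the stuck capillary-blade DNA segment
#'
#' While the DNA is stuck on a protein pinned at the blade, the contour
#' length of the capillary-blade segment is frozen at its value at the
#' sticking onset, while its end-to-end distance continues to follow the
#' piezo: `q(P) = sqrt((P - P0)^2 + d^2)`. The segment tension is the WLC
#' force at extension `q(P) / stuck_contour`. Forward motion (growing
#' `|P - P0|`) raises the tension; reverse motion lowers it.
#'
#' @param P Piezo coordinate(s) (nm).
#' @param geom A [pulley_geometry()].
#' @param stuck_contour Contour length (nm, crystallographic) of the frozen
#'   capillary-blade segment.
#' @param wlc A [wlc_params()] object whose persistence length and thermal
#'   energy are used (its contour length is ignored in favor of
#'   `stuck_contour`).
#' @return Tension(s) in pN. If the end-to-end distance reaches the contour
#'   length the segment is overstretched and an error of class
#'   `dnapulley_overstretch` is raised (rupture is forced).
#' @export
segment_tension <- function(P, geom, stuck_contour, wlc) {
  stopifnot(inherits(geom, "pulley_geometry"), inherits(wlc, "wlc_params"),
            stuck_contour > 0)
  q <- capillary_arm_length(P, geom)
  z <- q / stuck_contour
  if (any(z >= 1)) {
    stop(structure(
      class = c("dnapulley_overstretch", "error", "condition"),
      list(message = "stuck segment end-to-end reached its contour length",
           call = sys.call(-1))))
  }
  seg <- wlc_params(contour_length = stuck_contour,
                    persistence_length = wlc$persistence_length,
                    thermal_energy = wlc$thermal_energy)
  wlc_force(z, seg)
}

#' Local loading rate of the stuck segment at a given piezo position
#'
#' `dF/dt = (dF/dq) * (dq/dP) * scan_speed` by the chain rule, evaluated by
#' analytic WLC stiffness of the stuck segment.
#'
#' @inheritParams segment_tension
#' @param scan_speed Piezo speed (nm/s), signed along increasing `P`.
#' @return Loading rate (pN/s), signed.
#' @export
segment_loading_rate <- function(P, geom, stuck_contour, wlc, scan_speed) {
  q <- capillary_arm_length(P, geom)
  seg <- wlc_params(contour_length = stuck_contour,
                    persistence_length = wlc$persistence_length,
                    thermal_energy = wlc$thermal_energy)
  F_now <- wlc_force(q / stuck_contour, seg)
  dFdq <- wlc_stiffness(F_now, seg)
  dqdP <- (P - geom$P0) / q
  dFdq * dqdP * scan_speed
}

#' Sample rupture times under a linear force ramp
#'
#' Inverse-transform sampling from the rupture-time distribution
#' `1 - S(t)` of [ramp_survival()]. The inversion is exact (closed form)
#' including the clamp of the force at zero for negative rates.
#'
#' @param n Number of samples.
#' @param ramp A [ramp_spec()].
#' @param bond A [bond_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` rupture times (s).
#' @export
sample_rupture_times <- function(n, ramp, bond, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  H <- -log(u)                     # target cumulative hazard
  a <- bond$x_dagger / bond$thermal_energy
  r <- ramp$loading_rate
  if (r == 0) return(H / bell_rate(ramp$F0, bond))
  eF0 <- exp(a * ramp$F0)
  arg <- eF0 + (r * a / bond$k0) * H
  t <- numeric(n)
  if (r > 0) {
    t <- (log(arg) / a - ramp$F0) / r
  } else {
    t_clamp <- ramp$F0 / (-r)
    H_clamp <- (bond$k0 / (r * a)) * (1 - eF0)  # hazard spent before clamp
    pre <- H <= H_clamp
    t[pre] <- (log(arg[pre]) / a - ramp$F0) / r
    t[!pre] <- t_clamp + (H[!pre] - H_clamp) / bond$k0
  }
  t
}

#' Maximum-likelihood fit of the Bell-Evans model to rupture durations
#'
#' Fits `(k0, x_dagger)` by maximizing the ramp-survival likelihood
#' `f(t) = k(F(t)) S(t)` for durations observed under a known linear force
#' ramp. Profile-likelihood 95% confidence intervals are reported for both
#' parameters. With loading rate zero the model reduces to an exponential
#' distribution: `k0 = 1/mean(durations)` and `x_dagger` is not
#' identifiable (returned as `NA` with `identifiable = FALSE`).
#'
#' @param durations Rupture durations (s), at least 20.
#' @param ramp A [ramp_spec()] describing the ramp the durations were
#'   observed under.
#' @param thermal_energy Thermal energy kBT (pN nm). Default 4.114.
#' @return A list with `bond` (the fitted [bond_model()]), `k0`, `x_dagger`,
#'   `ci_k0`, `ci_x_dagger` (95% profile intervals), `loglik` and
#'   `identifiable`.
#' @export
fit_ramp_model <- function(durations, ramp, thermal_energy = 4.114) {
  stopifnot(is.numeric(durations), length(durations) >= 20,
            all(durations > 0), inherits(ramp, "ramp_spec"))
  if (ramp$loading_rate == 0) {
    k0 <- 1 / mean(durations)
    n <- length(durations)
    return(list(bond = NULL, k0 = k0, x_dagger = NA_real_,
                ci_k0 = k0 * c(qchisq(0.025, 2 * n), qchisq(0.975, 2 * n)) /
                  (2 * n),
                ci_x_dagger = c(NA_real_, NA_real_),
                loglik = sum(log(k0) - k0 * durations),
                identifiable = FALSE))
  }
  nll <- function(p) {
    b <- bond_model(exp(p[1]), exp(p[2]), thermal_energy)
    F_t <- ramp_force(durations, ramp)
    haz <- bell_rate(F_t, b)
    v <- -sum(log(haz) - ramp_hazard_integral(durations, ramp, b))
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e10  # off-scale region
    v
  }
  init <- c(log(1 / mean(durations)), log(1))
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) {
    warning("ramp-model optimization did not fully converge", call. = FALSE)
  }
  k0_hat <- exp(opt$par[1]); x_hat <- exp(opt$par[2])

  # profile-likelihood CI: deviance crosses qchisq(0.95, 1)
  profile_ci <- function(which_par) {
    target <- opt$value + qchisq(0.95, 1) / 2
    prof <- function(val) {
      obj <- function(q) {
        p <- numeric(2)
        p[which_par] <- val; p[-which_par] <- q
        nll(p)
      }
      optimize(obj, interval = opt$par[-which_par] + c(-8, 8))$objective -
        target
    }
    mle <- opt$par[which_par]
    lo <- tryCatch(uniroot(prof, c(mle - 10, mle), tol = 1e-4)$root,
                   error = function(e) -Inf)
    hi <- tryCatch(uniroot(prof, c(mle, mle + 10), tol = 1e-4)$root,
                   error = function(e) Inf)
    exp(c(lo, hi))
  }
  ci_k0 <- profile_ci(1)
  ci_x <- profile_ci(2)
  identifiable <- all(is.finite(ci_x)) && all(is.finite(ci_k0))
  if (!identifiable) {
    warning("flat likelihood direction: parameters not jointly ",
            "identifiable from these durations", call. = FALSE)
  }
  list(bond = bond_model(k0_hat, x_hat, thermal_energy),
       k0 = k0_hat, x_dagger = x_hat,
       ci_k0 = ci_k0, ci_x_dagger = ci_x,
       loglik = -opt$value, identifiable = identifiable)
}
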