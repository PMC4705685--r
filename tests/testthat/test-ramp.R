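test_that("Bell rate is exponential in force", {
  b <- bond_model(k0 = 0.2, x_dagger = 1)
  expect_equal(bell_rate(0, b), 0.2)
  expect_equal(bell_rate(4.114, b), 0.2 * exp(1), tolerance = 1e-12)
  b2 <- bond_model(k0 = 1, x_dagger = 2)
  expect_equal(bell_rate(4.114 / 2, b2), exp(1), tolerance = 1e-12)
  # overflow guard: capped, flagged, finite
  big <- bell_rate(1e6, b)
  expect_true(is.finite(big))
  expect_true(attr(big, "saturated"))
  expect_error(bell_rate(-1, b), "non-negative")
})

test_that("ramp survival matches numerical quadrature of the hazard", {
  bond <- bond_model(k0 = 0.05, x_dagger = 2)
  for (rate in c(4, -0.5, 0.3)) {
    ramp <- ramp_spec(F0 = 1, loading_rate = rate)
    for (t in c(0.1, 0.7, 2.5)) {
      quad <- integrate(function(u) {
        bell_rate(pmax(1 + rate * u, 0), bond)
      }, 0, t, rel.tol = 1e-12)$value
      expect_equal(ramp_survival(t, ramp, bond), exp(-quad),
                   tolerance = 1e-8)
    }
  }
  # constant-force limit
  ramp0 <- ramp_spec(F0 = 2, loading_rate = 0)
  expect_equal(ramp_survival(1.5, ramp0, bond),
               exp(-bell_rate(2, bond) * 1.5), tolerance = 1e-14)
  # S(0) = 1 and monotone non-increasing
  ramp <- ramp_spec(F0 = 1, loading_rate = 2)
  tt <- seq(0, 5, by = 0.05)
  S <- ramp_survival(tt, ramp, bond)
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 0))
})

test_that("rupture-time sampler follows the analytic distribution", {
  bond <- bond_model(k0 = 0.05, x_dagger = 2)
  ramp <- ramp_spec(F0 = 1, loading_rate = 4)
  t_samp <- sample_rupture_times(1e5, ramp, bond, seed = 8)
  # one-sample KS distance against the analytic CDF
  cdf <- function(t) 1 - ramp_survival(t, ramp, bond)
  ts <- sort(t_samp)
  emp_hi <- seq_along(ts) / length(ts)
  emp_lo <- (seq_along(ts) - 1) / length(ts)
  D <- max(abs(emp_hi - cdf(ts)), abs(emp_lo - cdf(ts)))
  expect_lt(D, 0.01)
  # reproducible under a fixed seed
  expect_identical(t_samp, sample_rupture_times(1e5, ramp, bond, seed = 8))
  # negative-rate branch also matches its closed form after the force clamp
  rampn <- ramp_spec(F0 = 0.5, loading_rate = -2)
  tn <- sort(sample_rupture_times(1e5, rampn, bond, seed = 9))
  cdfn <- function(t) 1 - ramp_survival(t, rampn, bond)
  Dn <- max(abs(seq_along(tn) / length(tn) - cdfn(tn)))
  expect_lt(Dn, 0.01)
})

test_that("forward loading shortens pauses and unloading lengthens them", {
  bond <- bond_model(k0 = 0.05, x_dagger = 2)
  n <- 20000
  t_fwd <- sample_rupture_times(n, ramp_spec(1, 4), bond, seed = 1)
  t_cst <- sample_rupture_times(n, ramp_spec(1, 0), bond, seed = 2)
  t_rev <- sample_rupture_times(n, ramp_spec(1, -4), bond, seed = 3)
  expect_lt(mean(t_fwd), mean(t_cst))
  expect_lt(mean(t_cst), mean(t_rev))
})

test_that("maximum-likelihood ramp fit recovers known bond parameters", {
  k0 <- 0.05; xd <- 2
  bond <- bond_model(k0, xd)
  ramp <- ramp_spec(F0 = 1, loading_rate = 4)
  durations <- sample_rupture_times(200, ramp, bond, seed = 21)
  fit <- fit_ramp_model(durations, ramp)
  expect_equal(fit$k0, k0, tolerance = 0.25)
  expect_equal(fit$x_dagger, xd, tolerance = 0.25)
  expect_true(fit$identifiable)
  expect_true(fit$ci_k0[1] < k0 && k0 < fit$ci_k0[2])
  # rate zero reduces to the exponential MLE, x_dagger unidentifiable
  d0 <- sample_rupture_times(500, ramp_spec(1, 0), bond, seed = 22)
  f0 <- fit_ramp_model(d0, ramp_spec(1, 0))
  expect_equal(f0$k0, 1 / mean(d0), tolerance = 1e-12)
  expect_false(f0$identifiable)
  expect_true(is.na(f0$x_dagger))
  # doubling all durations at rate zero halves k0
  f2 <- fit_ramp_model(2 * d0, ramp_spec(1, 0))
  expect_equal(f2$k0, f0$k0 / 2, tolerance = 1e-12)
})

test_that("sampling and fitting round-trip is unbiased over seeds", {
  bond <- bond_model(0.05, 2)
  ramp <- ramp_spec(F0 = 1, loading_rate = 4)
  est <- vapply(1:20, function(s) {
    d <- sample_rupture_times(300, ramp, bond, seed = 400 + s)
    f <- fit_ramp_model(d, ramp)
    c(f$k0, f$x_dagger)
  }, numeric(2))
  expect_equal(mean(est[1, ]), 0.05, tolerance = 0.15)
  expect_equal(mean(est[2, ]), 2, tolerance = 0.15)
})

test_that("stuck-segment tension is continuous, monotone and consistent
          with the chain-rule loading rate", {
  g <- default_geometry()
  wlc <- lambda_wlc()
  # sticking onset at the ambient extension: tension equals the ambient
  P_on <- 3000
  q_on <- sqrt((P_on - g$P0)^2 + g$d^2)
  stuck_contour <- q_on / g$extension_fraction
  F_on <- segment_tension(P_on, g, stuck_contour, wlc)
  expect_equal(F_on, wlc_force(g$extension_fraction, wlc),
               tolerance = 1e-9)
  # forward displacement raises the tension strictly
  Ps <- seq(P_on, P_on + 500, by = 50)
  Fs <- segment_tension(Ps, g, stuck_contour, wlc)
  expect_true(all(diff(Fs) > 0))
  # chain-rule loading rate matches a finite difference along the scan
  v <- 1000
  lr <- segment_loading_rate(P_on, g, stuck_contour, wlc, v)
  dP <- 0.1
  lr_fd <- (segment_tension(P_on + dP, g, stuck_contour, wlc) -
            segment_tension(P_on - dP, g, stuck_contour, wlc)) / (2 * dP) * v
  expect_equal(lr, lr_fd, tolerance = 1e-6)
  # overstretch is reported as a forced-rupture condition
  expect_error(segment_tension(P_on + 5e4, g, stuck_contour, wlc),
               class = "dnapulley_overstretch")
})
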