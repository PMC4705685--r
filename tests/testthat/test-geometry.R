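test_that("predicted radial coordinate follows the pulley equation", {
  g <- default_geometry()
  # apex: r is maximal and equals l0 - d
  expect_equal(predict_bead_r(g$P0, g), g$l0 - g$d)
  # symmetry about the apex
  expect_equal(predict_bead_r(g$P0 + 1234, g), predict_bead_r(g$P0 - 1234, g))
  # matches the generating formula exactly
  P <- seq(-6000, 6000, by = 100)
  expect_equal(predict_bead_r(P, g), g$l0 - sqrt(P^2 + g$d^2),
               tolerance = 1e-14)
  # unhooked: tether shorter than junction-blade distance
  expect_warning(r <- predict_bead_r(g$l0 + 5000, g), "unhooked")
  expect_true(is.na(r))
})

test_that("pulley frame transform is rigid and exactly invertible", {
  g <- pulley_geometry(l0 = 13800, d = 2800, P0 = 0, thetaF = 0.6,
                       origin = c(123, -456), extension_fraction = 0.85)
  expect_equal(drop(to_pulley_frame(g$origin, g)), c(r = 0, w = 0))
  # unit step along the force direction maps to (1, 0)
  step <- g$origin + c(cos(g$thetaF), -sin(g$thetaF))
  expect_equal(drop(to_pulley_frame(step, g)), c(r = 1, w = 0),
               tolerance = 1e-12)
  set.seed(42)
  xy <- matrix(rnorm(200, sd = 5000), ncol = 2)
  rt <- from_pulley_frame(to_pulley_frame(xy, g), g)
  expect_equal(unname(rt), unname(xy), tolerance = 1e-12)
  # norm-preserving about the origin
  d0 <- sqrt(rowSums(sweep(xy, 2, g$origin)^2))
  d1 <- sqrt(rowSums(to_pulley_frame(xy, g)^2))
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("nm/bp conversion matches the 85 nt to 25 nm correspondence", {
  # 85 bp at 85% extension span about 25 nm
  expect_equal(contour_bp_to_nm(85, 0.85), 25, tolerance = 0.04)
  expect_equal(contour_nm_to_bp(0.34, 1), 1)
  bp <- c(1, 85, 1000, 48502)
  expect_equal(contour_nm_to_bp(contour_bp_to_nm(bp, 0.85), 0.85), bp,
               tolerance = 1e-12)
  expect_error(contour_nm_to_bp(-1, 0.85), "non-negative")
  expect_error(contour_bp_to_nm(10, 0))
})

test_that("piezo-predicted and bead-measured contour positions agree when
          sliding freely", {
  g <- default_geometry()
  P <- seq(-5000, 5000, by = 250)
  L_pred <- map_piezo_to_contour(P, g)
  # at the apex the blade sits d worth of stretched length from the junction
  expect_equal(map_piezo_to_contour(g$P0, g),
               g$d / (0.34 * g$extension_fraction))
  # monotone in |P - P0|
  expect_true(all(diff(L_pred[P >= g$P0]) > 0))
  expect_true(all(diff(L_pred[P <= g$P0]) < 0))
  # free sliding: r = l0 - q, so L_meas equals L_pred sample by sample
  r_free <- predict_bead_r(P, g)
  expect_equal(measured_contour(r_free, g), L_pred, tolerance = 1e-12)
  # and the magnet-side length closes the conservation budget:
  # capillary-side bp + magnet-side bp = total stretched tether in bp
  magnet_bp <- contour_nm_to_bp(r_free, g$extension_fraction)
  total_bp <- contour_nm_to_bp(g$l0, g$extension_fraction)
  expect_equal(L_pred + magnet_bp, rep(total_bp, length(P)),
               tolerance = 1e-12)
  expect_error(measured_contour(g$l0 + 1, g), "exceeds")
})

test_that("geometry fit recovers a noiseless synthetic scan to <0.1%", {
  g <- pulley_geometry(l0 = 13800, d = 2800, P0 = 150, thetaF = 0.75,
                       origin = c(800, -200), extension_fraction = 0.85)
  cfg <- scan_config(g, sigma_r = 0, sigma_w = 0, tracking_noise = 0,
                     drift_nm_per_min = 0, seed = 1)
  sc <- simulate_scan(cfg)
  fit <- fit_geometry(sc$trajectory, origin = g$origin)
  expect_equal(fit$geometry$l0, g$l0, tolerance = 1e-3)
  expect_equal(fit$geometry$d, g$d, tolerance = 1e-3)
  expect_equal(fit$geometry$P0, g$P0, tolerance = 1e-3 * g$d)
  expect_equal(fit$geometry$thetaF, g$thetaF, tolerance = 1e-3)
  # pulley-equation residuals vanish on noiseless data
  expect_lt(max(abs(fit$residuals$r)), 1e-6)
  expect_lt(max(abs(fit$residuals$w)), 1e-6)
})

test_that("geometry fit recovers l0 and d to <1% at experimental noise", {
  g <- default_geometry()
  n_seeds <- 20
  rel <- matrix(NA_real_, n_seeds, 4,
                dimnames = list(NULL, c("l0", "d", "P0", "thetaF")))
  for (s in seq_len(n_seeds)) {
    sc <- simulate_scan(scan_config(g, seed = 100 + s))
    fit <- fit_geometry(sc$trajectory, origin = g$origin)
    rel[s, ] <- c(fit$geometry$l0 / g$l0 - 1,
                  fit$geometry$d / g$d - 1,
                  (fit$geometry$P0 - g$P0) / g$d,
                  fit$geometry$thetaF / g$thetaF - 1)
  }
  expect_lt(max(abs(rel[, "l0"])), 0.01)
  expect_lt(max(abs(rel[, "d"])), 0.01)
  # recovery is unbiased to well under a percent
  expect_lt(max(abs(colMeans(rel))), 0.01)
})

test_that("w-residual is zero-mean while in contact", {
  g <- default_geometry()
  sc <- simulate_scan(scan_config(g, seed = 77))
  fit <- fit_geometry(sc$trajectory, origin = g$origin)
  # 4 standard errors of the mean of OU noise with tau_w correlation
  T_total <- nrow(fit$residuals) * 0.005
  se_w <- sqrt(2 * 89^2 * 0.068 / T_total)
  expect_lt(abs(mean(fit$residuals$w)), 4 * se_w)
  expect_gt(fit$sigma_w, fit$sigma_r)  # transverse axis is softer
})

test_that("the origin/l0 degeneracy must be resolved explicitly", {
  g <- default_geometry()
  sc <- simulate_scan(scan_config(g, seed = 5))
  expect_error(fit_geometry(sc$trajectory), "origin")
  # resolving with l0 instead of origin reproduces the blade tip
  fit <- fit_geometry(sc$trajectory, l0 = g$l0)
  expect_equal(fit$geometry$origin, g$origin, tolerance = 0.01 * g$l0)
})
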