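test_that("autocovariance estimator reproduces OU statistics", {
  set.seed(1)
  # white noise: all positive lags vanish within 3/sqrt(N)
  n <- 20000
  wn <- rnorm(n)
  ac <- autocorrelation(wn, max_lag = 20, normalize = TRUE)
  expect_true(all(abs(ac$value[ac$lag > 0]) < 3 / sqrt(n)))
  expect_equal(ac$value[ac$lag == 0], 1)
  # simulated OU: ACF ~ sigma^2 exp(-lag dt / tau)
  x <- simulate_ou(200000, dt = 0.005, sigma = 32, tau = 0.010, seed = 2)
  ac <- autocorrelation(x, max_lag = 10)
  expect_equal(ac$value[ac$lag == 0], 32^2, tolerance = 0.05)
  expect_equal(ac$value, 32^2 * exp(-ac$lag * 0.005 / 0.010),
               tolerance = 0.06)
  expect_error(autocorrelation(rep(1, 100), 10),
               class = "dnapulley_zero_variance")
  expect_error(autocorrelation(rnorm(10), 10), "length")
})

test_that("exponential ACF fit recovers exact and simulated decays", {
  # exact exponential input: exact parameter recovery
  lags <- 0:40
  dt <- 0.005
  exact <- data.frame(lag = lags, value = 900 * exp(-lags * dt / 0.012))
  fit <- fit_exponential_acf(exact, dt)
  expect_equal(fit$tau, 0.012, tolerance = 1e-6)
  expect_equal(fit$sigma2, 900, tolerance = 1e-6)
  # non-decaying input is a fit failure
  flat <- data.frame(lag = lags, value = rep(1, length(lags)))
  expect_error(fit_exponential_acf(flat, dt), "decay")
  # unbiased over repeated simulation (50 seeds, experimental settings)
  taus <- vapply(1:50, function(s) {
    x <- simulate_ou(12000, dt, sigma = 32, tau = 0.010, seed = 1000 + s)
    fit_exponential_acf(autocorrelation(x, 60), dt)$tau
  }, numeric(1))
  expect_equal(mean(taus), 0.010, tolerance = 0.05)
  expect_true(all(abs(taus - 0.010) / 0.010 < 0.35))
})

test_that("blur correction inverts the exposure-averaging attenuation", {
  # zero exposure is the identity
  expect_identical(blur_correct(1024, 0.010, 0), 1024)
  # large-alpha asymptote: atten -> 2/alpha
  alpha <- 100
  expect_equal(blur_correct(1, 0.010, 0.010 * alpha),
               1 / (2 / alpha), tolerance = 0.02)
  # brute-force oracle: average densely simulated OU paths over the window
  sigma <- 32; tau <- 0.010; w <- 0.005
  m <- 50
  set.seed(9)
  fine <- simulate_ou(2e6, w / m, sigma, tau)
  blurred <- colMeans(matrix(fine, nrow = m))
  atten_mc <- var(blurred) / sigma^2
  atten_formula <- sigma^2 / blur_correct(sigma^2, tau, w)
  expect_equal(atten_mc, atten_formula, tolerance = 0.01)
})

test_that("averaging precision follows sigma sqrt(tau/t)", {
  expect_equal(averaging_precision(32, 0.010, 0.010), 32)
  expect_equal(averaging_precision(32, 0.010, 1), 3.2)
  expect_equal(averaging_precision(32, 0.010, 4) * 2,
               averaging_precision(32, 0.010, 1))
  expect_warning(averaging_precision(32, 0.010, 0.001), "relaxation")
  # cross-check against the standard error of a simulated OU mean: the
  # exact long-window OU result is sigma sqrt(2 tau / t), i.e. sqrt(2)
  # times the sigma sqrt(tau/t) rule of thumb used for the instrument
  sigma <- 10; tau <- 0.02; t_avg <- 1
  means <- vapply(1:200, function(s) {
    mean(simulate_ou(t_avg / 0.002, 0.002, sigma, tau, seed = s))
  }, numeric(1))
  expect_equal(sd(means), sqrt(2) * averaging_precision(sigma, tau, t_avg),
               tolerance = 0.2)
})

test_that("differential two-bead precision divides by sqrt(2)", {
  expect_equal(differential_precision(0.19), 0.19 / sqrt(2))
  expect_identical(differential_precision(0), 0)
  # two simulated beads with independent noise n: pair rms = n sqrt(2)
  set.seed(4)
  n_true <- 0.13
  b1 <- rnorm(50000, sd = n_true); b2 <- rnorm(50000, sd = n_true)
  expect_equal(differential_precision(sd(b1 - b2)), n_true,
               tolerance = 0.02)
})

test_that("calibration round-trip recovers sigma and tau through blur", {
  # simulate -> autocorrelation -> fit -> blur-correct across 20 seeds
  sig_err <- tau_err <- numeric(20)
  for (s in 1:20) {
    tb <- simulate_tethered_bead(60, seed = 200 + s)
    cal <- calibrate_thermal(tb)
    sig_err[s] <- cal$sigma_r / 32 - 1
    tau_err[s] <- cal$tau_r / 0.010 - 1
  }
  expect_true(all(abs(sig_err) < 0.10))
  expect_true(all(abs(tau_err) < 0.20))
  # blur correction matches the generator's exposure averaging: raw
  # variance sits below the corrected one by the analytic factor
  tb <- simulate_tethered_bead(300, seed = 31, drift_nm_per_min = 0,
                               tracking_noise = 0)
  cal <- calibrate_thermal(tb)
  ratio <- (cal$sigma_r_raw / cal$sigma_r)^2
  alpha <- cal$exposure_time / cal$tau_r
  expect_equal(ratio,
               (2 / alpha) * (1 - (1 / alpha) * (1 - exp(-alpha))),
               tolerance = 0.02)
})

test_that("calibrated relaxation time recovers a 1 pN tension end to end", {
  wlc <- lambda_wlc()
  bead <- bead_params()
  # ground truth consistent with 1.0 pN: tau = gamma/k(F), sigma^2 = kBT/k
  k_true <- wlc_stiffness(1.0, wlc)
  tau_true <- bead$drag / k_true
  sigma_true <- sqrt(wlc$thermal_energy / k_true)
  tensions <- vapply(1:5, function(s) {
    tb <- simulate_tethered_bead(60, sigma_r = sigma_true, tau_r = tau_true,
                                 seed = 500 + s)
    calibrated_tension(calibrate_thermal(tb), bead, wlc)$tension
  }, numeric(1))
  expect_true(all(abs(tensions - 1.0) <= 0.25))
})
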