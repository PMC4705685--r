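# dnapulley

Analysis of DNA-pulley nano-mechanical scanning experiments, in which a
magnetically stretched molecule of double-stranded DNA (typically λ phage
DNA) is dragged over a fixed nanoscale knife edge while the tethered
magnetic bead is tracked optically with sub-nanometer precision. Proteins
bound to the DNA cannot pass the knife: the bead pauses, and the pause
positions mapped onto the sequence locate the binding sites while the
pause durations probe bond strength. The package is for single-molecule
biophysicists running (or simulating) such experiments, and for anyone who
wants a tested, end-to-end reference implementation of the analysis.

## What it computes

* **Worm-like-chain mechanics** — the Marko–Siggia force–extension
  relation `F(z) = (kBT/Lp)[1/(4(1−z)²) − 1/4 + z]`, its numerical
  inverse, the stiffness `dF/dx`, and force calibration from the bead's
  thermal relaxation time via `k = γ/τ` with Stokes drag `γ = 6πηa`
  (`wlc_force`, `wlc_extension`, `wlc_stiffness`,
  `tension_from_relaxation`).
* **Thermal calibration** — autocovariance of bead trajectories,
  exponential decay fits, camera exposure-blur correction of an
  Ornstein–Uhlenbeck process
  (`σ²_obs = σ²·(2/α)[1 − (1/α)(1 − e^{−α})]`, `α = exposure/τ`), and
  tracking-precision bookkeeping (`calibrate_thermal`, `blur_correct`,
  `averaging_precision`, `differential_precision`).
* **Pulley geometry** — the scan model `r = l0 − sqrt((P−P0)² + d²)`,
  `w = 0`, its robust Levenberg–Marquardt fit to trajectories, and the
  piezo↔contour mapping in base pairs (`fit_geometry`,
  `map_piezo_to_contour`, `measured_contour`).
* **Protein bumps** — pause detection on the `L_meas − L_pred` residual
  with hysteresis thresholding, clustering and localization in bp/nm,
  IUPAC-aware recognition-site scanning, and bump↔site matching
  (`detect_pauses`, `localize_bumps`, `find_sites`,
  `match_bumps_to_sites`, `detection_rate`).
* **Force-ramp rupture kinetics** — the Evans–Ritchie model with Bell
  rate `k(F) = k0·exp(F·x‡/kBT)` under a linear ramp: closed-form
  survival, exact sampling, and maximum-likelihood fitting with profile
  confidence intervals (`ramp_survival`, `sample_rupture_times`,
  `fit_ramp_model`).
* **Elastica at the blade** — the planar bending boundary-value problem
  `κθ″ = F·sin(θ − θ_F)` for DNA bent over a point blade versus a
  free-pivot kink, by two independent routes (ODE integration and
  discrete energy minimization), and the resolvability map `dr/σ_r`
  (`solve_elastica`, `displacement_delta`, `resolvability_map`).
* **Synthetic data** — a full scan simulator (OU fluctuations, exposure
  blur, drift, tracking noise, planted bumps with force-ramp rupture)
  plus synthetic genomes with planted motifs, each with a JSON truth
  sidecar (`simulate_scan`, `simulate_tethered_bead`, `synth_genome`).

## Worked example

Calibrate a simulated tethered bead, run the pipeline on a simulated scan
with two planted EcoRI-like bumps, and ask the elastica model what a
flexible joint would do to the bead:

```r
library(dnapulley)

wlc  <- wlc_params(contour_length = 16200)   # lambda tether (nm)
bead <- bead_params()                        # 1 um bead in water

tb  <- simulate_tethered_bead(60, seed = 7)  # 60 s at 200 Hz
cal <- calibrate_thermal(tb)
cal
#> Thermal calibration (blur-corrected; raw in parentheses)
#>   sigma_r = 32.0 nm (29.7)   tau_r = 10.54 ms
#>   sigma_w = 89.6 nm (88.4)   tau_w = 60.04 ms
#>   12000 samples at 200 Hz, exposure 5.00 ms

calibrated_tension(cal, bead, wlc, tau_uncertainty = 0.005)
#> Tension: 1.07 pN +/- 0.39 pN  (extension 85.8% of contour)

g <- pulley_geometry(l0 = 13800, d = 2800, P0 = 0, thetaF = pi / 4,
                     origin = c(0, 0), extension_fraction = 0.85)
sites <- c(19000, 33000)                     # planted bump sites (bp)
scan  <- simulate_scan(scan_config(g, bump_sites = sites,
                                   site_occupancy = 1,
                                   scan_start = -2000, scan_span = 14000,
                                   legs = "forward", seed = 60))
reports <- run_pipeline(scan, pipeline_config(), sites = sites,
                        calibration = cal)
reports$matching$assignments
#>    bump_bp site_bp distance_bp
#> 1 18991.85   19000    8.146492
#> 2 32987.53   33000   12.468932

displacement_delta(1, pi / 4)[["dr"]]
#> [1] 2.183444
```

Reading the numbers: the calibration recovers the bead's radial
fluctuations (32 nm, ~10 ms) through the camera blur, which implies
~1 pN of tension stretching the DNA to ~86% of its contour; the two
planted protein bumps are detected and localized on the sequence to
within ~10 bp of their true sites; and replacing the smooth elastic bend
at the blade by a free pivot would move the bead by only ~2.2 nm at 1 pN
and 45° — the scale that makes nick detection marginal against 32 nm
thermal noise.

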