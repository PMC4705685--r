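---
title: "Models and methods behind dnapulley"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnapulley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnapulley)
```

# The measurement this package models

A DNA pulley stretches a single molecule of double-stranded DNA (typically
lambda phage DNA, 48,502 bp, 16.2 µm of contour) horizontally between a
glass capillary and a magnetic bead pulled by a permanent magnet. A
nanofabricated knife edge is brought against the taut molecule, and the
sample is then scanned with a piezo stage so that the knife's contact point
travels along the DNA contour while the bead is tracked optically with
sub-nanometer precision. A protein bound to the DNA cannot slide past the
knife edge: the bead pauses, the tension in the capillary-side segment
changes, and eventually the protein-DNA bond ruptures and the bead snaps
back. The positions of those pauses, mapped onto the sequence, locate the
protein's binding sites; their durations probe the bond's strength.

`dnapulley` implements the full quantitative chain of that experiment:
polymer mechanics, force calibration from thermal fluctuations, the scan
geometry, pause detection and sequence localization, rupture kinetics
under a force ramp, an elastica model of DNA bent at the blade, and a
synthetic-data generator that stands in for the instrument. All lengths
are nanometers, forces piconewtons, times seconds.

# Worm-like-chain mechanics

The tether is modeled as a worm-like chain with the Marko-Siggia
interpolation between the entropic and strong-stretching regimes,

$$F(z) = \frac{k_BT}{L_p}\left[\frac{1}{4(1-z)^2} - \frac14 + z\right],$$

where $z$ is the end-to-end extension as a fraction of the contour length
$L_0$ and $L_p$ the persistence length. `wlc_extension()` inverts this
relation numerically (Brent root-finding on $z$, machine-precision
tolerance; the round trip with `wlc_force()` is tested to $10^{-8}$
relative), and `wlc_stiffness()` evaluates the analytic derivative
$dF/dx$.

Defaults are $L_p = 50$ nm, $k_BT = 4.114$ pN·nm (298 K), solvent
viscosity 1.0 mPa·s and bead radius 0.5 µm. The experiment these values
describe never reports $L_p$ or temperature explicitly; these are the
field-standard dsDNA values, and with them the package reproduces the
canonical tether numbers — a 16.2 µm chain extends to 13.8 µm (85%) at
1 pN — to within the interpolation formula's known few-percent accuracy.
All of them are overridable through `wlc_params()`, `bead_params()` and
the `constants` block of `pipeline_config()`.

Force calibration follows the fluctuation route: the bead's radial
relaxation time obeys $\tau = \gamma/k$ with $\gamma = 6\pi\eta a$ the
Stokes drag (no Faxén wall correction — the capillary mount keeps the
bead far from any surface) and $k$ the WLC stiffness at the operating
tension, so `tension_from_relaxation()` solves $k(F) = \gamma/\tau$ for
$F$; the stiffness is strictly increasing in $F$, so the solution is
unique whenever $\gamma/\tau$ exceeds the zero-force stiffness
$\tfrac32 k_BT/(L_pL_0)$ (below that the tension is reported as
indistinguishable from zero). A $\pm\Delta\tau$ uncertainty is propagated
by symmetric finite differencing — half the spread of
$F(\tau\pm\Delta\tau)$. Because $F \sim k^{2/3}$ in the strong-stretching
regime, a 50% relative uncertainty in $\tau$ produces a roughly 40%
spread in $F$; the interval is markedly asymmetric (the downside
deviation is about half the upside), and the symmetric half-spread is
deliberately the conservative summary of it.

The dipolar magnet argument is the one-liner it should be: for
$F \propto R^{-4}$, a distance excursion $\delta R$ gives a fractional
force change $4\,\delta R/R$ (`magnet_force_variation()`); at the
instrument's $\delta R \approx 10$ µm over $R \approx 1$ mm that is 4%,
small enough that the pipeline holds tension constant along a scan.

# Thermal calibration and camera blur

A tethered bead is an overdamped harmonic fluctuator along each principal
axis, modeled as an Ornstein-Uhlenbeck (OU) process with stationary
standard deviation $\sigma$ and relaxation time $\tau$. The calibration
chain (`calibrate_thermal()`) is:

1. linear detrending of each coordinate (drift in this instrument is
   ~1 nm/min, slow enough that a linear term per recording removes it);
2. principal-axis decomposition of the position covariance — the
   fluctuation ellipse's axes are the radial (stretching) and transverse
   (pendulum) directions, the radial axis identified as the faster one;
3. the biased ($1/N$) autocovariance estimator (`autocorrelation()`,
   lower variance at large lags than the unbiased one);
4. a weighted exponential fit $A e^{-t/\tau}$ over lags $\le 3\tau$,
   iterated once after the first $\tau$ estimate (`fit_exponential_acf()`).
   Lag 0 is excluded: uncorrelated tracking noise and exposure blur both
   distort it, while for lags of a frame or more a boxcar-averaged OU
   process keeps exactly the same decay time;
5. blur correction of the lag-0 variance (`blur_correct()`): averaging an
   OU process over an exposure window $W$ attenuates its variance by
   $\frac{2}{\alpha}\left[1-\frac{1}{\alpha}(1-e^{-\alpha})\right]$,
   $\alpha = W/\tau$. At the default full-frame exposure (5 ms at 200 Hz)
   and $\tau = 10$ ms this is a 15% effect on the variance — ignoring it
   would bias $\sigma_r$ by 8%.

The time-averaged localization precision uses the instrument convention
$\sigma_{\rm meas} = \sigma_{\rm therm}\sqrt{\tau/t}$
(`averaging_precision()`). The exact long-window standard error of an OU
mean is $\sqrt2$ larger; the tests pin down both the convention and that
factor so neither can drift silently. Two-bead differential tracking
rejects common-mode stage noise, and with independent identical noise on
each bead the per-bead precision is the pair r.m.s. over $\sqrt2$
(`differential_precision()`).

# Pulley geometry and its fit

With the blade tip as origin, the radial axis $\hat r$ along the magnetic
force ($\theta_F$ below the camera x-axis, typically near 45°) and the
piezo coordinate $P$ zeroed where the junction-blade line is along x, the
capillary-side stretched length is $q(P) = \sqrt{(P-P_0)^2 + d^2}$ and
the bead's radial coordinate while the DNA ties the blade is

$$r = l_0 - q(P), \qquad w = 0,$$

with $l_0$ the stretched tether length at the calibrated tension and $d$
the blade-capillary distance. Everything here is a stretched (spatial)
length; conversion to sequence coordinates divides by the helical rise
(0.34 nm/bp) times the fractional extension, the convention under which
85 bp at 85% extension span 25 nm.

`fit_geometry()` fits the in-contact model
$\mathrm{bead}(P) = A - q(P)\hat r$ by Levenberg-Marquardt. Two points
deserve emphasis:

* **Identifiability.** The trajectory determines the apex point
  $A = O + l_0\hat r$, $d$, $P_0$ and $\theta_F$ — but not the split of
  $A$ into blade-tip origin $O$ and tether length $l_0$: sliding $O$
  along $\hat r$ while adjusting $l_0$ changes nothing observable, and
  pre-contact data cannot break the tie either (the bead then moves
  rigidly with the stage, carrying no information about $O$). The fit
  therefore requires one of the two from outside: the blade tip position
  (visible in the camera image in practice; available from the truth
  sidecar for synthetic data) or $l_0$ from the WLC calibration.
* **Robustness.** Protein pauses are gross one-sided outliers of the
  free-sliding model, concentrated along $\hat r$. The fit iterates
  trimmed least squares: residuals are projected on the current $(r,w)$
  axes, samples beyond 4 robust standard deviations on either axis are
  set aside, and the fit restarts from its apex/45° initialization so a
  contaminated early pass cannot lock in. Box constraints exclude the
  degenerate branch where $d$ and $P_0$ run away together and $q(P)$
  flattens into a straight line; a solution at a bound is reported as a
  fit failure rather than returned.

Scans whose piezo range embraces the apex measure $l_0$ directly; scans
confined to one flank extrapolate to it and inherit several-fold larger
$l_0$ errors. The package's tests follow the experimental practice of
fitting geometry on protein-free, apex-covering calibration scans
(averaging a few of them) before analyzing protein-laden ones; the
single-scan pipeline tolerates moderate pause contamination but not
wall-to-wall occupancy.

# Pause detection and sequence localization

The detection statistic is the residual between the blade's contour
position measured from the bead, $L_{\rm meas} = (l_0 - r)$ in bp, and
the one predicted from the stage, $L_{\rm pred} = q(P)$ in bp. While the
DNA slides freely the two agree; when the DNA sticks at the blade,
$L_{\rm meas}$ freezes while $L_{\rm pred}$ advances.

A pause is a maximal interval where $|L_{\rm meas} - L_{\rm pred}|$
exceeds `threshold_sigmas` (default 4) times the residual noise scale,
with hysteresis — the interval extends while the residual stays above
half the entry threshold — and a minimum duration of 50 ms (10 frames at
200 Hz). The 4σ default balances the ~110 bp per-frame residual noise
implied by 32 nm radial fluctuations against sensitivity to pauses a few
hundred nanometers in size; it is a declared default, not a value
inferred from any particular dataset. The noise scale should come from
calibration (`sigma_residual`, and `run_pipeline()` wires the calibrated
$\sigma_r$ through automatically); the internal fallback is a
low-quantile estimator (25th percentile of $|$residual$|$, Gaussian
rescaled) chosen because one-sided pause excursions cannot reach it
until they cover three quarters of a scan, where the usual MAD already
breaks at 50%.

Event positions are the median $L_{\rm meas}$ during the pause;
`localize_bumps()` clusters positions by single linkage with a 500 bp
gap, reporting per-cluster means and standard deviations in bp and nm,
and `match_bumps_to_sites()` assigns clusters to recognition sites by
greedy nearest pairs within a tolerance (default 300 bp), at most one
bump per site, leftovers reported unmatched rather than force-assigned.
$\Delta L_{\rm bump}$, the amount the DNA would have slid had it been
free, is $|q(P_{\rm end}) - q(P_{\rm start})|$ across the stuck
interval.

Recognition-site maps come from `find_sites()`: IUPAC-aware scanning
(via Biostrings) reported as 1-based forward-strand positions of the
site's first base. Palindromic motifs such as EcoRI's GAATTC and EcoRV's
GATATC need only the forward strand; non-palindromes are also searched
as their reverse complement. For the palindromic motifs the first-base
convention differs from a midpoint convention by at most 3 bp, far below
the instrument's ~85 nt localization spread. The tests hold the scanner
to an exhaustive sliding-window oracle, exactly.

# Rupture kinetics under a force ramp

A pinned protein at the blade feels the tension of the capillary-blade
segment, whose contour is frozen at the sticking onset while its
end-to-end distance keeps following the piezo (`segment_tension()`).
Moving toward the blade loads the bond; moving away unloads it. With the
Bell rate $k(F) = k_0 e^{F x^\ddagger / k_BT}$ and a locally linear ramp
$F(t) = F_0 + rt$ (clamped at zero), the survival probability has the
closed form

$$S(t) = \exp\!\left[-\frac{k_0 k_BT}{r x^\ddagger}
  \left(e^{F(t)x^\ddagger/k_BT} - e^{F_0 x^\ddagger/k_BT}\right)\right],$$

continued with a constant hazard $k_0$ after a negative ramp reaches
zero force. `ramp_survival()` implements it in an `expm1` form that is
overflow-safe and accurate for small excursions; the tests check it
against direct quadrature of the hazard at $10^{-8}$. Sampling
(`sample_rupture_times()`) is exact inverse-transform through the same
closed form, and `fit_ramp_model()` maximizes the corresponding
likelihood for $(k_0, x^\ddagger)$ with profile-likelihood 95%
intervals; at zero loading rate the model collapses to an exponential,
$k_0 = 1/\bar t$, with $x^\ddagger$ reported non-identifiable. This
hazard ordering is the mechanism behind the experiment's asymmetry:
pauses are briefer when the bead approaches the blade (tension ramping
up) than when it recedes (tension relaxing), and the simulator
reproduces it quantitatively.

The loading rate is frozen at its onset value for the closed form; the
simulator itself integrates the hazard frame by frame with the exact
time-varying tension, so the two agree in the regime where both apply.

# Elastica at the blade versus a free-pivot kink

Could the pulley detect a point of free rotation in the chain — a
single-stranded nick acting as a floppy joint? The observable is the
difference between the bead positions of the smoothly bent chain and the
kinked one at equal contour length.

The smooth shape is a planar elastica: tangent angle
$\kappa\,\theta'' = F\sin(\theta - \theta_F)$ with bending modulus
$\kappa = L_p k_BT$, relaxing to the force direction over the
boundary-layer length $\lambda_e = \sqrt{L_p k_BT/F}$ (14.3 nm at 1 pN).
The geometric closure deserves care, because it decides the answer. The
package's default treats the tangent at the blade as fixed along the
junction-blade line (the capillary-side arm, short and taut, holds it
there), so the magnet-side arm carries one boundary layer of full turn
angle $\theta_F$ at the apex configuration; the capillary-arm direction
is an explicit parameter (`clamp_angle`) for other scan positions. The
kinked reference is a straight line from the blade along the force. The
resulting radial displacement has the closed form
$dr = 2\lambda_e(1 - \cos(\theta_F/2))$ — 2.2 nm at 1 pN and 45°, the
scale that makes the signature marginally resolvable against
$\sigma_r = 32$ nm with realistic averaging. The alternative closure
that splits the turn symmetrically between both arms gives roughly half
that, 1.1 nm; it corresponds to a frictionless point contact with
curvature continuity and is available by setting `clamp_angle` between
the arm directions. The clamped reading is the default because it is the
one consistent with the ~2 nm resolvability scale of the instrument's
own feasibility analysis.

`solve_elastica()` offers two deliberately independent routes — the
boundary-value problem via its decaying first integral
$\theta' = -(2/\lambda_e)\sin((\theta-\theta_F)/2)$ integrated by
fourth-order Runge-Kutta, and direct minimization of the discretized
bending-plus-tension energy over segment angles (L-BFGS-B with analytic
gradient, initialized from a straight ramp, not from the ODE profile) —
and the tests require them to agree on $dr$ within 2% across forces
0.2-5 pN and angles 20-70°. Defaults: arm length $40\lambda_e$ (the
displacement is arm-length independent beyond $20\lambda_e$, enforced),
4000 segments (halving changes $dr$ by under 0.5%).
`resolvability_map()` tabulates $dr$ and $dr/\sigma_r$ over force-angle
grids for contouring.

# The synthetic-data generator

`simulate_scan()` and `simulate_tethered_bead()` produce every input the
analysis consumes, with the statistical structure of the real
measurements:

* OU fluctuations along $\hat r$ and $\hat w$ with defaults
  $\sigma_r = 32$ nm, $\tau_r = 10$ ms, $\sigma_w = 89$ nm,
  $\tau_w = 68$ ms — the measured bead statistics at ~1 pN;
* 200 Hz acquisition with full-frame exposure, implemented by exact OU
  simulation on a fine grid (8 steps per exposure) and boxcar averaging,
  so the blur the calibration corrects for is physically present, not
  painted on via the formula being tested;
* 0.13 nm per-axis tracking noise and ~1 nm/min linear drift with a
  random direction and a per-leg random slope;
* piezo scans at 1 µm/s over 12 µm (14 µm with an apex-covering start in
  the calibration workflow), forward then reverse;
* protein bumps: per crossing of an occupied site (Bernoulli
  `site_occupancy`), the blade-side contour freezes, the segment tension
  evolves by the WLC, and rupture is drawn frame by frame from the Bell
  hazard, with slack release on unloaded reverse pauses and forced
  release at overstretch. The default bond ($k_0 = 0.05\,$s$^{-1}$,
  $x^\ddagger = 2$ nm) describes a stable site-specific complex: ~1 s
  forward pauses, much longer reverse ones — the observed asymmetry —
  while keeping sub-threshold ruptures rare. No kinetic parameters for
  the real enzyme are published to compare against; these are the
  package's declared simulation conditions, not estimates.

Bead dynamics during a scan are quasi-static — OU fluctuations about the
instantaneous geometric position — justified by the scan speed (5 nm per
frame) being small against the fluctuation scales. Every generator
writes a truth sidecar (JSON) sufficient to score every downstream stage
without re-deriving anything, and all outputs are byte-reproducible from
(config, seed).

What the generator does **not** emulate: image-level effects (point
spread, pixelation — tracking noise is additive Gaussian), nonspecific
protein binding (every planted site is specific), rebinding kinetics
between scans (occupancy is an independent draw per crossing), blade
compliance, out-of-plane motion, and the slow non-linear components of
real drift. Green tests therefore demonstrate the analysis is correct
and self-consistent under the stated noise model, not that it is immune
to instrument pathologies outside it.

`synth_genome()` plants motif copies at chosen positions in a uniform
random background and re-randomizes away any spurious occurrence of the
motif or its reverse complement, so the scanner's ground truth is exact
by construction.

# Problem sizes and runtime choices

The test suite simulates at the experiment's own acquisition settings
(12,000-sample calibration recordings at 200 Hz; 12-14 µm scans at
1 µm/s) and sizes its replications — 20 seeds for calibration recovery,
20 scans for detection sensitivity, 100 bump-free scans for the
false-positive rate, $10^5$ samples for the rupture-time KS check — so
the whole suite completes in about a minute while keeping Monte-Carlo
error comfortably inside each asserted tolerance. The false-positive
scans drop the blur oversampling to 2 fine steps per exposure, which
leaves the detector's operating point unchanged.

# Known limitations

* The tension is held constant along a scan; the ≤4% dipolar variation
  across the piezo range is knowingly ignored.
* The blade is an ideal point in the elastica model; a real 55 nm-wide
  edge bends the DNA far more gently, which is the accepted explanation
  for why nicks produce no detectable signature at that blade width.
* `fit_geometry()` on a single heavily-occupied scan can fail or bias;
  fit protein-free scans (or pass `geometry` to `run_pipeline()`).
* The symmetric half-spread force uncertainty is a conservative summary
  of a strongly asymmetric propagation; reporting the two one-sided
  deviations separately (they differ by roughly a factor of two at
  $\Delta\tau/\tau = 0.5$) is the better report when it matters.
* Sequence coordinates assume uniform rise and extension along the
  tether; sequence-dependent elasticity is out of scope.
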