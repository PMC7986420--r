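---
title: "Automated beam-model tuning: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated beam-model tuning: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(beamtune)
```

# The problem

Monte Carlo and analytical dose engines for scanned proton and light-ion
beams need a *beam model*: for every nominal accelerator energy, the mean
energy and energy spread of the beam actually delivered, and for each
transverse plane the width sigma (mm), divergence theta (mrad) and
emittance epsilon (mm mrad) of the phase-space ellipse at a chosen source
plane. Commissioning measurements constrain these parameters indirectly:
laterally integrated depth-dose curves (IDCs) in water constrain the
energy spectrum through the beam range and Bragg-peak width, and spot
sizes in air at several isocenter distances constrain the optics.
`beamtune` turns those measurements into a beam model automatically, by
iterative least-squares tuning, and compiles the per-energy results into
polynomial parameter curves over nominal energy.

# Forward models

The package replaces full Monte Carlo particle transport with two fast
analytic engines that capture exactly the observables the tuning uses.

## Longitudinal: pristine Bragg curve

The range follows the Bragg-Kleeman rule `R = 10 alpha E^p` (mm; protons:
alpha = 0.0022 cm MeV^-p, p = 1.77). The pre-straggling depth dose is the
power law `D0(z) ~ (R - z)^(1/p - 1)`, an integrable singularity at
`z = R`. Range straggling and beam energy spread broaden the peak by
`sigma_R^2 = sigma_strag^2 + (sigma_E dR/dE)^2` with
`sigma_strag = 0.012 R_cm^0.935` (cm); the curve is the Gaussian
convolution of `D0` with `sigma_R`, normalized to peak 1, on a 0.1 mm
grid.

Numerical choices:

* **Singularity sampling.** Each grid sample of `D0` is the exact average
  of the integrand over its bin, computed from the analytic
  antiderivative. Point-sampling with a cap near `R` (the more obvious
  regularization) makes the sampled curve *discontinuous in energy*: as
  `R` sweeps across a grid point, a full-amplitude capped sample pops in
  and out, which we measured as 0.19 mm jumps in R80(E) that create
  spurious optimizer minima. Bin-averaging is continuous in `E`, grid
  stable, and mass conserving.
* **Convolution.** Discrete convolution with a unit-sum Gaussian kernel
  truncated at 6 sigma; the curve is extended internally beyond both grid
  ends so the returned window is free of edge artifacts, and the discrete
  integral of interior curves is preserved exactly.
* The model deliberately omits nuclear build-up and fragmentation tails;
  it reproduces the two observables the method tunes (R80, BPW80) and the
  evaluation-only BPW50, not absolute dose.

## Lateral: moment transport with air scattering

A plane's optics (sigma, theta, epsilon, and the correlation sign, +1
diverging / -1 converging) map to second moments with
`cov = sign sqrt(sigma^2 theta^2 - (epsilon/pi)^2)`; `epsilon = pi sigma
theta` is the upright-ellipse (waist) case. Free drift is the standard
unimodular transfer, conserving the emittance. Air adds Fermi-Eyges
moment contributions `T L^3/3`, `T L^2/2`, `T L` with the Highland
scattering power `T = theta_0^2 / L`,
`theta_0 = (14.1 MeV Z / pv) sqrt(L/X0) (1 + log10(L/X0)/9)`, air
X0 = 304.2 m. Because the Highland log-correction is not additive in
path length, `T` is defined on the full geometry segment and treated as
uniform within it; the test oracles use the same convention but
independent numerics (quadrature, and a 2e6-particle slab-transport
sampler that agrees with the closed form to well under 1%).

Spot FWHM is `2 sqrt(2 ln 2) sigma(z)` for the Gaussian beam; measured
profiles are analyzed by linear interpolation of the half-maximum
crossings (innermost flank crossings), with a log-parabola Gaussian-fit
estimator available as an alternative (`estimator = "gaussfit"`),
emulating vendor spot-analysis software.

# The tuning sequence

Per nominal energy, four one- or three-dimensional least-squares problems
are solved with an in-package Nelder-Mead simplex (coefficients 1, 2,
0.5, 0.5; deterministic tie-breaking; stops: best objective < 1e-5,
simplex parameter spread < 1e-4, or 400 iterations):

1. **Mean energy** minimizes `(R80_meas - R80_sim(E))^2` at fixed spread.
2. **Energy spread** minimizes `(BPW80_meas - BPW80_sim(sigma_E))^2` at
   the tuned energy. Because the distal-80% point of the convolved peak
   shifts weakly with the spread, the pipeline alternates steps 1-2 for
   two rounds so the final pair matches both observables; a single pass
   leaves an R80 residual of order 0.1 mm.
3. **Optics per plane** minimizes the sum of squared FWHM differences
   over all measurement positions, in (sigma, theta, epsilon) with the
   correlation sign held fixed.
4. Energies are processed lowest first; from the second energy on, a
   regularization term couples the candidate to the preceding energy's
   result (below). The lowest energy is tuned unregularized.

Initial guesses are data driven. The spectrum starts from the
Bragg-Kleeman inversion of the measured R80 and 0.5% relative spread.
For the optics we subtract the (optics-independent) scattering variance
from the measured squared beam sizes and fit the free-drift quadratic
`var(z) = var_x + 2 a cov + a^2 var_xp`; this yields source-plane
moments, hence the starting triple *and the correlation sign*. The naive
alternative - reading the sign off the FWHM-versus-position slope - fails
on converging beams whenever scattering growth dominates the slope
within the measurement window; an early version of this package used the
slope rule and its simplex settled in the wrong-sign basin, which is why
it was replaced.

Infeasible simplex candidates (non-positive sigma/theta, epsilon outside
`[0, pi sigma theta]`) are clamped for the data term and penalized by
`1e6 (1 + violation^2)`, keeping the objective finite and pointed back
into the feasible region. When the simplex collapses before the
objective stop is met, the search restarts deterministically around the
best point with steps scaled by 0.2 and then 0.04 - a cheap polish
through the micro-kinks that grid-sampled forward models leave in the
objective.

## Regularization and its unit convention

The optics objective from the second energy upward is
`f_r = sum_i (FWHM_meas,i - FWHM_sim,i)^2 + lambda R`, with
`R = (sigma_j - sigma_{j-1})^2 + (theta_j - theta_{j-1})^2 +
(epsilon_j - epsilon_{j-1})^2` and `lambda = 0.1`. Written this way, `R`
adds quantities in mm^2, mrad^2 and (mm mrad)^2 - the penalty's effect
depends entirely on the numerical scale of the parameters, and lambda
values quoted for one beam line do not transfer to another.

This matters because the emittance direction of the optics problem is
nearly degenerate: with measurement planes spanning a few hundred mm and
a source more than a meter upstream, large correlated changes of (sigma,
theta, epsilon) move the predicted FWHMs very little. The emittance also
*must* change along the energy list (it scales like 1/(beta gamma), a
factor ~2 across a clinical proton range). With the literal convention
and emittances of tens of mm mrad, `lambda (delta epsilon)^2` dwarfs the
flat data term and pins the emittance at its lowest-energy value: we
measured a worst-case 2% FWHM bias at zero measurement noise, i.e. the
regularizer - not the data - was setting the answer.

`beamtune` therefore scales each difference in `R` by the preceding
energy's parameter magnitude, making the penalty a sum of squared
*relative* changes with the same lambda = 0.1. The exported
`regularization_term()` / `regularized_optics_objective()` keep the plain
unscaled arithmetic by default (scale = `c(1, 1, 1)`) and take the
scaling as an argument; only the per-energy sequencing applies the
relative convention. At zero noise the relative penalty leaves the tuned
parameters within a fraction of a percent of truth while still damping
the noise-driven wander of the degenerate emittance direction (the
run-to-run standard deviations of sigma, theta and epsilon drop by
roughly a quarter to a half on the synthetic machine with five noisy
re-optimizations).

Note the *exactness limit* of the pipeline - exact recovery of zero-noise
synthetic measurements - is a property of the unregularized estimator:
any lambda > 0 biases a chained estimator whenever the truth varies
along the chain. The test suite checks exactness with lambda = 0 and the
variance-reduction property with lambda = 0.1 against lambda = 0.

# Model generation

Each of the eight tuned parameter sets (mean energy, spread, and
sigma/theta/epsilon per plane) is fitted by a polynomial in nominal
energy, degrees 4 to 6. Fitting uses the scaled variable
`u = (E - center)/scale` (raw powers of energies up to 253 MeV at degree
6 are numerically ill-conditioned); center and scale are stored in the
JSON model, coefficients lowest order first. Degree selection takes the
lowest candidate whose residual standard error is within 5% of the best
candidate's. The residual is dof-adjusted (`sqrt(SSR/(n - d - 1))`):
the raw RMS always rewards higher degrees and would defeat the
anti-overfit comparison; an absolute floor of `1e-9 max|value|` makes
exactly-interpolated data select the lowest degree. The built model is
validated for physical feasibility (positive widths, epsilon inside the
waist bound) at 50 probe energies and refuses to build otherwise.

Evaluation re-simulates IDCs and lateral profiles from the
model-interpolated parameters at five equally spaced energies (snapped to
measured energies) and reports signed absolute and relative differences
(simulation minus measurement) with avg/min/max/RMS per metric - R80,
BPW50, BPW80 and FWHM - mirroring how commissioning reports are usually
tabulated. BPW50 never enters an objective; it is evaluation-only.

The dose-scaling calibration factor is the mean of pointwise
measured/simulated dose ratios in the spread-out-Bragg-peak region of a
reference plan (zeroing the mean relative difference by construction);
the ratio of means is available as an option. The package consumes paired
dose lists; plan construction and 3-D dose cubes are out of scope.

# The synthetic machine

Because real commissioning datasets are proprietary, the package ships a
generator whose defaults are a stated, fixed world:

* `synchrotron-20`: 20 uniformly spaced proton energies, 62-253 MeV,
  source plane 1300 mm upstream of the isocenter, an all-air path, spot
  planes at -200, -100, 0, +100, +200 mm. `synchrotron-5` is the same
  line with 5 energies (a research-line-sized dataset); `cyclotron-27`
  has 27 energies over 100-226.7 MeV with the source at the nozzle exit
  (500 mm) and planes at 0, +/-100, +/-150 mm.
* Truth curves are low-order polynomials in normalized energy: mean
  energy offset +0.5 to +0.6 MeV, energy spread 0.8-0.9 MeV (a synchrotron-
  scale spread, large enough that BPW80 carries usable information
  against the ~0.4-3.7 mm straggling background), source widths
  8.5 -> 5.3 mm, divergences 5.0 -> 3.2 mrad falling with energy,
  emittance fractions 0.55-0.68 of the waist bound, both planes
  converging (sign -1). This yields isocenter FWHMs of roughly 9-15 mm -
  a wide-spot synchrotron line - with the waist just downstream of the
  isocenter.
* Noise: multiplicative Gaussian noise of 0.5% per IDC dose bin and
  additive Gaussian noise of 0.05 mm per spot FWHM, both seeded and
  reproducible to the byte.

What a green recovery test establishes: that the tuning machinery
inverts its own forward models through realistic noise, file formats and
sequencing. What it does not establish: transferability to real beam
lines, where the forward model is imperfect (nuclear halo, non-Gaussian
spots, detector response). The generator's `model mismatch` of real data
is deliberately not emulated beyond the noise model; with zero noise the
measurements equal the forward model exactly, which the exactness tests
exploit.

A note on the spot-size recovery bound (0.4% mean relative FWHM
difference): with 0.05 mm FWHM noise and ~11 mm mean spot FWHM, the
irreducible noise floor of that statistic is
`E|N(0, 0.05)|/FWHM ~ 0.31%`. The pipeline lands at 0.31-0.42% depending
on the noise seed - the criterion sits essentially at the noise floor of
the stated world, and individual seeds can fall marginally on either
side of it.

# Degenerate inputs and numerical edges

* Curves without a distal falloff, profiles that never cross half
  maximum, or non-monotone depth grids raise extraction/validation errors
  naming the offending feature (and file line, for readers).
* Exact threshold hits and plateaus in the crossing search are handled by
  run grouping (rising crossings at the first plateau sample, falling at
  the last).
* A zero energy spread is a valid boundary (straggling-only peak); the
  spread tuner approaches it through a penalty on negative candidates.
* The waist bound `epsilon = pi sigma theta` is enforced everywhere; the
  model builder rejects polynomial fits that cross it between tuned
  energies.

# Known limitations

* The forward engines are analytic stand-ins: no nuclear interactions,
  no spot halo, no detector response; carbon ions are supported through
  scaled Bragg-Kleeman/straggling constants without a fragmentation
  tail, so absolute peak shapes for ions are approximate.
* The regularization couples energies in one fixed (ascending) order;
  a first-energy outlier propagates into the chain (visible in the
  variance study as inherited offsets).
* Polynomials are fitted per parameter independently; feasibility is
  validated, but correlated parameter errors along the degenerate
  emittance direction are not penalized jointly.
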