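---
title: "Models and methods: electron solvation, attachment and scavenging kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: electron solvation, attachment and scavenging kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasolv)
```

## The kinetic model

The package simulates and analyzes picosecond pulse-radiolysis transient
absorption experiments on excess electrons in a viscous solvent containing a
nucleoside solute. The ionizing pulse creates quasi-free electrons; a
fraction $1 - e^{-C/C_{37}}$ is captured by the solute within the pulse
(concentration $C$, scavenging capacity $C_{37}$), forming an excited anion
radical; the rest enters a linear relaxation cascade:

$$
e^-_{IR} \xrightarrow{\;\tau_1\;} e^-_{vis}
        \xrightarrow{\;\tau_2\;} e^-_{sol}
        \xrightarrow{\;1/\tau_{esol} + k_{attach}C\;} \text{anion (ground)},
\qquad
\text{anion}^{*} \xrightarrow{\;\tau_{TNI}\;} \text{non-absorbing products}.
$$

The five species and their population equations are solved in closed form
(Bateman chain); `simulate_populations()` is validated against independent
ODE integration in the tests. Defaults encode the study conditions:
$\tau_1 = 45$ ps and $\tau_2 = 80$ ps (the two relaxation components in neat
diethylene glycol), $\tau_{TNI} = 350$ ps, $\tau_{esol} = 5\ \mu$s,
$C_{37} = 0.37$ mol/L, a 7 ps FWHM Gaussian instrument response, a dose of
25.3 Gy with linear amplitude scaling, the 370–1100 nm probe grid with the
770–790 nm detector region masked, and additive Gaussian noise of
$5\times10^{-4}$ OD.

Two renderings connect populations to absorbance. *Bilinear* mode is the
exact product of static species bands and populations — the factorization
MCR-ALS assumes. In this representation the hot visible state and the
solvated electron are distinct static bands (750 nm and 630 nm), so the
neat-solvent matrix carries exactly the components
$e^{-t/\tau_1}$, $e^{-t/\tau_2}$ and a quasi-constant solvated-electron
term — which is what a two-exponential global fit plus offset measures.
*Shifting* mode renders the combined visible-electron population as one band
whose center follows $\lambda(t) = 630 + 120\,e^{-t/\tau_2}$ nm, reproducing
the continuous blue shift of the relaxing electron; it deliberately violates
the bilinear model.

### Choices made where the study conditions leave freedom

* **Bands.** Only the 630 nm solvated-electron maximum and the ~750 nm
  initial visible maximum are constrained; the near-IR band (1150 nm center,
  mostly outside the probe window), the excited-anion band (400 nm — a
  mono-peaked band extending into the UV), the ground-anion band (520 nm,
  chosen distinct from both 400 and 630 nm) and all widths are generator
  defaults picked for spectral realism and distinguishability.
* **$C_{37} = 0.37$ mol/L** is the least-squares compromise between the two
  printed capture-fraction anchors, which imply 0.391 M (12% at 0.05 M) and
  0.361 M (75% at 0.5 M) individually and are not exactly consistent with a
  single exponential.
* **$k_{attach} = 5\times10^{7}$ L mol$^{-1}$s$^{-1}$** for the slow
  solvated-electron + solute step. The Smoluchowski diffusion limit in a
  35.7 cP solvent is about $2\times10^{8}$; the relaxed electron reacts well
  below that limit (an activation barrier is the central mechanistic point),
  and the value keeps ground-anion formation negligible on the picosecond
  window (under 1% by 500 ps at 0.3 M) while producing the
  formation-follows-electron-decay behavior on the nanosecond–microsecond
  window.
* **Grids.** The microsecond window is 0.01–20 µs with 200 log-spaced points
  (a log grid cannot start at zero); delays are stored in ps everywhere. The
  canonical three-species deconvolution dataset is 0.3 M, bilinear, with 150
  log-spaced delays from 300 ps (when solvation is complete) to 300 ns, the
  window where exactly the excited anion, ground anion and solvated electron
  carry population.
* **Noise.** $5\times10^{-4}$ OD was chosen so that time-constant recovery at
  the quoted uncertainties (±15 ps and ±30 ps) is achievable but not trivial.

## Global lifetime analysis

`global_fit()` fits
$A(\lambda, t) = c_0(\lambda) + \sum_i \mathrm{DAS}_i(\lambda)\,e^{-t/\tau_i}$,
convolved with the instrument response, by variable projection: conditional
on the time constants all amplitudes are solved by linear least squares, and
only $\log_{10}\tau$ is optimized (bounded quasi-Newton, bounds
$[0.1, 10^7]$ ps, relative tolerance $10^{-10}$, 500 iterations). The log
scale makes conditioning scale-free; a small deterministic multistart over
log-spaced initializations guards against local minima when no starting
values are given. Components are sorted ascending after fitting; negative
(rise) amplitudes are allowed; the offset column is an IRF-broadened step,
representing the solvated electron, which is stable on the picosecond
window. Approximate standard errors come from a finite-difference Hessian of
the profile objective. The tests require agreement with a brute-force joint
fit of all parameters to better than 0.5% in $\tau$.

The basis functions use the same discrete convolution as the generator
(`irf_convolve()`: unit-area Gaussian kernel, edge replication, exact for
constants), so noiseless recovery is exact by construction rather than
accurate to a quadrature error.

## Peak tracking

`track_peak()` locates the band maximum per delay by a quadratic fit to
log-absorbance over the grid points within ±75 nm of the discrete argmax —
the log-parabola estimator, exact for Gaussian bands at any neighborhood
width. A three-point parabola on a 5 nm grid was rejected: for a 300 nm-wide
band the curvature across 10 nm is far below the noise in log-absorbance,
giving ±50 nm position scatter per delay even at peak signal-to-noise; the
windowed fit brings this to a few nm. Delays whose window is masked,
non-positive, or whose maximum sits on the window edge are omitted with a
warning.

The trajectory is summarized by
$\lambda(t) = \lambda_\infty + \Delta e^{-t/\tau_s}$, fit with
amplitude-squared weights (position variance scales inversely with squared
band amplitude). The reported `total_shift` is $-\Delta$, the full amplitude
of the fitted shift: the visible band grows out of the IR state, so its
earliest trackable positions already sit below 750 nm, and a raw
first-to-last difference would systematically underestimate the shift.

## Lifetime estimation

`estimate_lifetime_loglinear()` is ordinary least squares of
$\ln(\text{signal})$ against time inside a window, $\tau = -1/\text{slope}$,
with the half-life $\tau\ln 2$ and $R^2$ reported. Non-positive values
inside the window raise a classed error (they signal baseline
mis-specification) rather than being dropped silently. Microsecond traces
are extracted with ±20 nm detector-pixel averaging (`get_trace()`), without
which single-pixel noise makes late-window points non-positive.

## MCR-ALS

`mcr_als()` alternates non-negative least squares (Lawson–Hanson, per
column) between spectra and concentration profiles, rescaling spectra to
unit maximum each iteration (profiles compensated) to fix the scale
ambiguity. The lack of fit, $100\sqrt{\sum r^2 / \sum y^2}$ over unmasked
cells, must be non-increasing (asserted in tests against a brute-force
active-set enumeration oracle for the half-steps); iteration stops when it
changes by less than $10^{-3}$ percentage points. Rank-deficient steps fall
back to a ridge solve ($\lambda = 10^{-10}\times$ trace) and are counted,
not fatal; non-convergence is flagged, not an error. Closure and
unimodality constraints exist as flags but default off — constraint-free
recovery is the stronger validation. Masked rows are excluded from every
least-squares step and from the lack of fit.

**Initialization.** `initialize_purest_variables()` implements the
SIMPLISMA-style iterative purity selection, picking variables that maximize
`mean/(sd + α)` (α = 5% of the largest mean) weighted by the determinant of
the correlation-around-origin matrix with previously selected variables. It
operates in either direction. On this system no *wavelength* is pure for the
ground anion (its band is buried under the solvated-electron band and its
trace is nearly flat), while quasi-pure *delays* exist for all three late
species — so `mcr_als()` defaults to delay-direction initial spectra. A
non-negativity "needle" refinement then subtracts from each selected
spectrum the largest multiple of the others that keeps it non-negative,
removing, e.g., the solvated-electron background under the early-time anion
spectrum.

**Identifiability.** The ground anion forms exclusively from
solvated-electron decay, so their profiles are exactly complementary and the
bilinear factorization has genuine rotational ambiguity: many non-negative
factorizations reach the noise-floor lack of fit. Consequences, measured on
seeded runs: the free-ALS solvated-electron band maximum is accurate to
roughly ±25 nm across noise realizations, and the excited-anion profile can
carry enough solvated-electron admixture to inflate its apparent lifetime.
For kinetic conclusions the package therefore offers the standard
chemometric remedy, the known-species variant: the solvated-electron
spectrum is *measured* on the neat-solvent microsecond experiment
(`mean_spectrum()`), frozen as one column, and the remaining two species are
resolved freely. With it the excited-anion lifetime is recovered within a
few percent.

## Reference subtraction

In the 720–1000 nm window only the (pre-)solvated electron absorbs, so for
each delay a least-squares scalar matches the neat matrix to the solution
matrix over the chosen window (default 900–1000 nm) and
`solution − scale·neat` isolates the solute species. Two numerical
safeguards matter at realistic noise. First, the raw scalar is
attenuation-biased once the IR signal decays (noise in the neat matrix
inflates the denominator); the denominator is corrected by an estimate of
the noise variance from second differences along the delay axis. Second, the
true scale factor is a smooth ratio of survival kinetics, so the per-delay
estimates are smoothed by loess weighted with the least-squares information
(window sum of squared neat absorbance); both behaviors can be disabled.
Solution and reference are treated as independent measurements with
independent noise — subtracting two matrices sharing one noise realization
biases the late-time scale toward unity and the recovered lifetime low.

## Scavenging analysis

`fit_scavenging()` fits $A(C) = a_0 e^{-C/C_{37}}$ on the log scale with
absorbance weights (linearizing the exponential while approximating
unweighted least squares on the linear scale). "Initial absorbance" is the
mean over the first three delays after $t_0 + \mathrm{FWHM}$; the series
analysis averages over the full electron-only 720–1000 nm window (the anion
bands contribute under 0.4% there), because the narrower 900–1000 nm window
leaves the 0.5 M capture fraction with a standard error comparable to the
effect being tested. `capture_fraction()`, `scavenging_time()` (= $1/kC$,
with $k$ an input constant, not fit) and `yield_curve()` complete the
arithmetic; `normalized_kinetics_compare()` tests shape invariance of the
IR kinetics with a short boxcar smoothing (default 9 delay points) so the
statistic reflects kinetic shape rather than white noise — without it, a
25% concentration-dependent change in $\tau_1$ across the series would be
undetectable at the default noise level.

## What the tests do and do not show

All validation is parameter recovery on synthetic data whose ground truth is
set to the study conditions: sizes used are the full 147 × 261 picosecond
matrices, the 147 × 150 deconvolution matrix, 200-point microsecond traces,
and Monte-Carlo loops of 60–100 seeds on reduced grids. Passing shows the
estimators are unbiased and appropriately precise *under the generator's
assumptions*: exactly exponential kinetics, Gaussian bands, white Gaussian
noise, a strictly linear dose response, and a clean within-pulse branching.
Real accelerator data add baseline drift, wavelength-correlated noise,
solvent heating and spur chemistry that the generator deliberately omits; a
shape mismatch of that kind would appear here only through the shifting-mode
rendering, which is the package's one built-in model violation (and is why
MCR is specified to run on bilinear-mode data).

## Known limitations

* The rotational ambiguity of the three-species factorization is inherent to
  the complementary kinetics, not a solver defect; free-ALS spectra should
  be quoted with the ±25 nm caveat above, or resolved with the known-species
  variant.
* The subtraction route assumes the electron spectrum shape is identical in
  neat and solution matrices at matched delays; mid-relaxation (50–300 ps)
  the solvated-electron decay differs slightly between them, contributing a
  sub-percent residual.
* No rate-distribution (maximum-entropy) analysis, no hard-modelling hybrid
  MCR, no multiset analysis across concentrations, and no
  diffusion-kinetic (spur) modelling of time-dependent rate constants.
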