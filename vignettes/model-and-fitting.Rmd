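---
title: "The spectrum model and the differentiable fitting engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spectrum model and the differentiable fitting engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adxrf)
```

## The problem

An energy-dispersive X-ray fluorescence (XRF) spectrum is a histogram of
photon counts over detector channels. Channel `i` maps to energy through a
quadratic calibration `E_i = offset + slope·i + quad·i²`. On that axis sit
the characteristic emission lines of the elements in the specimen, the
elastically (Rayleigh) and inelastically (Compton) scattered beam, detector
escape peaks, optional pileup sum peaks, and a smooth continuum. Fitting
means choosing per-element amplitudes **A** and instrument parameters **θ**
(calibration, detector resolution, peak-shape, scatter and escape
parameters) so the model reproduces the measured counts.

Classically the instrument parameters are tuned by hand, spectrum by
spectrum. `adxrf` instead expresses the entire model — including the
background estimate — as a differentiable computation graph, so that exact
gradients of the fitting loss with respect to every parameter are available
by reverse-mode automatic differentiation (AD), and a single adaptive
gradient loop can fit everything jointly from rough or even random starting
values.

## The model, term by term

**Lines.** Each element specification ("Fe", "Pt_L", …) expands to the
bundled emission lines of its (element, family) group whose originating
shell's binding energy lies below the incident beam energy — a shell cannot
be ionized by photons below its edge. Line intensities within a group are
normalized branching ratios that sum to 1, so one free amplitude `A_e` per
group equals, to good approximation, the group's total fitted counts. That
convention makes amplitudes directly testable by summation and independent
of the calibration.

**Peak shape.** A line of energy `μ` has Gaussian width
`σ(μ) = sqrt((fwhm_offset/2.3548)² + 0.00358·fwhm_fano·μ)` — the standard
silicon-detector resolution model (electronic noise floor plus
Fano-statistics broadening; 0.00358 keV is the Si electron–hole pair
energy, and `fwhm_fano` absorbs the true Fano factor, since only the
product is identifiable). On top of the area-normalized Gaussian the
Hypermet shape adds two detector artifacts:

* a *step* shelf `step_height·area·slope/(2μ)·erfc(z/√2)` from incomplete
  charge collection — flat below the peak, rolling off above it;
* an exponential low-energy *tail*,
  `tail_fraction·area·slope/(2γσ)·exp(z/γ + 1/2γ²)·erfc(z/√2 + 1/√2γ)`
  with `γ = tail_slope`. This is exactly the density of a Gaussian
  convolved with a one-sided exponential of decay `γσ`, so its integrated
  counts equal `tail_fraction·area` — another convention chosen for
  testability.

Evaluation clips `|z| = |E−μ|/σ` at 30: beyond that both value and
gradient are far below machine-relevant magnitude for the Gaussian and
tail, and only the (analytically constant) step shelf survives, which the
compiled kernel adds in closed form. The tail is evaluated in the stable
form `exp(−z²/2)·erfcx(t)`, which never overflows.

**Scatter.** The Rayleigh peak is a Gaussian at the incident energy. The
Compton peak sits at the Compton-shifted energy
`E0/(1 + (E0/511)(1−cos angle))`, widened by `compton_fwhm_corr`, with its
own step/tail parameters — scattering kinematics and Doppler broadening
make it wider and more asymmetric than fluorescence lines.

**Escape.** Every modeled Gaussian above the Si K edge (1.839 keV) spawns
a satellite at `μ − 1.740` keV with area `escape_fraction·area`. A single
global, optimizable escape fraction is used; scatter-peak escapes are
included by default behind a flag.

**Pileup.** Optional sum peaks at the sum of two partners' strongest line
energies, each with a free amplitude; off unless the element list names
them (e.g. `"Si_Si"`).

## The differentiable SNIP background

The continuum is estimated from the data by SNIP: counts are boxcar
smoothed, compressed by the log-log-square-root transform
`v = ln(ln(√(y+1)+1)+1)`, then repeatedly clipped to
`min(v_i, (v_{i−w} + v_{i+w})/2)` with a half-width `w_i` proportional to
the local FWHM, held for several passes and then decayed geometrically;
finally the transform is inverted. The estimate participates in the
computation graph: the clip is an exact (sub)differentiable min, and the
fractional half-widths read their neighbours by linear interpolation, so
the background carries gradients with respect to the calibration and
resolution parameters. Rounding the widths to whole channels would make
the background piecewise constant in those parameters and silently cut
this gradient path — that is why interpolation, which reduces to exact
indexing at integer widths, was chosen.

Three further choices matter in practice; each was selected by measuring
background fidelity against known synthetic continua:

* **Clipping half-width** `base_width = 2` FWHM units. A window narrower
  than a peak cannot clip it away — the symmetric neighbours still sit on
  the peak's flanks, so the background rides up under every line and the
  fitted amplitudes lose the absorbed area. At two FWHM an isolated
  Gaussian is clipped cleanly (the test suite asserts the background
  under such peaks stays within 15% of the true continuum, and the
  linear amplitude solve at true parameters recovers areas to well under
  half a percent). `initial_reps = 16` full-width passes run before the
  decay schedule, because clipping converges only linearly at the
  off-center channels of a peak.
* **Edge rule.** Channels whose offset neighbours would leave the fit
  range are left unclipped. Clipping against edge-clamped neighbours is a
  one-sided average that is systematically biased low wherever the
  continuum is steep — worst at the low-energy boundary, where the
  resulting background deficit becomes the dominant fit residual on
  weak-peak spectra.
* **Artifact-aware refinement** (`refine_background = TRUE`). The step
  shelves and tails of strong peaks are flat or slowly varying, so a
  clipping estimator happily absorbs them into the background while the
  peak model counts them again, deflating fitted tail fractions and
  inflating Gaussian areas at equilibrium. The embedded background is
  therefore estimated from `observed − (current step and tail
  components)`, recomputed inside the graph at every iteration. The
  standalone estimators (`snip_background()`,
  `snip_background_reference()`) keep the plain spectrum-in contract, and
  the linear solver reaches the same refined background by fixed-point
  iteration so both amplitude routes agree.

## Loss, metric and optimizer

The objective is the plain mean squared error over channels inside the fit
range (default 0.25 keV to incident + 1 keV; channels with non-positive
energy are excluded). Fit quality is reported as the coefficient of
determination `R² = 1 − RSS/TSS`, whose numerator is the MSE times the
number of channels; it is scale-free and so comparable across spectra with
very different count totals. Poisson-weighted objectives are deliberately
out of scope.

Every optimizable scalar is rescaled to the unit interval over its bound
box (amplitudes live on a log10 scale, which enforces positivity without a
projection step), so one learning rate suits parameters whose natural
magnitudes span twelve orders. The optimizer is Adam (β₁ = 0.9,
β₂ = 0.99 — the shorter second-moment horizon tracks the exponentially
shrinking gradients of a converging fit; ε = 1e−8) with base learning
rate 0.02. The loss is evaluated, gradients are obtained by one backward
sweep of the tape, parameters are updated and clamped to their boxes, and
the best (lowest-loss) iterate over the whole run is returned.

The default schedule has two phases, both plain adaptive-gradient
iterations:

1. **Warmup** (first 20%): only the amplitudes and the energy-calibration
   coefficients move, and the loss compares boxcar-smoothed (31-channel)
   observed and model spectra. Randomly initialized amplitudes can be off
   by orders of magnitude and a few-percent calibration error displaces a
   peak by many line widths — far outside its basin of attraction.
   Smoothing widens every basin, and freezing the shape parameters
   prevents the classic failure where the optimizer "explains" one huge
   misplaced peak by inflating the detector resolution.
2. **Joint phase**: all parameters, exact loss, cosine-annealed learning
   rate over `n_restarts = 2` cycles. The restart re-energizes the
   optimizer once, which measurably improves the endgame in shallow,
   nearly degenerate directions (amplitude vs. tail fraction vs.
   background).

The loss-trace entries during warmup are on the smoothed scale;
best-iterate tracking restarts at the phase boundary.

One discreteness detail: the set of channels in the fit window and the
SNIP index range are frozen from the starting calibration. Recomputing
them from the current calibration would make the loss discontinuous in
`offset`/`slope` each time a boundary channel entered or left the window.

## Linear mapping and the pipeline

With **θ** frozen the model is linear in the amplitudes, so per-pixel maps
of a raster scan are obtained by non-negative least squares
(Lawson–Hanson) against a design matrix of unit-amplitude component
spectra, built once per scan. The automated pipeline chains: first-pass
fit of the integrated spectrum (random initialization by default) →
per-pixel linear maps at the fitted parameters → ROI selection (top-k
25×25 tiles by total counts, or user boxes) → nonlinear refinement of each
ROI with bounds tightened to ±10% around the first-pass parameters.
Per-pixel *nonlinear* fitting exists behind the same functions but is not
the default; the linear solve is the right accuracy/cost trade-off for
full maps.

## The synthetic-data generator

Every quantitative claim in the test suite is made against synthetic data
drawn from the forward model itself, so ground truth is known exactly.
`sample_truth()` draws **θ** uniformly within the bound box of
`param_table()` — the same ranges used for random initialization — and
log-uniform amplitudes over 10²–10⁶ counts. The continuum is an
exponential `C·exp(−E/τ)` with `C = 200` counts/channel and `τ = 4` keV, a
smooth, featureless stand-in chosen because real spectra estimate their
background from data rather than from a physical continuum model; typical
realizations put the peak fraction between a few and ~50% of total counts,
which is the regime of real biological maps. Scans modulate each element's
amplitude by a spatial field (Gaussian blobs by default, mean 1) at
desk scale (default 32×32×2048; the tests use smaller cubes down to
6×6×512 so the whole suite runs in minutes). Poisson noise is applied per
channel when requested, and every generated object carries its truth
manifest.

What passing these tests shows — and what it does not: recovery on
self-generated data demonstrates that the gradients are exact, the
optimizer converges, and the background estimator does not systematically
eat peak area. It cannot certify the physical fidelity of the line table,
the absence of self-absorption or matrix effects (out of scope), or
behavior under detector artifacts the model does not describe.

## Numerical choices and degenerate inputs

* Gaussians, steps and tails are fused in one compiled kernel with
  hand-derived adjoints; the AD engine checks it against central finite
  differences in the test suite.
* `erfcx` switches to an asymptotic series above `t = 20` (relative error
  < 1e−9), keeping the tail expression finite everywhere.
* Elements with no excitable line contribute a zero spectrum, not an
  error; their heuristic amplitude floor is 1 count.
* An all-zero spectrum yields all-zero linear amplitudes; a constant
  spectrum makes R² undefined and is rejected with a clear message.
* Non-finite losses abort with the names of the suspect parameters.
* Ties in the SNIP min are resolved toward the unclipped value, matching
  the plain reference implementation channel for channel.

## Known limitations

The amplitude/tail/background split is weakly identified for elements
contributing only ~1% of counts on top of a dominant continuum: the MSE
surface is nearly flat along a direction that trades a few percent of
Gaussian area against the tail fraction and the data-driven background,
so fitted amplitudes of such minor constituents carry a few-percent
uncertainty even on noise-free data. Self-absorption, matrix effects,
Doppler-broadened Compton profiles, detector nonlinearity and
concentration calibration are out of scope. The line energies are bundled
constants from standard tabulations; third-decimal differences between
reference compilations are possible.
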