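---
title: "Quantifying dye extravasation from SPIM time lapses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dye extravasation from SPIM time lapses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spimdiff)
```

# The measurement problem

A fluorescent tracer injected into the vasculature of a zebrafish embryo
leaks out of the vessels and spreads through the surrounding tissue. A
selective-plane-illumination microscope (SPIM) records this as a stack of
frames at a fixed cadence; the mean intensity over a region of interest
(ROI) at a known distance from the vessel is a concentration-versus-time
curve. The quantity of interest is the effective diffusion coefficient
`D` of the tracer in the tissue: permeable, leaky tumour vasculature
changes it by an order of magnitude relative to healthy controls.

# The delayed point-source model

We treat the vessel as a confined source releasing a fixed tracer mass
`B` at injection time into a semi-infinite medium, and solve Fick's
second law in one dimension. Because sample mounting takes minutes, the
recording starts a delay `t0` after injection, so the observation clock
is shifted:

$$C(x, t) = \frac{B}{\sqrt{\pi D (t + t_0)}}
  \exp\!\left(-\frac{x^2}{4 D (t + t_0)}\right).$$

This Gaussian is the simplification of the cylindrically symmetric
problem (whose exact solution is a Bessel-function superposition); the
package implements exactly the Gaussian form, whose properties the tests
verify directly: it satisfies the diffusion PDE, conserves the half-line
mass `B` at every time, and depends on `D` and time only through their
product.

Three analytic companions matter in practice:

* the concentration at fixed `x` peaks at `t + t0 = x^2 / (2D)`; when
  `t0` exceeds this, the recorded trace is monotonically decaying — the
  typical embryo situation;
* the *half time* `tau_1/2`, when the trace falls to half its first
  recorded value, solves
  `log(u/t0)/2 + a/u - a/t0 = log 2` with `u = t + t0`, `a = x^2/(4D)`;
  at `x = 0` it is exactly `3 t0`. `half_time()` brackets the root on
  the decaying branch (`u >= max(t0, 2a)`) and solves it with Brent's
  method to relative tolerance 1e-10; a dense-grid crossing search is
  kept in the test suite as an independent oracle;
* the empirical correction polynomial
  `f(D) = 0.013 D^2 - 0.51 D + 8.14` (dimensionless, `D` in µm²/s,
  calibrated for `1 <= D <= 20` where it is ≈ 4) relates distance, half
  time and diffusivity.

## The f(D) relation and its algebraic reading

The printed wavefront relation is ambiguous between
`R0^2 = 4 D tau / f(D)` and `R0^2 = 4 D tau f(D)`. We adopt the
*quotient* reading as the default in `solve_Dv()` because it reproduces
the right order of magnitude for physiological parameters (`R0 = 70` µm,
`tau = 700` s gives `Dv ≈ 8.4` µm²/s, versus ≈ 0.2 under the product
reading, two orders below any fitted value); the product reading remains
available behind the `reading` argument. Note `D/f(D)` increases only up
to `D = sqrt(c0/c2) ≈ 25` µm²/s, so the root search is confined to that
increasing branch.

# The two estimators

## Global shared-D fit

All ROI traces are fitted simultaneously to the model with one shared
`D` and a free per-trace amplitude `B_i` (optionally a per-trace
baseline); distances are fixed geometry, never fitted. The amplitudes
enter linearly and are profiled out, reducing the optimization to a 1-D
search over `log10 D` (2-D with `t0` free), run over five log-spaced
sub-intervals of the `D` bounds to guard against local minima; standard
errors come from the Jacobian of the stacked residual vector at the
optimum. Traces are Savitzky–Golay smoothed first (window 11 frames,
order 3 by default — the cadence is 5 s, so the window spans 55 s, short
against the hundreds-of-seconds decay times; both configurable), with
endpoints handled by off-center evaluation of the full first/last
window, not by reflection padding.

`t0` is *fixed* by default at the known experimental delay: the fit's
time shape at the small ROI distances used in embryos is dominated by
the `1/sqrt(t + t0)` prefactor, so `D` and `t0` trade off strongly.
Misspecifying `t0` corrupts `D` asymmetrically: fixing it below truth
biases `D` low, fixing it above truth inflates `D` until it hits the
search bound (the result is then flagged, never returned silently).
This sensitivity is why the half-time analysis below doubles as an
independent check on `t0`.

## Half-time wavefront analysis

`measure_half_time()` finds the first linear-interpolated crossing of
half the initial value. "Initial value" defaults to the first recorded
frame; a config switch uses the early-window maximum instead for traces
that still rise after recording starts (far agarose ROIs). ROIs whose
traces never halve within the record carry no half-time information and
are dropped from the trend with a warning — this censoring is not a
nuisance but part of the measurement model: for slow (xenograft-like)
diffusion only the near ROIs yield half times inside a one-hour record,
and the delay-matching below operates on exactly those observable
points.

`build_trend()` fits the ordinary-least-squares line
`tau_1/2 = slope * R0 + intercept`. The relation is linear but not
proportional: the intercept approximates `3 t0`. The wavefront speed is
`v = 1/slope` (per-point ratios `R0/tau` are also reported, since the
printed speed convention is ambiguous), and the corrected diffusion
estimate is `Dv = solve_Dv(v * tau_ref, tau_ref)` at a reference half
time of 700 s, a value in the middle of the observed control-embryo half
times. On noise-free control data this gives `Dv ≈ 12.9` against the
fitted `D = 12`, comfortably inside the factor-2 agreement the method
claims.

`estimate_t0()` compares measured half-time points against
`simulate_trend()` curves over a candidate grid (defaults
`D ∈ {4, 10}` µm²/s, `t0 ∈ {300, 450, 600, 1200, 1800}` s) by sum of
squared errors at the measured distances, ties broken toward smaller
`t0`. Because the same `half_time()` operator generates the candidate
curves and (through the model) the data, the matching is
self-consistent. On noise-free synthetic data it returns 600 s for the
xenograft condition and 300 s (the grid point nearest the true 320 s)
for controls.

# The synthetic generator

`make_preset()` encodes the three experimental regimes as named presets:

| preset | D (µm²/s) | t0 (s) | ROIs (µm) |
|---|---|---|---|
| `agarose_1pct` / `_2pct` / `_5pct` | 18.1 / 8.9 / 2.6 | 0 | 30–200, step 10 |
| `control_embryo` | 12 | 320 | 10–40, step 5 |
| `xenograft_embryo` | 1.0 | 600 | 10–40, step 5 |
| `xenograft_variant_a` / `_b` | 1.9 / 0.82 | 600 | 10–40, step 5 |

All presets acquire 720 frames every 5 s (one hour of recording; the
agarose acquisitions are described as "more than 700 frames" and the
embryo cadence is taken as the same 5 s). For `t0 = 0` presets the model
is singular at the injection instant, so the first recorded frame is
placed one cadence (5 s) after injection — which is also when a camera
could first have completed a frame.

Noise is additive Gaussian read noise plus a signal-proportional
variance term (`sd = sqrt(read_sigma^2 + shot_scale * signal)`,
defaults 2 and 0.05), seeded and bit-reproducible. The default source
amplitude is chosen so the first recorded frame at the source is about
1000 a.u., giving traces with the high signal-to-noise ratio of a
typical dye-channel acquisition; an amplitude of order ten against read
noise 2 would make the shared-D fit ill-conditioned at embryo ROI
distances, where the exponential term varies weakly. An optional
pressure ramp adds the early linear rise seen near the injection site
(rate × time, saturating after ~10 s, confined within ~10 µm); it is off
by default and is only ever simulated, never fitted — early frames can
be masked out of the fit instead.

`render_stack()` rasterizes the model over per-pixel Euclidean distance
from a point or segment source (default pitch 1.375 µm/px, the 880 µm
field of view over 640 binned pixels) and pairs it with a static vessel
channel; annular-band ROIs extracted from a noise-free render match the
trace generator to well under 2%. `rebin()` implements hardware-style
sum binning with floor division (a 2560×1920 frame binned 4× becomes
640×480; one published caption states 640×512, which floor division
cannot produce — we keep exact semantics). What the generator does *not*
emulate: vascular network morphology, photobleaching, embryo motion, or
flow; passing tests demonstrate correct recovery of the model's own
parameters under the stated noise, not robustness to those real-data
effects.

# Optics quality control

`sheet_thickness()` fits every row of a mirror calibration image to a
Gaussian plus constant offset and reports the FWHM
(`2 sqrt(2 ln 2) sigma`, converted to µm) as mean ± sd over accepted
rows; rows failing the fit or an amplitude-to-residual SNR gate are
excluded and counted. `psf_from_beads()` detects local maxima, gates
singleton beads by integrated spot intensity (within ±40% of the
median, which removes overlapping doublets at twice the median), then
radially dissects each spot about its intensity centroid and fits the
radial profile to a Gaussian with the center pinned at radius zero —
letting the center float on a folded radial profile systematically
shrinks the width. Bead-size deconvolution is not applied: for 1 µm
beads against a ~3 µm PSF the broadening bias is below a few percent.
The Rayleigh range implied by a 7.8 µm FWHM waist under the standard
Gaussian-beam convention (`z_R = pi w0^2 / lambda`, `w0 = FWHM /
sqrt(2 ln 2)`) is ≈ 280 µm at 488 nm; instruments are sometimes quoted
with other conventions, so the package reports only the FWHM itself.

# Numerical choices and degenerate inputs

* Root finding (`half_time`, `solve_Dv`) uses bracketed Brent iteration;
  brackets are grown geometrically and failure to bracket is an error,
  never an extrapolation.
* The profiled fit objective returns a large finite penalty where the
  model underflows (very small candidate `D` at large distance) so that
  bounded optimizers can traverse those regions; a fit that terminates
  at a `D` or `t0` bound is flagged in the result and by a warning.
* Distances are band-center to source in µm (0-based pixel coordinates,
  origin at the top-left pixel center); ROI aggregation uses the mean so
  traces are amplitude-comparable across ROI sizes; background
  correction is available but off by default.
* TIFF stacks are written as 32-bit-float pages normalized to [0, 1]
  with the intensity scale in a sidecar JSON, round-tripping to ~1e-10
  relative.
* Singular inputs error early with informative messages: evaluation at
  `t + t0 = 0`, half times at `t0 = 0`, empty ROI bands, ragged TIFF
  pages, constant traces without a half-value crossing.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the preset sizes (7–18 ROIs × 720 frames per fit; 64-line sheet and
100-bead calibration images; 20 noisy replicates for the recovery
statistics; 200 replicates for the noise-law check on a reduced 12-frame,
2-ROI preset). A full simulate → analyze round trip per preset completes
in seconds on one CPU.

# Known limitations

* The 1-D Gaussian is an approximation to the cylindrical geometry; the
  Bessel-superposition solution is out of scope by design.
* `estimate_t0()` is a discrete grid match, not a continuous maximum
  likelihood estimate; its resolution is the grid spacing.
* With per-trace free amplitudes, `D` and a badly misspecified fixed
  `t0` cannot be disentangled at small ROI distances (see above); use
  `t0_s = "free"` or the half-time check when the delay is uncertain.
* The wavefront `Dv` depends on the reference half time through the
  nonlinearity of `f(D)`; it is a consistency check on the fit, not a
  replacement for it.
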