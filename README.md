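# spimdiff

Quantification of vascular permeability from light-sheet (SPIM) time-lapse
imaging.

In a dye-extravasation assay, a fluorescent tracer (e.g. 2 MDa
rhodamine-labelled dextran) is injected into the blood flow of a zebrafish
embryo and its leakage out of the subintestinal vein (SIV) plexus is
recorded as a time-lapse image stack. How fast the tracer spreads through
the surrounding tissue — its effective diffusion coefficient `D` — is a
readout of vessel permeability: tumour-xenografted embryos show effective
diffusivities more than tenfold below healthy controls. `spimdiff`
implements the full analysis for this kind of experiment, for microscopists
and image analysts who have a stack of frames and a set of regions of
interest (ROIs) at known distances from the vessel.

## The model

Tracer spreading is modelled as Fickian diffusion of a fixed mass released
at a confined source into a semi-infinite medium. With recording starting a
delay `t0` after injection, the concentration at distance `x` and
observation time `t` is the delayed point-source Gaussian

    C(x, t) = B / sqrt(pi D (t + t0)) * exp( -x^2 / (4 D (t + t0)) )

where `B` is the released mass (the half-line integral of `C` at every
time). Two independent estimators are built on it:

1. **Global fit** — mean-intensity traces extracted at graded distances
   `R0_i` are Savitzky–Golay smoothed and fitted simultaneously to
   `C(R0_i, t)`, with `D` shared across all traces and one free amplitude
   `B_i` per trace (`fit_global()`).
2. **Half-time wavefront analysis** — the time `tau_1/2` at which each
   trace halves its initial value grows linearly with distance; the
   inverse slope is a wavefront speed `v`, and the relation
   `R0^2 = 4 D tau_1/2 / f(D)`, with the empirical correction polynomial
   `f(D) = 0.013 D^2 - 0.51 D + 8.14` (≈ 4 for `1 ≤ D ≤ 20` µm²/s), gives
   a second, fit-free diffusion estimate `Dv` (`build_trend()`).
   Matching the measured `tau_1/2(R0)` points against simulated curves
   over a `(D, t0)` grid also estimates the injection-to-observation
   delay (`estimate_t0()`).

The package also ships a synthetic generator (`make_preset()`,
`simulate_traces()`, `render_stack()`) reproducing the assay's three
experimental regimes — agarose point-injection calibrations, control
embryos, and tumour xenografts — plus optics quality control:
light-sheet thickness from a mirror image (`sheet_thickness()`) and
lateral PSF from a bead field (`psf_from_beads()`).

## Worked example

Simulate a control-embryo acquisition (D = 12 µm²/s, t0 = 320 s, seven
ROIs 10–40 µm from the SIV, 720 frames every 5 s, camera noise) and run
both analyses:

```r
library(spimdiff)

preset <- make_preset("control_embryo")
traces <- simulate_traces(preset)                      # noisy traces
smoothed <- lapply(traces, smooth_trace, cfg = fit_config())

fit <- fit_global(smoothed, fit_config(t0_s = preset$t0))
print(fit)
trend <- build_trend(smoothed)
print(trend)
estimate_t0(trend)$t0_hat
```

```
Global diffusion fit over 7 traces (5040 points)
  D_hat = 11.84 +/- 0.057 um^2/s
  t0 (fixed) = 320 s
  RSS = 2.62e+04, median per-trace R^2 = 0.9998
Half-time trend over 7 ROIs (0 dropped)
  tau_1/2 = 7.756 * R0 + 865.1 s (SEs 1.1, 30)
  v_hat = 0.1289 um/s, Dv_hat = 11.57 um^2/s (tau_ref = 700 s)
[1] 300
```

The global fit recovers the generating diffusivity (11.84 ± 0.06 vs the
true 12 µm²/s, on this noise realization). The half-time trend is linear
with intercept ≈ 3·t0 (865 s vs 960 s analytic; the finite ROI range
biases it slightly low), the wavefront speed is ≈ 0.13 µm/s, and the
independent `Dv` estimate (11.6 µm²/s) agrees with the fit. Grid matching
of the trend returns 300 s, the candidate delay nearest the true 320 s.

The same pipeline runs from a shell via the thin CLI:

```sh
Rscript inst/cli/spimdiff.R analyze --preset control_embryo \
    --output out/ --t0 320
```

or on a real stack with `--input stack.tif --roi <src_x>,<src_y>,<start>,<stop>,<step>`.

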