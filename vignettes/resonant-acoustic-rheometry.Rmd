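---
title: "Resonant acoustic rheometry: models, signal chain and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonant acoustic rheometry: models, signal chain and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheowave)
```

## The measurement

Resonant acoustic rheometry (RAR) monitors the viscoelasticity of a small
liquid or gelling sample — typically ~100 µl of plasma in a 96-well
microplate well — without touching it. A focused ultrasound tone burst
("push") applies acoustic radiation force to the sample surface; the
surface then rings down as a resonant standing surface wave whose
frequency and damping encode the sample's mechanical state. The same
transducer, switched to pulse-echo mode, tracks the ringing surface at a
high pulse repetition frequency (PRF): each detection pulse returns an
A-line whose sample-surface echo shifts in arrival time as the surface
moves. Repeating the whole push-and-track measurement every few seconds
turns clot formation into a movie of surface-wave snapshots.

Two time axes matter throughout the package:

* **fast time** `tau` — time after one push, sampled at the PRF
  (`1/prf = 0.1` ms at the defaults); it resolves the surface oscillation
  within one measurement;
* **observation time** `T` — elapsed coagulation time; measurements repeat
  every `measurementInterval` (6 s default).

The tracked displacement forms the two-time field `S(T, tau)` held in a
`DisplacementMatrix`.

## Dispersion model

The resonant wavenumber is fixed by the well geometry, `k = z / a`, with
`a` the well radius (3.25 mm for a 96-well plate) and `z` the resonant
mode constant. The package defaults to `z = 3.8317`, the first nonzero
root of the Bessel function J1, i.e. the fundamental axisymmetric mode
with a free-slip wall; the boundary condition of the physical contact
line is not settled, so `z` is an explicit, swappable parameter of
`wellGeometry()` rather than a hidden constant.

While the sample is liquid the restoring force is surface tension and the
surface wave is capillary:

$$f_{CW} = \frac{1}{2\pi}\sqrt{\frac{\sigma k^3}{\rho}},$$

so a water-like surface (σ = 72 mN/m, ρ = 1000 kg/m³) resonates near
54.7 Hz in this geometry. Once the sample has gelled the wave is a
Rayleigh wave on a soft elastic solid:

$$f_{RW} = \frac{1}{2\pi}\sqrt{\frac{G k^2}{\rho}},$$

about 187.6 Hz for a 1 kPa clot. Both relations invert algebraically
(`invertToSurfaceTension()`, `invertToShearModulus()`); the caller picks
the regime — liquid before clotting starts, solid after it ends. The
visco-elasto-capillary crossover in between has no closed form here and
is deliberately out of scope, as is extracting viscosity from the peak
width.

```{r dispersion}
k <- wavenumber(wellGeometry())
capillaryFrequency(0.072, 1000, k)
rayleighFrequency(1000, 1000, k)
```

## What the simulator emulates

`simulateRun()` generates the full acquisition: per measurement, 20
baseline detection pulses, one 100-cycle push (20 µs at 5 MHz), then 500
detection pulses at 10 kHz; measurements every 6 s on up to 4 synchronised
channels. Each A-line carries two fixed well-plate interface echoes and
the air–sample surface echo — the strongest one, since the air interface
reflects almost totally — modelled as Gaussian-windowed tone bursts with
60 % (−6 dB) fractional bandwidth. Surface motion enters *exactly* as a
round-trip delay `2·displacement/soundSpeed` of the surface echo, so the
programmed displacement is the ground truth for the tracker by
construction. Per-pulse multiplicative amplitude jitter (±5 %) emulates
transmit-amplitude variation — the reason the reference echo is averaged
over the baseline pulses — and white Gaussian noise is added at a
configurable SNR relative to the surface echo (30 dB default).

The surface rings down as a damped harmonic oscillator,
`S = A(T)·exp(−tau/tau_d(T))·sin(2π f(T) tau)`, with `f`, `A` and `tau_d`
interpolating between liquid and clotted values along a
`CoagulationTrajectory`. The default transition is a logistic sigmoid
(midpoint `(tStart+tEnd)/2`, width `(tEnd−tStart)/8`) rescaled to meet its
plateaus exactly; a piecewise-linear alternative gives analytically
trivial truth. Default magnitudes — 20 µm / 20 ms in the liquid state,
2 µm / 2 ms once clotted, liquid frequency from σ = 72 mN/m and clotted
frequency from G = 1 kPa — reproduce the canonical staging of a clotting
plasma sample: a lag phase with large, long-ringing oscillations, a rapid
transition in which amplitude and ring-down collapse while the frequency
rises, and a stable clotted plateau. The digitiser rate defaults to
100 MHz (20 samples per carrier cycle) for comfortable sub-sample
interpolation.

What the simulator does **not** model: diffraction and full wave
propagation, bulk speckle, nonlinear propagation, radiation-force
magnitude (amplitudes are programmed, not derived from pressure), streaming
or temperature effects, and any instrument drift beyond per-pulse jitter.
Passing tests therefore demonstrate that the *signal chain* recovers what
the physics model encodes — not that a real transducer achieves these
SNRs, nor that real plasma follows a sigmoid.

## Echo tracking

`trackMeasurement()` proceeds per measurement:

1. **Reference**: pointwise mean of the baseline A-lines. Averaging
   suppresses jitter and noise; normalised correlation removes the
   remaining common amplitude factor.
2. **Gating**: the surface echo is located as the envelope maximum of the
   reference (moving-RMS envelope over one carrier cycle) and the
   correlation is restricted to ±3 pulse lengths around it. Gating keeps
   the plate echoes, which do not move, out of the estimate.
3. **Delay estimation**: normalised cross-correlation against every
   integer lag within ±0.5 µs (±50 samples; generous against the ±µm
   motion expected), then a 3-point parabolic fit of the correlation peak
   for the sub-sample part. Peaks below 0.5 flag the sample
   low-confidence; the value is kept, the flag travels with it.
4. **Conversion**: `displacement = soundSpeed · delay / 2`, positive away
   from the transducer.

Each echo is always compared to the *equilibrium* reference, never to the
previous echo, so errors do not accumulate along fast time. The inner lag
scan is compiled code; the test suite checks it lag-for-lag against a
plain-R brute-force scan.

At 100 MHz sampling the parabolic interpolator's worst-case bias is
~0.002 samples (≈0.014 µm) on the Gaussian-windowed 5 MHz echo — measured
by scanning programmed fractional shifts — which is why the noise-free
tracking budget of 0.05 µm RMS holds without further refinement. Coarser
sampling rates (the unit tests run much of their coverage at 20 MHz for
speed) raise this bias to ~0.1 µm; it cancels in difference-based checks
but is visible against absolute truth.

## Spectral analysis

Each displacement trace is mean-subtracted, zero-padded to four times its
length (next power of two; 2048 bins for 500 samples), transformed with a
plain FFT and normalised to unit maximum. No taper is applied by default:
the ring-down decays naturally inside the window, and tapering would only
broaden the peak. The resonant frequency is the global maximum inside a
search band of 10 Hz (rejecting residual DC leakage) to 80 % of the
fast-time Nyquist, refined by a 3-point parabolic fit on log power; ties
resolve deterministically to the lower frequency. The −3 dB width is the
half-power span around the peak, linearly interpolated. Spectrogram
columns are normalised per observation time — matching the display
convention of coagulation spectrograms, where the post-clot power is
orders of magnitude below the liquid phase — and all-zero or missing
traces propagate as flagged degenerate columns, never as errors.

## Coagulation parameters

From the resonant-frequency trace `f(T)`:

* `f_int`: mean over the first minute `[T0, T0 + 60 s]`;
* `f_end`: mean over the last five minutes `[T_last − 300 s, T_last]`;
* `T_int`: first observation time with `f ≥ 1.05 · f_int`;
* `T_end`: first observation time with `f ≥ 0.95 · f_end`;
* clotting duration `= T_end − T_int`.

Both windows are closed intervals on observation time; endpoints to
sample precision are a convention, made explicit here. Threshold
crossings must persist for two consecutive valid samples, so a single
noisy spectral estimate cannot trigger them; `NA` samples are skipped,
never treated as crossings. A 3-point median filter (default on, and
applied before both the averages and the thresholds) removes isolated
outliers. Samples whose total rise is below 5 % (`f_end < 1.05 f_int`)
are flagged `no_clot` instead of reporting a degenerate near-zero
duration; short traces are flagged `truncated` and evaluated
best-effort. In the rare near-degenerate geometry where the 95 % level
sits below the 105 % level, `T_end` is clamped to `T_int` so the ordering
invariant holds.

## Estimator validity and the choice of validation scenarios

The spectral argmax is only a faithful frequency estimator when the
resonance is spectrally resolved. For a one-sided damped sinusoid the
magnitude spectrum is a Lorentzian of half-width `1/(2π tau_d)` skewed by
its negative-frequency mirror; the relevant dimensionless number is the
quality factor `Q = π f tau_d`. Numerical evaluation of the noiseless
spectra shows the argmax sits ~1 % low at `Q ≈ 3–4` but ~5 % low at
`Q ≈ 1.2` — and under measurement noise the argmax of a near-flat
spectrum wanders across the whole peak. Because the clotting thresholds
are *relative* (1.05 f_int, 0.95 f_end), a bias that is uniform across
the run cancels; what breaks parameter recovery is a *Q mismatch*
between regimes.

The default liquid state has `Q = π · 54.7 · 0.02 ≈ 3.4`. The default
clotted state (187.6 Hz, 2 ms) has `Q ≈ 1.2` — physically a nearly
critically damped surface, on which *any* peak-picking estimator is
ill-posed. The validation studies therefore model stiff clots inside the
estimator's validity regime: G = 2 kPa (265 Hz) with a 5 ms ring-down
(`Q ≈ 4.2`) for the randomized parameter-recovery study, and
G = 2–16 kPa for the multichannel staging study, where the analytic
ratio error of the recovered `f_end` against the `sqrt(G)` law is below
0.9 %. The generator defaults are left untouched; the low-Q bias is a
documented limitation of spectral peak tracking on heavily damped
resonances, not something the package attempts to hide.

Problem sizes used by the validation suite: full-scale measurements
(520 pulses × ~800 samples at 100 MHz) throughout; 20 seeded 15-minute
single-channel runs (151 measurements each) for parameter recovery; one
720 s four-channel run for staging; 1000 log-spaced points per material
axis for the dispersion round trip. Unit tests use a compact 20 MHz /
64-pulse configuration where only relative behaviour matters.

## Numerical conventions and degenerate inputs

* Fast-time grid: `tau_n = n/prf`, `n = 0 …` — the first detection pulse
  is at `tau = 0`, where the programmed displacement is exactly zero.
* Sign convention: positive displacement = surface receding from the
  transducer = later echo.
* Lag-scan edges: if the correlation maximum lands on the scan boundary
  the parabolic refinement is skipped (the integer lag is reported).
* Parabolic refinements are skipped whenever the local curvature is not
  concave or a neighbouring power is zero (log undefined).
* All-zero traces, missing measurements and failed trackings propagate as
  flags (`degenerate`, `gap`, `low_confidence`) — the pipeline never
  silently interpolates and never aborts a run for one bad measurement.
* Seeds: a run is reproduced bit-identically by `(config, trajectories,
  seed)`; jitter is always drawn before noise within a measurement.

## Known limitations

* The intermediate visco-elasto-capillary regime is not modelled; between
  `T_int` and `T_end` the frequency trace is treated as an empirical
  curve, not inverted to material properties.
* Spectral peak tracking degrades for `Q ≲ 2` (see above); equivalently,
  `f_end` from a very soft clot (~sub-kPa with millisecond ring-down)
  carries a low bias of several percent.
* The simulator's noise is white and per-sample; correlated clutter,
  reverberation and wall-motion artefacts of real wells are not
  represented, so real-data tracking floors will be higher than the
  simulated 0.23 µm at 30 dB.
* Group-level statistics across samples (e.g. regression of clotting
  times on anticoagulation level) are intentionally out of scope; the
  package stops at the per-channel parameter table.
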