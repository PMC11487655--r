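---
title: "Simulating SNSPD-array two-photon microscopy: models, calibrations and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SNSPD-array two-photon microscopy: models, calibrations and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snspdsim)
```

`snspdsim` is a forward model of a deep-tissue two-photon microscope whose
detector is a 6×6 superconducting-nanowire single-photon detector (SNSPD)
array with dual readout — analog channel summation and FPGA-gated digital
photon counting. This vignette is the package's account of the science it
implements: the models and their assumptions, the parameters that matter,
what the synthetic data do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## The signal model

The expected number of signal photons emitted from the focus per laser pulse
is

$$S(z) = B \cdot C(\mathbf{r}_f) \cdot \left(\frac{E_s}{E_{\mathrm{ref}}}\right)^2
         e^{-2z/l_{ex}} \, e^{-z/l_{em}},$$

with $B$ the brightness scale (photons per pulse at the surface for unit dye
concentration at the reference pulse energy), $C$ the local dye
concentration, $E_s$ the pulse energy at the tissue surface, and $l_{ex}$,
$l_{em}$ the effective attenuation lengths of excitation and emission light.
The square law is the defining property of two-photon excitation; the factor
$e^{-2z/l_{ex}}$ is the squared one-way attenuation of the excitation and
$e^{-z/l_{em}}$ the attenuation of the fluorescence on its way out.

Two assumptions are deliberate simplifications. Axial sectioning is treated
as ideal: the focus excites a single z-plane, laterally blurred by a Gaussian
excitation spot (`focal_spot_fwhm_um`, default 1 µm, a typical two-photon
lateral FWHM for a high-NA objective at long excitation wavelengths). And the
out-of-focus background is not computed as a volume integral over the
excitation cone — no formula for it is available at this level of abstraction
— but modelled as a single-coefficient term,

$$ B_g(z) = c_{bg} \cdot \bar{C}_{\mathrm{shallow}} \cdot (E_s/E_{\mathrm{ref}})^2, $$

proportional to the mean dye concentration in the shallow tissue (the top
half attenuation length, where out-of-focus excitation is strongest) and to
the squared surface energy. The coefficient $c_{bg}$ is calibrated per
experiment (below) and recorded in every report.

### Power scheduling

The surface pulse energy is raised as $e^{z/l_{ex}}$ with focus depth so that
the pulse energy *at the focus* stays at its configured value (default 2 nJ,
the photodamage guideline), capped by the average-power limit
(100 mW at 1 MHz → 100 nJ per pulse). Beyond the cap the focal energy — and
with it the signal, quadratically — rolls off; `surface_pulse_energy()` warns
when the cap engages. Under this schedule the focal signal decays only as
$e^{-z/l_{em}}$ while the background grows as $e^{2z/l_{ex}}$, which is what
makes the SBR fall with depth.

### Attenuation-length defaults

$l_{ex} = 365$ µm (cortex at ~1700 nm) and $l_{em} = 270$ µm (cortex at
~1100 nm emission) are literature-typical values for mouse neocortex, chosen
once as defaults. They are free parameters of the model, not measured ground
truth, and everything downstream (most visibly the depth limit) scales with
them.

## The detector model

Each pixel detects photons as a thinned Poisson process: with $\lambda$
photons expected on a pixel in one pulse and total efficiency $\eta$, the
detected count is Poisson($\eta\lambda$) and the pixel reports a *binary*
hit when the count is at least one — the per-pulse saturating response of a
counting channel. The efficiency chain factorises as window transmission
(0.935) × lens transmission (0.99) × detector efficiency, the latter a
sigmoidal function of bias current: an error-function rise reaching 99% of
the plateau value (0.61) at the saturation current (default 75% of the
critical current) and exactly zero above the critical current, where
superconductivity is lost. Critical currents are drawn per pixel from a
narrow normal distribution around 10 µA. The error-function shape is a
modelling choice — the plateau behaviour is what matters, and any smooth
monotone sigmoid with the same plateau would serve.

Only 24 of the 36 pixels are connected to readout channels; the default
leaves the three pixels of each corner cluster (the corner and its two edge
neighbours) unconnected, since corner pixels receive only a minority of the
light. Dark counts are homogeneous Poisson processes per connected pixel.
The default per-pixel rate divides the array total of 9.7×10³ s⁻¹ by 36
elements (≈ 269 s⁻¹) — the "per pixel on average" convention; dividing by
the 24 connected channels instead is a caller's choice via
`dark_rate_per_pixel(total, n_elements = 24)`, and reports state which
convention they use. Timing jitter is Gaussian with σ = 16.99 ps, i.e. a
40 ps FWHM; fluorescence emission is delayed by an exponential lifetime
(default 1.5 ns, far below the gate width, as appropriate for a fast organic
SWIR dye whose lifetime is not separately specified).

### Detection footprint

Descanned fluorescence arrives on the array as a mixture of a tight
ballistic spot (Gaussian, FWHM 15 µm) and a broad scattered halo whose width
grows linearly with depth (`footprint_scatter_sigma_growth`, default
0.02 µm/µm — a free parameter; no measurement of halo growth is available).
Weights are exact Gaussian integrals over the 10 µm pixel squares; photons
missing the 60×60 µm array are counted as a reported spill-over fraction.
The halo mixture fraction (0.645) and surface halo width (σ = 30 µm) were
solved once, analytically, so that a shallow focus gives edge pixels one
tenth of the centre pixel's counts — the rig's stated alignment target —
and are documented here as that calibration. Because the halo fraction is
fixed while a broadening halo loses mass off the array, the edge-to-centre
ratio *decreases* with depth in this model even as spill-over grows.

## The readout model

Driver pulses are standardised to 50 ns TTL pulses; pulses on one channel
whose leading edges fall within one TTL width merge (a comparator/monoflop
cannot retrigger while high). The FPGA time base is 125 MHz → 8 ns bins;
gate bins are computed from the pulse time rounded down to the clock bin, so
bin-edge events are deterministic. Within a gate at most one photon per
pixel is recorded (optionally two for an extremely long pulse); outside the
gate nothing is. Ungated counting is exactly a gate spanning the full
inter-pulse interval, which is why gated hits are a subset of ungated hits
stream by stream.

The analog path is modelled at the per-dwell level rather than as an
80 MS/s waveform: the dwell value is (TTL pulses in the dwell) × 300 mV plus
a single-sinusoid ripple with a random phase per frame, Gaussian white
noise, and uniform ADC quantisation error. Ripple amplitude (0.6 count
equivalents), frequency (37 kHz) and white-noise sigma (0.4 counts) are free
parameters: the hardware's ripple spectrum and amplitudes are not published,
so the analog-versus-digital SBR comparison is *qualitative* — the ordering
(gated digital best) is reproduced, the printed percentage improvements are
not targeted.

Event streams are written in a little-endian binary format (16-byte header,
16-byte per-pulse records with 48-bit hit masks and trigger flags, optional
time-bin side channel) documented in the README and round-tripped bit-exactly
by `write_event_stream()`/`read_event_stream()`.

## The phantom generator

Phantoms are cylindrical vessels with piecewise-linear centerlines
(quadratic Bézier curves discretised to nine segments) in a uniform weakly
fluorescent background. Voxels are included by their centre — no
anti-aliasing — which is the simplest convention whose cross-section areas
can be checked against $\pi r^2$ by voxel counting. Each vessel draws from
its own seeded RNG substream, so vessel *k* is identical whatever the total
count. A fraction of vessels (`axial_fraction`) runs along the depth axis,
emulating penetrating arterioles and venules; axial vessels cross every
slice, which the depth-sweep experiments rely on. A `z_offset_um` lets a
deep band of tissue be modelled without voxelising everything above it.

What the phantom does *not* emulate: branching trees, vessel tapering,
hemodynamics/flow, dye washout over time (labelling density is a free
concentration parameter), motion, and any structured (non-vascular)
background. Tests passing on these phantoms therefore validate the detection
chain, the readout electronics and the image statistics — not biological
realism of the vasculature.

## Calibrating the background coefficient and the depth limit

The depth limit is defined as the depth where the SBR falls to 1, with the
image statistic

$$\mathrm{SBR} = \frac{\mu_S - \mu_{BR}}{\sigma_{BR}}$$

(signal-mask mean minus background-mask mean, over the background-mask
standard deviation; `max_SBR` replaces $\mu_S$ by the signal maximum). Note
this image statistic is *not* the ratio of signal to background photon
rates: it depends on shot noise and hence on the number of pulses averaged.
The package therefore calibrates where it measures: `calibrate_background()`
solves (by `uniroot` on $\log_{10} c_{bg}$) for the coefficient at which the
*predicted* image SBR equals 1 at the target depth, using the closed-form
expectation of the gated digital image — per dwell and pixel the hit
probability is $1 - e^{-\eta\lambda - r_d\tau_g}$ (including in-gate dark
counts), dwell values are binomial sums, and the background standard
deviation combines per-pixel shot variance with the spatial variance of the
mean. No random numbers are drawn during calibration. The
`depth_limit_experiment()` then simulates a 20-slice stack through the
target depth and hands the measured per-slice SBR curve to `depth_limit()`,
which interpolates the first crossing of SBR = 1 linearly in
(depth, log SBR). Agreement of the extracted limit with the calibration
target is a genuine self-consistency check of forward model, analytic
expectation and Monte-Carlo pipeline; the rate-ratio curve
(`sbr_rate_curve()`), on which log SBR is exactly linear in depth, is used
as the closed-form oracle for the interpolation itself.

Because the per-slice SBR estimate carries shot noise (its standard error
scales as the inverse square root of the number of signal-mask pixels) and
`depth_limit()` takes the *first* crossing, sparse phantoms bias the
extracted limit shallow. The depth experiment therefore uses a
dense-statistics protocol: 128×128 pixels over a 300 µm field, 28 axial
vessels of 6–10 µm, 10 pulses × 10 frames per pixel, 20 slices at 15 µm
spacing starting 60 µm above the target.

## Numerical choices and degenerate inputs

* Gaussian fits (jitter histograms, vessel profiles) use
  Levenberg–Marquardt (`minpack.lm::nlsLM`) with moment-based starts;
  non-convergent or degenerate fits (non-positive amplitude, width wider
  than the profile) are flagged and excluded from summaries, never silently
  dropped.
* `vessel_width()` reports FWHM $= 2.3548\,\sigma_{\mathrm{fit}}$ × pixel
  size; averaging across the 5- or 10-pixel line width can only widen the
  profile, so results are upper bounds on the true width.
* `align_lines()` breaks correlation ties toward zero shift and returns a
  low-confidence flag for zero-variance lines or weak peaks (r < 0.2).
* `depth_limit()` warns on multiple crossings (noise) and uses the first;
  an all-above-1 curve returns the deepest depth flagged "limit not
  reached".
* Jitter histograms with fewer than 100 events error (unreliable fit); a
  spread below half a bin returns the bin width, flagged degenerate.
* Threshold segmentation excludes the band between the background and
  signal quantiles (a conservative exclusion zone) and errors when the two
  thresholds collide (e.g. constant images).
* The empty phantom, empty signal masks, σ_BR = 0, trigger-count
  mismatches, unsorted pulse times, and corrupted stream files all raise
  explicit errors or flagged warnings with the offending quantity named.

## Design decisions on open points

* **Segmentation** — the learned pixel-classifier used on real data is
  replaced by quantile thresholding plus phantom ground truth: reproducible
  without a trained model, and the Jaccard overlap between the two mask
  sources on rendered slices is itself under test.
* **Per-pulse array aggregation** — digital images sum hits over connected
  pixels per pulse, matching the analog summation semantics; per-pixel
  images are retained in the stream for future image-scanning uses but not
  reconstructed.
* **Raster** — unidirectional, row-major, 0-based pixel indexing;
  bidirectional scanning and its phase correction are not modelled.
* **Dead time** — not modelled beyond the one-hit-per-gate rule: at a 1 MHz
  repetition rate the per-pulse binary response already caps each channel at
  10⁶ counts/s.
* **Configs** — YAML only (no TOML parser in the R dependency set); unknown
  keys are rejected and the resolved config is written beside every run's
  outputs. One master seed fans out into named substreams (phantom
  geometry, pixel bank, photon detection, analog noise) so that toggling
  one noise source leaves the others' draws unchanged.
* **Crosstalk, latching, electro-thermal dynamics, spectral quantum
  efficiency** — out of scope; the detector is purely the efficiency-chain /
  bias-response / dark / jitter model above.

## Problem sizes

The test-suite simulations are deliberately desk-scale: slices of 32²–128²
pixels with 8–100 pulse-frames per pixel, 10⁵-trial Monte-Carlo thinning
checks, 10⁴-event jitter fits, 2×10³-pulse bias sweeps per current, six
capillaries for the width study and a 20-slice stack for the depth limit.
These sizes keep every experiment reproducible in seconds to a couple of
minutes on one CPU while leaving the estimators' standard errors well inside
the tolerances asserted by the tests.

## Known limitations

The background model is parametric, so absolute background levels (and
therefore absolute depth limits for *uncalibrated* configurations) are only
as good as the calibration; the attenuation lengths are literature-typical
defaults, not fitted to data; the analog noise amplitudes are free
parameters, so analog/digital SBR differences are qualitative; detection
footprint growth with depth is a free linear model; and the phantom's
geometric simplicity means image-quality metrics here should be read as
detector-chain validation, not as predictions for real cortex.
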