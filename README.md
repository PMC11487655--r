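# snspdsim

Forward simulator and image-analysis pipeline for deep-tissue shortwave-infrared
(SWIR) two-photon microscopy read out by a pixelated superconducting-nanowire
single-photon detector (SNSPD) array.

## The problem

Two-photon microscopy of the adult mouse brain is depth-limited: scattering
attenuates both the focused excitation and the returning fluorescence, and at
some depth the focal signal drowns in out-of-focus background — the
signal-to-background ratio (SBR) falls to ~1 and structure becomes
indistinguishable. Moving excitation and emission into the SWIR window
(1000–1700 nm) pushes that limit past a millimetre, but demands single-photon
detectors that barely exist at those wavelengths. A cryogenic 6×6 SNSPD array
(10 µm pixels, 3600 µm² sensitive area, 24 connected channels) with custom
electronics provides two readout paths: **analog summation** of the 24 scaled
channel pulses into one PMT-compatible signal, and **gated digital counting**,
where an FPGA running at 125 MHz (8 ns time bins) records, per laser pulse and
pixel, whether a photon arrived inside a programmable gate.

`snspdsim` reproduces this detection chain end to end on synthetic vascular
phantoms, so every published analysis — per-slice SBR, vessel-width line
profiles, depth-limit extraction, count-rate budgets, bias sweeps, jitter
histograms — can be exercised quantitatively without hardware.

## The model in brief

* **Phantom** — cylindrical vessels (piecewise-linear centerlines, diameters
  3–10 µm) in a weakly fluorescent volume; ground-truth signal/background
  masks come from the geometry. z = 0 is the tissue surface (pia).
* **Optics** — two-photon focal signal per pulse
  `S(z) = B · C(focus) · (E_s/E_ref)² · exp(−2z/l_ex) · exp(−z/l_em)`,
  with the surface pulse energy `E_s` scheduled as `exp(z/l_ex)` to hold the
  focal energy constant (≤ 2 nJ) up to the 100 mW average-power cap.
  Out-of-focus background is a calibrated single-coefficient term driven by
  the shallow dye concentration and the squared surface excitation. The
  detector-plane footprint mixes a ballistic Gaussian (FWHM 15 µm) with a
  depth-broadened scattered halo, calibrated so edge pixels see ~10× fewer
  counts than the centre pixel.
* **Detector** — per-pixel efficiency chain (window 0.935 × lens 0.99 ×
  detector ≈ 0.61 → system ≈ 57%), sigmoidal internal efficiency versus bias
  with a hard cutoff at the critical current (~10 µA), Poisson photon
  thinning with a saturating one-hit-per-pulse response, Poisson dark counts
  (9.7×10³ s⁻¹ array total), and Gaussian timing jitter (40 ps FWHM).
* **Readout** — 50 ns TTL standardisation with merge semantics, per-pulse
  event records (48-bit hit masks, 8 ns bins, frame/line triggers), gated
  and ungated counting, analog summation with ripple, white noise and ADC
  quantisation, and a documented binary event-stream format (below).
* **Analysis** — `SBR = (µ_S − µ_BR)/σ_BR` (mean or max signal minus
  background mean over background standard deviation), quantile-threshold or
  ground-truth segmentation, Gaussian+offset line-profile fits
  (`FWHM = 2.3548 σ`), log-linear depth-limit interpolation at SBR = 1.

## Worked example

```r
library(snspdsim)

chain <- efficiency_chain()          # window 0.935, lens 0.99, detector 0.61
system_efficiency(chain)             # 0.5646  -> the measured ~57%
detector_efficiency_from_system(0.57, 0.935, 0.99)  # 0.6158 -> the ~61%

# one shallow slice, simulated once, read out three ways
fx <- make_figure5_fixture(list(
  phantom = list(volume_shape = c(48L, 48L, 30L), voxel_size_um = 2.5,
                 vessel_count = 4L, diameter_range_um = c(3, 8),
                 axial_fraction = 1),
  scan = list(nx = 32L, ny = 32L, pulses_per_pixel = 4L,
              frames_averaged = 2L, fov_um = 120),
  seed = 1L), depth_um = 40)
fx$sbr_table
#> # A tibble: 3 × 3
#>   mode            mean_sbr max_sbr
#>   <chr>              <dbl>   <dbl>
#> 1 digital_gated       19.7    26.5
#> 2 digital_ungated     17.6    23.8
#> 3 analog              12.1    17.2
```

Gated digital counting gives the best SBR: the 80 ns gate rejects dark and
stray events spread over the 1 µs inter-pulse interval, and counting is
immune to the analog chain's ripple and quantisation noise. The calibrated
deep-imaging protocol is one call:

```r
bundle <- depth_limit_experiment(target_depth_um = 1150, seed = 1)
bundle$depth_limit      # depth_limit_um ~ 1150, limit_reached TRUE
autoplot(bundle$sbr)    # per-slice SBR vs depth, log scale, SBR = 1 line
```

Every tabular result has `tidy()`/`glance()` methods and an `autoplot()`.

## Event-stream format (`.snev`)

Little-endian. 16-byte header: magic `"SNEV"`, version `u16`, flags `u16`
(bit 0 = time-bin side channel present), repetition rate `u64` (Hz). When the
side channel is present the header is followed by the record count `u64`.
Then fixed 16-byte records — pulse index `u64`, hit mask `u48` (bit 0 =
pixel (0,0), row-major), flags `u8` (bit 0 frame trigger, bit 1 line
trigger), reserved `u8` — running to EOF when there is no side channel.
The side channel holds the event count `u64` followed by 12-byte entries:
pulse index `u64`, pixel `u8`, reserved `u8`, 8 ns bin `u16`.
`write_event_stream()` / `read_event_stream()` round trip losslessly.

## Command line

A thin driver over the exported functions lives at `inst/cli/snspdsim.R`
(subcommands `phantom`, `simulate`, `count`, `reconstruct`, `analyze`,
`demo-fig5`, `report-targets`; options `--config`, `--seed`, `--out`,
`--gate-delay`, `--gate-width`, `--ungated`). Configurations are YAML; every
run writes its resolved config beside its outputs.

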