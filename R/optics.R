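# Excitation/emission optics: two-photon signal and background rates versus
# depth, surface power scheduling, and the photon footprint on the detector.

#' Pulsed-laser configuration
#'
#' Defaults follow the imaging conditions of a deep-tissue SWIR two-photon
#' rig: 1700 nm excitation at 1 MHz repetition rate with 60 fs pulses,
#' holding at most 2 nJ per pulse at the focus and 100 mW average power at
#' the surface (photodamage limits).
#'
#' @param wavelength_nm Excitation wavelength.
#' @param rep_rate_hz Pulse repetition rate.
#' @param pulse_duration_fs Pulse duration.
#' @param pulse_energy_focus_nj Target pulse energy at the focus; a warning
#'   is issued above 2 nJ.
#' @param avg_power_max_mw Maximum average power at the tissue surface.
#' @param e_ref_nj Reference pulse energy for the two-photon square law.
#' @return An object of class `laser_config`.
#' @export
laser_config <- function(wavelength_nm = 1700, rep_rate_hz = 1e6,
                         pulse_duration_fs = 60, pulse_energy_focus_nj = 2,
                         avg_power_max_mw = 100, e_ref_nj = 2) {
  assert_scalar_pos(rep_rate_hz, "rep_rate_hz")
  assert_scalar_pos(pulse_energy_focus_nj, "pulse_energy_focus_nj")
  assert_scalar_pos(avg_power_max_mw, "avg_power_max_mw")
  assert_scalar_pos(e_ref_nj, "e_ref_nj")
  if (pulse_energy_focus_nj > 2) {
    warning("pulse energy at focus exceeds the 2 nJ photodamage guideline",
            call. = FALSE)
  }
  structure(list(wavelength_nm = wavelength_nm, rep_rate_hz = rep_rate_hz,
                 pulse_duration_fs = pulse_duration_fs,
                 pulse_energy_focus_nj = pulse_energy_focus_nj,
                 avg_power_max_mw = avg_power_max_mw, e_ref_nj = e_ref_nj),
            class = "laser_config")
}

#' Optics configuration
#'
#' Attenuation lengths default to literature-typical values for mouse cortex
#' (excitation ~365 um at 1700 nm; emission ~270 um at ~1100 nm); they are
#' free parameters, not measured ground truth. `background_coefficient` is a
#' single-coefficient stand-in for the out-of-focus excitation integral and
#' is calibrated per experiment (see [calibrate_background()]).
#'
#' The detector-plane footprint is a two-component mixture: a ballistic
#' Gaussian (FWHM ~15 um, the aligned detection spot) plus a scattered halo
#' whose width grows with depth. The default halo fraction/width are
#' calibrated so a shallow focus gives edge pixels about a factor 10 fewer
#' counts than the centre pixel, the rig's stated alignment target.
#'
#' @param l_ex_um Effective attenuation length for the excitation light (um).
#' @param l_em_um Effective attenuation length for the emitted fluorescence.
#' @param focal_spot_fwhm_um Lateral FWHM of the two-photon excitation spot.
#' @param brightness_scale Expected emitted signal photons per pulse at z = 0
#'   for unit dye concentration and reference pulse energy.
#' @param background_coefficient Dimensionless out-of-focus background
#'   coefficient (>= 0).
#' @param footprint_ballistic_fwhm_um FWHM of the ballistic detection spot.
#' @param footprint_halo_fraction Weight of the scattered halo component.
#' @param footprint_halo_sigma0_um Halo Gaussian sigma at the surface.
#' @param footprint_scatter_sigma_growth Halo sigma growth per um of depth.
#' @param background_footprint_sigma_um Width of the (broad) detector-plane
#'   distribution of out-of-focus background photons.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(l_ex_um = 365, l_em_um = 270,
                          focal_spot_fwhm_um = 1,
                          brightness_scale = 5,
                          background_coefficient = 1e-3,
                          footprint_ballistic_fwhm_um = 15,
                          footprint_halo_fraction = 0.645,
                          footprint_halo_sigma0_um = 30,
                          footprint_scatter_sigma_growth = 0.02,
                          background_footprint_sigma_um = 60) {
  assert_scalar_pos(l_ex_um, "l_ex_um")
  assert_scalar_pos(l_em_um, "l_em_um")
  assert_scalar_pos(focal_spot_fwhm_um, "focal_spot_fwhm_um")
  assert_scalar_pos(brightness_scale, "brightness_scale")
  assert_scalar_pos(background_coefficient, "background_coefficient",
                    strict = FALSE)
  assert_scalar_pos(footprint_ballistic_fwhm_um, "footprint_ballistic_fwhm_um")
  assert_fraction(footprint_halo_fraction, "footprint_halo_fraction")
  assert_scalar_pos(footprint_halo_sigma0_um, "footprint_halo_sigma0_um")
  assert_scalar_pos(footprint_scatter_sigma_growth,
                    "footprint_scatter_sigma_growth", strict = FALSE)
  assert_scalar_pos(background_footprint_sigma_um,
                    "background_footprint_sigma_um")
  structure(list(l_ex_um = l_ex_um, l_em_um = l_em_um,
                 focal_spot_fwhm_um = focal_spot_fwhm_um,
                 brightness_scale = brightness_scale,
                 background_coefficient = background_coefficient,
                 footprint_ballistic_fwhm_um = footprint_ballistic_fwhm_um,
                 footprint_halo_fraction = footprint_halo_fraction,
                 footprint_halo_sigma0_um = footprint_halo_sigma0_um,
                 footprint_scatter_sigma_growth = footprint_scatter_sigma_growth,
                 background_footprint_sigma_um = background_footprint_sigma_um),
            class = "optics_config")
}

#' Scheduled surface pulse energy at depth
#'
#' The surface pulse energy is raised as `exp(z / l_ex)` to hold the pulse
#' energy at the focus constant, capped by the average-power limit. Beyond
#' the cap the focal energy (and hence signal) rolls off; the returned value
#' carries attribute `capped`.
#'
#' @param z_um Focus depth (um), scalar or vector.
#' @param laser A [laser_config()].
#' @param optics An [optics_config()].
#' @return Surface pulse energy in nJ with logical attribute `capped`.
#' @export
surface_pulse_energy <- function(z_um, laser, optics) {
  e_cap <- laser$avg_power_max_mw * 1e6 / laser$rep_rate_hz # nJ per pulse
  e <- laser$pulse_energy_focus_nj * exp(z_um / optics$l_ex_um)
  capped <- e > e_cap
  if (any(capped)) {
    warning("average-power cap reached at depth >= ",
            signif(min(z_um[capped]), 4), " um; focal pulse energy rolls off",
            call. = FALSE)
  }
  structure(pmin(e, e_cap), capped = capped)
}

# Concentration at the focus, with the focal spot modelled as a lateral
# Gaussian average over the slice (two-photon optical sectioning is treated
# as ideal in z).
focus_concentration <- function(phantom, focus_position) {
  cfg <- phantom$config
  ext <- phantom_extent_um(cfg)
  x <- focus_position[1]; y <- focus_position[2]; z <- focus_position[3]
  zl <- z - cfg$z_offset_um
  if (x < 0 || x > ext[1] || y < 0 || y > ext[2] || zl < 0 || zl > ext[3]) {
    stop("focus position is outside the phantom volume", call. = FALSE)
  }
  k <- phantom_slice_index(phantom, z)
  ix <- pmin(pmax(ceiling(x / cfg$voxel_size_um), 1L), cfg$volume_shape[1])
  iy <- pmin(pmax(ceiling(y / cfg$voxel_size_um), 1L), cfg$volume_shape[2])
  phantom$concentration[cbind(ix, iy, k)]
}

# Slice concentration map blurred by the excitation spot, on the voxel grid.
excitation_slice <- function(phantom, slice_z_um, optics) {
  k <- phantom_slice_index(phantom, slice_z_um)
  sl <- phantom$concentration[, , k]
  sig_vox <- fwhm_to_sigma(optics$focal_spot_fwhm_um) /
    phantom$config$voxel_size_um
  if (sig_vox > 0.2) sl <- EBImage::gblur(sl, sigma = sig_vox)
  pmax(sl, 0)
}

#' Expected focal signal photons per pulse (emitted, pre-detection)
#'
#' Two-photon signal model: `brightness_scale * C(focus) * (E_s / E_ref)^2 *
#' exp(-2 z / l_ex) * exp(-z / l_em)`, where `E_s` is the surface pulse
#' energy (squared excitation attenuates going in, emitted fluorescence
#' attenuates coming out).
#'
#' @param phantom An `snspd_phantom`.
#' @param focus_position Numeric `c(x, y, z)` in um (z absolute depth).
#' @param laser A [laser_config()].
#' @param optics An [optics_config()].
#' @param surface_pulse_energy_nj Surface pulse energy; default uses the
#'   depth-compensating schedule of [surface_pulse_energy()].
#' @return Expected emitted signal photons per pulse.
#' @export
focal_signal_rate <- function(phantom, focus_position, laser, optics,
                              surface_pulse_energy_nj = NULL) {
  z <- focus_position[3]
  conc <- focus_concentration(phantom, focus_position)
  if (is.null(surface_pulse_energy_nj)) {
    surface_pulse_energy_nj <-
      suppressWarnings(surface_pulse_energy(z, laser, optics))
  }
  optics$brightness_scale * conc *
    (as.numeric(surface_pulse_energy_nj) / laser$e_ref_nj)^2 *
    exp(-2 * z / optics$l_ex_um) * exp(-z / optics$l_em_um)
}

# Mean concentration over the shallow part of the phantom (the top half
# attenuation length), the region where out-of-focus excitation is strongest.
shallow_concentration <- function(phantom, optics) {
  zl <- phantom$depth_axis_um - phantom$config$z_offset_um
  keep <- zl <= max(optics$l_ex_um / 2, zl[1])
  mean(phantom$concentration[, , which(keep), drop = FALSE])
}

#' Expected out-of-focus background photons per pulse
#'
#' Single-coefficient parametric model: background scales with the mean
#' shallow dye concentration and the squared surface excitation,
#' `background_coefficient * C_shallow * (E_s / E_ref)^2`. Under the
#' depth-compensating power schedule this is non-decreasing in focus depth.
#'
#' @inheritParams focal_signal_rate
#' @param focus_z_um Focus depth (um), scalar or vector.
#' @return Expected background photons per pulse.
#' @export
background_rate <- function(phantom, focus_z_um, laser, optics,
                            surface_pulse_energy_nj = NULL) {
  stopifnot(all(focus_z_um >= 0))
  if (is.null(surface_pulse_energy_nj)) {
    surface_pulse_energy_nj <-
      suppressWarnings(surface_pulse_energy(focus_z_um, laser, optics))
  }
  optics$background_coefficient * shallow_concentration(phantom, optics) *
    (as.numeric(surface_pulse_energy_nj) / laser$e_ref_nj)^2
}

#' Rate-level SBR versus depth
#'
#' Ratio of expected focal signal (at a reference unit-concentration focus)
#' to expected background, per pulse, over a depth sweep.
#'
#' @inheritParams background_rate
#' @param depths_um Depth grid (um).
#' @param concentration Dye concentration at the focus used for the signal.
#' @return A tibble with `depth_um`, `signal_rate`, `background_rate`, `sbr`.
#' @export
sbr_rate_curve <- function(phantom, depths_um, laser, optics,
                           concentration = NULL) {
  if (is.null(concentration)) concentration <- phantom$config$dye_concentration
  es <- suppressWarnings(surface_pulse_energy(depths_um, laser, optics))
  sig <- optics$brightness_scale * concentration *
    (as.numeric(es) / laser$e_ref_nj)^2 *
    exp(-2 * depths_um / optics$l_ex_um) * exp(-depths_um / optics$l_em_um)
  bg <- background_rate(phantom, depths_um, laser, optics,
                        surface_pulse_energy_nj = es)
  tibble::tibble(depth_um = depths_um, signal_rate = sig,
                 background_rate = bg, sbr = sig / bg)
}

# 1D Gaussian mass over pixel intervals [lo, hi] for a spot centred at 0.
gauss_interval_mass <- function(lo, hi, sigma) {
  stats::pnorm(hi / sigma) - stats::pnorm(lo / sigma)
}

# Per-pixel integral of a centred 2D isotropic Gaussian over the array grid.
gaussian_pixel_weights <- function(sigma, geometry) {
  side <- geometry$pixel_side_um
  edges <- (seq_len(geometry$cols + 1L) - 1L - geometry$cols / 2) * side
  mx <- gauss_interval_mass(edges[-length(edges)], edges[-1], sigma)
  edges_r <- (seq_len(geometry$rows + 1L) - 1L - geometry$rows / 2) * side
  my <- gauss_interval_mass(edges_r[-length(edges_r)], edges_r[-1], sigma)
  outer(my, mx) # rows x cols
}

#' Photon footprint on the detector array
#'
#' Mixture of the ballistic detection spot (Gaussian, fixed FWHM) and a
#' scattered halo whose sigma grows linearly with depth. Each component is
#' integrated over the 10 um pixel squares; weights over the 6x6 grid plus
#' the reported spill-over fraction (photons missing the array) sum to 1.
#'
#' @param focus_z_um Focus depth (um).
#' @param optics An [optics_config()].
#' @param geometry An [array_geometry()].
#' @return An object of class `snspd_footprint`: list with `weights`
#'   (rows x cols matrix), `spill_over`, `focus_z_um`.
#' @export
detector_footprint <- function(focus_z_um, optics, geometry = array_geometry()) {
  stopifnot(focus_z_um >= 0)
  sig_b <- fwhm_to_sigma(optics$footprint_ballistic_fwhm_um)
  sig_h <- optics$footprint_halo_sigma0_um +
    optics$footprint_scatter_sigma_growth * focus_z_um
  f <- optics$footprint_halo_fraction
  w <- (1 - f) * gaussian_pixel_weights(sig_b, geometry) +
    f * gaussian_pixel_weights(sig_h, geometry)
  structure(list(weights = w, spill_over = 1 - sum(w),
                 focus_z_um = focus_z_um),
            class = "snspd_footprint")
}

# Broad detector-plane distribution of out-of-focus background photons.
background_footprint <- function(optics, geometry = array_geometry()) {
  w <- gaussian_pixel_weights(optics$background_footprint_sigma_um, geometry)
  structure(list(weights = w, spill_over = 1 - sum(w), focus_z_um = NA_real_),
            class = "snspd_footprint")
}

#' @export
print.snspd_footprint <- function(x, ...) {
  cat(sprintf("<snspd_footprint> z = %s um, on-array %.3f, spill-over %.3f\n",
              format(x$focus_z_um), sum(x$weights), x$spill_over))
  print(round(x$weights, 4))
  invisible(x)
}
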