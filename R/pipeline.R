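# End-to-end pipeline driver: run configuration (YAML), seed fan-out,
# slice-by-slice simulation, multi-mode reconstruction, SBR/depth reports
# and artifact output.

#' Default run configuration
#'
#' A nested list with one block per pipeline stage (`phantom`, `laser`,
#' `optics`, `detector`, `gate`, `analog`, `scan`, `analysis`) plus the run
#' controls `depths_um`, `modes`, `calibrate`, `seed`. Any block value can
#' be overridden; unknown keys are rejected at validation. The single
#' `seed` is fanned out into named substreams (phantom geometry, photon
#' detection, analog noise) so that toggling one noise source leaves the
#' others' draws unchanged.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    phantom = list(volume_shape = c(64L, 64L, 110L), voxel_size_um = 300 / 64,
                   vessel_count = 8L, diameter_range_um = c(3, 10),
                   dye_concentration = 1, background_concentration = 0.02,
                   z_offset_um = 0, axial_fraction = 0.3),
    laser = list(wavelength_nm = 1700, rep_rate_hz = 1e6,
                 pulse_duration_fs = 60, pulse_energy_focus_nj = 2,
                 avg_power_max_mw = 100, e_ref_nj = 2),
    optics = list(l_ex_um = 365, l_em_um = 270, focal_spot_fwhm_um = 1,
                  brightness_scale = 5, background_coefficient = 1e-3,
                  footprint_ballistic_fwhm_um = 15,
                  footprint_halo_fraction = 0.645,
                  footprint_halo_sigma0_um = 30,
                  footprint_scatter_sigma_growth = 0.02,
                  background_footprint_sigma_um = 60),
    detector = list(eta_max = 0.61, i_c_mean_ua = 10, i_c_sd_ua = 0.3,
                    i_sat_frac = 0.75, dark_rate_cps = 9700 / 36,
                    jitter_sigma_ps = 16.99, bias_ua = 9, lifetime_ns = 1.5),
    gate = list(clock_hz = 125e6, delay_bins = 0L, width_bins = 10L,
                long_pulse_double_count = FALSE,
                long_pulse_threshold_ns = 100),
    analog = list(per_channel_amplitude_mv = 300,
                  driver_pulse_length_ns = 20, driver_pulse_peak_mv = 200,
                  ttl_width_ns = 50, ttl_level_v = 3.3,
                  ripple_amplitude = 0.6, ripple_freq_hz = 37e3,
                  white_noise_sigma = 0.4, adc_bits = 16L,
                  adc_fullscale_mv = 20000),
    scan = list(nx = 64L, ny = 64L, pulses_per_pixel = 10L,
                frames_averaged = 10L, fov_um = 300, z_step_um = 5),
    analysis = list(mask_dilation_um = 10),
    depths_um = seq(25, 500, by = 25),
    modes = c("analog", "digital_gated", "digital_ungated"),
    calibrate = NULL, # or list(target_depth_um =, target_sbr = 1)
    seed = 1L), class = "run_config")
}

# Recursively check `config` against the default template: unknown keys are
# rejected; missing keys fall back to the defaults.
merge_config <- function(config, template = default_run_config(),
                         path = character()) {
  if (!is.list(config)) return(config)
  extra <- setdiff(names(config), names(template))
  if (length(extra)) {
    stop("unknown config key(s): ",
         paste(paste(c(path, extra[1]), collapse = "$"), collapse = ", "),
         call. = FALSE)
  }
  out <- template
  for (nm in names(config)) {
    out[[nm]] <- if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      merge_config(config[[nm]], template[[nm]], c(path, nm))
    } else {
      config[[nm]]
    }
  }
  out
}

#' Validate and complete a run configuration
#'
#' @param config A (possibly partial) nested list of overrides.
#' @return A complete `run_config`; errors on unknown keys.
#' @export
validate_run_config <- function(config = list()) {
  cfg <- merge_config(unclass(config))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `load_run_config()`: a validated `run_config`;
#'   `save_run_config()`: `path`, invisibly.
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Instantiate the typed configuration objects from a run config.
build_components <- function(config) {
  cfg <- validate_run_config(config)
  phantom_cfg <- do.call(phantom_config,
                         c(cfg$phantom,
                           list(seed = substream_seed(cfg$seed, "phantom"))))
  geometry <- array_geometry()
  pixels <- do.call(pixel_bank,
                    c(list(geometry = geometry),
                      cfg$detector[c("eta_max", "i_c_mean_ua", "i_c_sd_ua",
                                     "i_sat_frac", "dark_rate_cps",
                                     "jitter_sigma_ps")],
                      list(seed = substream_seed(cfg$seed, "pixel-bank"))))
  list(config = cfg,
       phantom = generate_phantom(phantom_cfg),
       laser = do.call(laser_config, cfg$laser),
       optics = do.call(optics_config, cfg$optics),
       detector = detector_config(geometry = geometry, pixels = pixels,
                                  bias_ua = cfg$detector$bias_ua,
                                  lifetime_ns = cfg$detector$lifetime_ns),
       gate = do.call(gate_config, cfg$gate),
       analog = do.call(analog_chain_config, cfg$analog),
       scan = do.call(scan_config, cfg$scan))
}

# Reconstruct the requested modes from one slice stream.
slice_images <- function(stream, comp, modes, noise_seed) {
  out <- list()
  if ("digital_gated" %in% modes) {
    out$digital_gated <- reconstruct_digital(gated_count(stream, comp$gate))
  }
  if ("digital_ungated" %in% modes) {
    out$digital_ungated <- reconstruct_digital(ungated_count(stream))
  }
  if ("analog" %in% modes) {
    av <- with_seed(noise_seed, analog_sum(stream, comp$analog))
    out$analog <- reconstruct_analog(av, comp$scan)
  }
  out
}

#' Run a full simulated imaging experiment
#'
#' For every requested depth, simulates the slice's photon event stream and
#' reconstructs it in each requested mode; per-slice SBR statistics are
#' computed against the phantom's ground-truth masks, and a depth limit is
#' extracted from the gated digital SBR curve (falling back to the first
#' available mode). With `config$calibrate` set, the background coefficient
#' is first calibrated so the predicted SBR hits the target at the target
#' depth. Deterministic for a fixed `config$seed`.
#'
#' @param config A (partial) run configuration; see [default_run_config()].
#' @param output_dir Optional directory for artifacts: per-slice event
#'   streams, per-mode TIFF stacks with JSON sidecars, the SBR table (CSV),
#'   a JSON summary, the resolved config (YAML) and a run log.
#' @return Invisible list: `config`, `phantom`, `optics` (post-calibration),
#'   `stacks` (per mode), `sbr` (an `snspd_sbr_report`), `depth_limit`.
#' @export
run_experiment <- function(config = list(), output_dir = NULL) {
  comp <- build_components(config)
  cfg <- comp$config
  if (!is.null(cfg$calibrate)) {
    comp$optics <- calibrate_background(
      comp$phantom, comp$scan, comp$laser, comp$optics, comp$detector,
      comp$gate,
      target_depth_um = cfg$calibrate$target_depth_um,
      target_sbr = if (is.null(cfg$calibrate$target_sbr)) 1
                   else cfg$calibrate$target_sbr,
      dilation_um = cfg$analysis$mask_dilation_um)
  }
  depths <- sort(as.numeric(cfg$depths_um))
  detect_seed <- substream_seed(cfg$seed, "detect")
  noise_seed <- substream_seed(cfg$seed, "analog-noise")

  images <- stats::setNames(vector("list", length(cfg$modes)), cfg$modes)
  for (m in cfg$modes) images[[m]] <- vector("list", length(depths))
  sbr_rows <- list()
  streams_dir <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    streams_dir <- file.path(output_dir, "streams")
    dir.create(streams_dir, showWarnings = FALSE)
  }
  for (k in seq_along(depths)) {
    z <- depths[k]
    stream <- simulate_slice(comp$phantom, z, comp$scan, comp$laser,
                             comp$optics, comp$detector, comp$gate,
                             seed = detect_seed)
    if (!is.null(streams_dir)) {
      write_event_stream(stream,
                         file.path(streams_dir,
                                   sprintf("slice_%04.0fum.snev", z)))
    }
    imgs <- slice_images(stream, comp, cfg$modes,
                         noise_seed = noise_seed + k)
    masks <- suppressWarnings(ground_truth_masks(
      comp$phantom, z, cfg$analysis$mask_dilation_um,
      grid = list(nx = comp$scan$nx, ny = comp$scan$ny,
                  fov_um = comp$scan$fov_um)))
    for (m in names(imgs)) {
      images[[m]][[k]] <- imgs[[m]]
      images[[m]][[k]]$depth_um <- z
      row <- suppressWarnings(
        compute_sbr(imgs[[m]], masks$signal, masks$background))
      sbr_rows[[length(sbr_rows) + 1L]] <-
        dplyr::mutate(row, depth_um = z, mode = m, .before = 1)
    }
  }
  sbr <- new_sbr_report(dplyr::bind_rows(sbr_rows),
                        background_coefficient = comp$optics$background_coefficient)
  dl_mode <- if ("digital_gated" %in% cfg$modes) "digital_gated" else cfg$modes[1]
  dl_tbl <- sbr[sbr$mode == dl_mode & !sbr$empty_signal &
                  is.finite(sbr$mean_sbr) & sbr$mean_sbr > 0,
                c("depth_um", "mean_sbr")]
  dl <- if (nrow(dl_tbl) >= 2) {
    suppressWarnings(depth_limit(
      tibble::tibble(depth_um = dl_tbl$depth_um, sbr = dl_tbl$mean_sbr)))
  } else {
    tibble::tibble(depth_limit_um = NA_real_, limit_reached = FALSE,
                   n_crossings = 0L)
  }
  stacks <- lapply(images, function(imgs) image_stack(imgs, depths))
  bundle <- list(config = cfg, phantom = comp$phantom, optics = comp$optics,
                 stacks = stacks, sbr = sbr, depth_limit = dl)
  if (!is.null(output_dir)) {
    for (m in names(stacks)) {
      save_image_stack(stacks[[m]],
                       file.path(output_dir, paste0("stack_", m, ".tif")))
    }
    utils::write.csv(as.data.frame(sbr),
                     file.path(output_dir, "sbr_per_slice.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, modes = cfg$modes,
           background_coefficient = comp$optics$background_coefficient,
           dark_rate_convention = "total over 36 elements",
           depth_limit = as.list(dl)),
      file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    save_run_config(cfg, file.path(output_dir, "resolved_config.yaml"))
    writeLines(c(sprintf("snspdsim %s", as.character(utils::packageVersion("snspdsim"))),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("R: %s", R.version.string),
                 sprintf("depths: %s um", paste(depths, collapse = ", "))),
               file.path(output_dir, "run.log"))
  }
  invisible(bundle)
}

#' Three-modality comparison on one shared event stream
#'
#' Simulates a single shallow slice once and processes the same stream
#' three ways — analog summation, ungated digital counting, gated digital
#' counting — so the modality comparison is free of acquisition noise
#' differences. Emits the SBR table for the three images.
#'
#' @param config A (partial) run configuration.
#' @param depth_um Slice depth (default 42 um, a shallow high-SBR slice).
#' @return List: `images` (named list), `sbr_table` (tibble with `mode`,
#'   `mean_sbr`, `max_sbr`), `stream`.
#' @export
make_figure5_fixture <- function(config = list(), depth_um = 42) {
  comp <- build_components(config)
  cfg <- comp$config
  stream <- simulate_slice(comp$phantom, depth_um, comp$scan, comp$laser,
                           comp$optics, comp$detector, comp$gate,
                           seed = substream_seed(cfg$seed, "detect"))
  imgs <- slice_images(stream, comp,
                       c("analog", "digital_ungated", "digital_gated"),
                       noise_seed = substream_seed(cfg$seed, "analog-noise"))
  masks <- suppressWarnings(ground_truth_masks(
    comp$phantom, depth_um, cfg$analysis$mask_dilation_um,
    grid = list(nx = comp$scan$nx, ny = comp$scan$ny,
                fov_um = comp$scan$fov_um)))
  sbr_table <- dplyr::bind_rows(lapply(names(imgs), function(m) {
    dplyr::mutate(suppressWarnings(
      compute_sbr(imgs[[m]], masks$signal, masks$background)),
      mode = m, .before = 1)
  }))
  list(images = imgs, sbr_table = sbr_table[, c("mode", "mean_sbr", "max_sbr")],
       stream = stream)
}

#' Depth-limit self-consistency experiment
#'
#' Runs the calibrated deep-imaging protocol: a vascular band phantom of
#' descending (axial) vessels spanning the target depth, the background
#' coefficient calibrated so the predicted image SBR equals 1 at
#' `target_depth_um`, and a simulated stack whose per-slice gated SBR curve
#' is handed to [depth_limit()]. If the forward model, the calibration and
#' the SBR statistic are mutually consistent, the extracted limit falls at
#' the target depth up to Monte-Carlo noise.
#'
#' @param target_depth_um Calibration target depth (um).
#' @param n_slices Number of simulated slices.
#' @param span_um Depth span of the simulated stack, centred near the
#'   target (the stack starts 150 um above the target).
#' @param config Overrides for the non-phantom blocks.
#' @param seed Integer seed.
#' @return The [run_experiment()] bundle (with `depth_limit`).
#' @export
depth_limit_experiment <- function(target_depth_um = 1150, n_slices = 20L,
                                   span_um = 285, config = list(),
                                   seed = 1L) {
  vox <- 300 / 128
  z0 <- target_depth_um - 60
  nz <- ceiling((span_um + 90) / vox)
  overrides <- list(
    phantom = list(volume_shape = c(128L, 128L, nz), voxel_size_um = vox,
                   vessel_count = 28L, diameter_range_um = c(6, 10),
                   z_offset_um = z0 - 30, axial_fraction = 1),
    scan = list(nx = 128L, ny = 128L),
    depths_um = seq(z0, z0 + span_um, length.out = n_slices),
    modes = "digital_gated",
    calibrate = list(target_depth_um = target_depth_um, target_sbr = 1),
    seed = seed)
  cfg <- utils::modifyList(overrides, config)
  run_experiment(cfg)
}

#' Vessel-width recovery study at depth
#'
#' Simulates thin capillaries (true diameters drawn near 3 um) lying in the
#' image plane at depths spanning 800-964 um, reconstructs each slice in
#' gated digital mode at ~1.2 um pixels, and fits a Gaussian line profile
#' across each vessel. The summary mean/sd emulate the capillary-diameter
#' quantification protocol.
#'
#' @param n_vessels Number of capillaries (one per mini-phantom).
#' @param diameter_um Nominal true diameter; individual vessels draw
#'   uniformly within +/-20%.
#' @param depth_range_um Depth span of the study.
#' @param config Overrides for the laser/optics/detector blocks.
#' @param seed Integer seed.
#' @return List: `widths` (per-profile tibble with `true_diameter_um`),
#'   `summary` ([vessel_width_summary()] row).
#' @export
vessel_width_experiment <- function(n_vessels = 6L, diameter_um = 3,
                                    depth_range_um = c(800, 964),
                                    config = list(), seed = 1L) {
  cfg <- validate_run_config(config)
  laser <- do.call(laser_config, cfg$laser)
  optics <- do.call(optics_config, cfg$optics)
  geometry <- array_geometry()
  pixels <- do.call(pixel_bank,
                    c(list(geometry = geometry),
                      cfg$detector[c("eta_max", "i_c_mean_ua", "i_c_sd_ua",
                                     "i_sat_frac", "dark_rate_cps",
                                     "jitter_sigma_ps")],
                      list(seed = substream_seed(seed, "pixel-bank"))))
  detector <- detector_config(geometry = geometry, pixels = pixels,
                              bias_ua = cfg$detector$bias_ua,
                              lifetime_ns = cfg$detector$lifetime_ns)
  gate <- do.call(gate_config, cfg$gate)
  depths <- seq(depth_range_um[1], depth_range_um[2],
                length.out = n_vessels)
  diam <- with_seed(substream_seed(seed, "capillary-diameters"), {
    stats::runif(n_vessels, 0.8 * diameter_um, 1.2 * diameter_um)
  })
  vox <- 0.6
  nvx <- 128L
  scan <- scan_config(nx = 64L, ny = 64L, pulses_per_pixel = 10L,
                      frames_averaged = 10L, fov_um = nvx * vox,
                      z_step_um = 5)
  px_um <- scan$fov_um / scan$nx
  rows <- list()
  for (i in seq_len(n_vessels)) {
    z <- depths[i]
    pcfg <- phantom_config(volume_shape = c(nvx, nvx, 12L),
                           voxel_size_um = vox, vessel_count = 1L,
                           diameter_range_um = c(diam[i], diam[i] + 1e-9),
                           dye_concentration = cfg$phantom$dye_concentration,
                           background_concentration =
                             cfg$phantom$background_concentration,
                           z_offset_um = z - 6 * vox, seed = seed + i)
    mid <- nvx * vox / 2
    vessel <- list(radius_um = diam[i] / 2,
                   centerline = cbind(x = c(mid, mid),
                                      y = c(vox, nvx * vox - vox),
                                      z = c(z, z)))
    ph <- phantom_from_vessels(pcfg, list(vessel))
    stream <- simulate_slice(ph, z, scan, laser, optics, detector, gate,
                             seed = substream_seed(seed, paste0("width-", i)))
    img <- reconstruct_digital(gated_count(stream, gate))
    xc <- mid / px_um + 0.5 # vessel centre in pixel coordinates
    yc <- scan$ny / 2
    endpoints <- rbind(c(xc - 9, yc), c(xc + 9, yc))
    w <- vessel_width(img, endpoints, line_width_px = 5,
                      pixel_size_um = px_um, depth_um = z)
    rows[[i]] <- dplyr::mutate(w, true_diameter_um = diam[i])
  }
  widths <- dplyr::bind_rows(rows)
  list(widths = widths, summary = vessel_width_summary(widths))
}
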