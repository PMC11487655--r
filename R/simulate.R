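# Forward simulation of one raster-scanned slice: expected photon rates per
# dwell from the optics model, Poisson detection on the connected SNSPD
# pixels, dark counts, and assembly into a per-pulse event stream.

#' Bundle the detector-side configuration
#'
#' @param geometry An [array_geometry()].
#' @param pixels A [pixel_bank()] tibble.
#' @param chain An [efficiency_chain()].
#' @param bias_ua Operating bias current (uA); the default sits on the
#'   efficiency plateau below the critical current.
#' @param lifetime_ns Fluorescence lifetime (mean emission delay, ns); kept
#'   well below the gate width.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(geometry = array_geometry(),
                            pixels = pixel_bank(geometry),
                            chain = efficiency_chain(),
                            bias_ua = 9, lifetime_ns = 1.5) {
  assert_scalar_pos(bias_ua, "bias_ua")
  assert_scalar_pos(lifetime_ns, "lifetime_ns")
  structure(list(geometry = geometry, pixels = pixels, chain = chain,
                 bias_ua = bias_ua, lifetime_ns = lifetime_ns),
            class = "detector_config")
}

# Expected incident photons per pulse for each dwell x connected pixel:
# focal signal spread by the depth-dependent footprint plus out-of-focus
# background spread by the broad background footprint.
dwell_lambda_matrix <- function(phantom, depth_um, scan, laser, optics,
                                detector) {
  geom <- detector$geometry
  conn <- connected_ids(geom)
  fp <- detector_footprint(depth_um, optics, geom)
  bgfp <- background_footprint(optics, geom)
  # footprint weights indexed by 0-based row-major pixel id
  w_sig <- as.vector(t(fp$weights))[conn + 1L]
  w_bg <- as.vector(t(bgfp$weights))[conn + 1L]

  sl <- excitation_slice(phantom, depth_um, optics)
  cfg <- phantom$config
  xs <- (seq_len(scan$nx) - 0.5) * scan$fov_um / scan$nx
  ys <- (seq_len(scan$ny) - 0.5) * scan$fov_um / scan$ny
  ix <- pmin(pmax(ceiling(xs / cfg$voxel_size_um), 1L), cfg$volume_shape[1])
  iy <- pmin(pmax(ceiling(ys / cfg$voxel_size_um), 1L), cfg$volume_shape[2])
  conc <- sl[ix, iy] # nx x ny, sampled at dwell centres
  conc_dwell <- as.vector(conc) # dwell order: x fast, then y

  es <- suppressWarnings(surface_pulse_energy(depth_um, laser, optics))
  s_rate <- optics$brightness_scale * conc_dwell *
    (as.numeric(es) / laser$e_ref_nj)^2 *
    exp(-2 * depth_um / optics$l_ex_um) * exp(-depth_um / optics$l_em_um)
  b_rate <- background_rate(phantom, depth_um, laser, optics,
                            surface_pulse_energy_nj = es)
  outer(s_rate, w_sig) + b_rate * matrix(w_bg, length(s_rate), length(w_bg),
                                         byrow = TRUE)
}

#' Simulate the photon event stream of one z slice
#'
#' Runs the full unidirectional raster over the slice: per laser pulse and
#' connected pixel, detected fluorescence photons are Poisson-thinned by the
#' efficiency chain and the pixel's bias response (a saturating binary hit
#' per pulse), dark counts arrive as a homogeneous Poisson process across
#' the inter-pulse period, and frame/line triggers are recorded as the
#' FPGA would see them. Event times are folded into 8 ns bins (fluorescence
#' lifetime delay plus ps-scale jitter).
#'
#' @param phantom An `snspd_phantom`.
#' @param depth_um Slice depth (um, absolute).
#' @param scan A [scan_config()].
#' @param laser A [laser_config()].
#' @param optics An [optics_config()].
#' @param detector A [detector_config()].
#' @param gate A [gate_config()] (time base only; gating happens later).
#' @param seed Integer seed for this slice's photon statistics.
#' @return An [event_stream()] with the scan attached.
#' @export
simulate_slice <- function(phantom, depth_um, scan, laser, optics,
                           detector = detector_config(),
                           gate = gate_config(), seed = 1L) {
  geom <- detector$geometry
  conn <- connected_ids(geom)
  pix <- detector$pixels[match(conn, detector$pixels$pixel), ]
  lam <- dwell_lambda_matrix(phantom, depth_um, scan, laser, optics, detector)

  eta <- chain_efficiency_vector(pix, detector$chain, detector$bias_ua)
  p_hit <- 1 - exp(-sweep(lam, 2, eta, `*`)) # dwell x connected pixel

  pp <- scan$pulses_per_pixel
  n_dwell <- scan$nx * scan$ny
  n_frames <- scan$frames_averaged
  n_pulses <- n_dwell * pp * n_frames
  period_ns <- 1e9 / laser$rep_rate_hz
  bin_ns <- gate$bin_ns
  period_bins <- floor(period_ns / bin_ns)

  with_seed(substream_seed(seed, paste0("slice-", round(depth_um))), {
    # fluorescence hits: expand dwell probabilities to every pulse
    pulse_rows <- rep(rep(seq_len(n_dwell), each = pp), times = n_frames)
    hit <- matrix(stats::runif(n_pulses * length(conn)),
                  n_pulses, length(conn)) < p_hit[pulse_rows, , drop = FALSE]
    idx <- which(hit, arr.ind = TRUE)
    n_ev <- nrow(idx)
    if (n_ev) {
      t_ns <- stats::rexp(n_ev, rate = 1 / detector$lifetime_ns) +
        stats::rnorm(n_ev, 0, pix$jitter_sigma_ps[idx[, 2]] / 1000)
      bins <- pmin(pmax(floor(t_ns / bin_ns), 0L), period_bins - 1L)
      fl_events <- tibble::tibble(pulse = idx[, 1] - 1,
                                  pixel = conn[idx[, 2]],
                                  bin = as.integer(bins))
    } else {
      fl_events <- tibble::tibble(pulse = numeric(), pixel = integer(),
                                  bin = integer())
    }
    # dark counts, uniform over pulses and the inter-pulse period
    slice_time_s <- n_pulses / laser$rep_rate_hz
    n_dark_px <- stats::rpois(length(conn), pix$dark_rate_cps * slice_time_s)
    n_dark <- sum(n_dark_px)
    if (n_dark) {
      dk_events <- tibble::tibble(
        pulse = floor(stats::runif(n_dark, 0, n_pulses)),
        pixel = rep(conn, n_dark_px),
        bin = as.integer(floor(stats::runif(n_dark, 0, period_bins))))
    } else {
      dk_events <- tibble::tibble(pulse = numeric(), pixel = integer(),
                                  bin = integer())
    }
    ev <- dplyr::bind_rows(fl_events, dk_events)
    ev <- ev[order(ev$pulse, ev$pixel, ev$bin), ]
    event_stream(n_pulses = n_pulses, rep_rate_hz = laser$rep_rate_hz,
                 geometry = geom, events = ev,
                 triggers = scan_triggers(scan), gate = gate, scan = scan,
                 meta = list(depth_um = depth_um, seed = seed))
  })
}

# Per-connected-pixel total efficiency (transmissions x bias response).
chain_efficiency_vector <- function(pixels, chain, bias_ua) {
  eta_int <- internal_efficiency(bias_ua, eta_max = pixels$eta_max,
                                 i_c_ua = pixels$i_c_ua,
                                 i_sat_ua = pixels$i_sat_ua)
  chain$window_transmission * chain$lens_transmission * eta_int
}
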