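# SNSPD array detection physics: geometry, efficiency chain, bias response,
# Poisson photon thinning with saturating per-pulse binary response, dark
# counts and timing jitter.

#' Detector array geometry
#'
#' A 6x6 grid of 10 um square pixels (3600 um^2 sensitive area). Only 24
#' pixels are connected to readout channels; by default the 3 pixels forming
#' each corner (the corner and its two edge neighbours) are left
#' unconnected, since corner pixels contribute only a minority of counts.
#'
#' Pixel ids are 0-based row-major: id = (row - 1) * cols + (col - 1), so
#' bit 0 of a hit mask is pixel (1, 1).
#'
#' @param rows,cols Grid size.
#' @param pixel_side_um Pixel edge length (um).
#' @param connected Logical rows x cols matrix; default leaves the 12 corner
#'   cluster pixels unconnected.
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(rows = 6L, cols = 6L, pixel_side_um = 10,
                           connected = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  assert_scalar_pos(pixel_side_um, "pixel_side_um")
  if (is.null(connected)) {
    connected <- matrix(TRUE, rows, cols)
    if (rows >= 2L && cols >= 2L) {
      corners <- list(c(1L, 1L), c(1L, cols), c(rows, 1L), c(rows, cols))
      for (cr in corners) {
        r <- cr[1]; c <- cr[2]
        connected[r, c] <- FALSE
        connected[r, if (c == 1L) 2L else cols - 1L] <- FALSE
        connected[if (r == 1L) 2L else rows - 1L, c] <- FALSE
      }
    }
  }
  stopifnot(is.logical(connected), all(dim(connected) == c(rows, cols)))
  structure(list(rows = rows, cols = cols, pixel_side_um = pixel_side_um,
                 connected = connected,
                 total_area_um2 = rows * cols * pixel_side_um^2),
            class = "array_geometry")
}

# 0-based row-major pixel ids of connected pixels.
connected_ids <- function(geometry) {
  idx <- which(t(geometry$connected)) - 1L # t(): row-major order
  sort(idx)
}

# row/col (1-based) from 0-based row-major id.
pixel_row <- function(id, geometry) id %/% geometry$cols + 1L
pixel_col <- function(id, geometry) id %% geometry$cols + 1L

#' Optical efficiency chain
#'
#' @param window_transmission Transmission of the cryostat optical windows.
#' @param lens_transmission Transmission of the focusing lens.
#' @param detector_efficiency Detection efficiency of the bare SNSPD array.
#' @return An object of class `efficiency_chain`.
#' @export
efficiency_chain <- function(window_transmission = 0.935,
                             lens_transmission = 0.99,
                             detector_efficiency = 0.61) {
  assert_fraction(window_transmission, "window_transmission")
  assert_fraction(lens_transmission, "lens_transmission")
  assert_fraction(detector_efficiency, "detector_efficiency")
  structure(list(window_transmission = window_transmission,
                 lens_transmission = lens_transmission,
                 detector_efficiency = detector_efficiency),
            class = "efficiency_chain")
}

#' Total system efficiency from the chain
#'
#' Product of detector efficiency and the two optical transmissions; with
#' the default chain this gives ~0.565, i.e. the ~57% measured system value.
#'
#' @param chain An [efficiency_chain()].
#' @return System detection efficiency in `[0, 1]`.
#' @export
system_efficiency <- function(chain) {
  stopifnot(inherits(chain, "efficiency_chain"))
  chain$detector_efficiency * chain$window_transmission *
    chain$lens_transmission
}

#' Back out detector efficiency from a measured system efficiency
#'
#' @param system_eff Measured system efficiency.
#' @param window_transmission,lens_transmission Optical transmissions.
#' @return Detector efficiency; errors if the result exceeds 1 (unphysical).
#' @export
detector_efficiency_from_system <- function(system_eff,
                                            window_transmission = 0.935,
                                            lens_transmission = 0.99) {
  assert_fraction(system_eff, "system_eff")
  assert_fraction(window_transmission, "window_transmission")
  assert_fraction(lens_transmission, "lens_transmission")
  denom <- window_transmission * lens_transmission
  if (denom <= 0) stop("optical transmission product must be > 0", call. = FALSE)
  eta <- system_eff / denom
  if (eta > 1) {
    stop("implied detector efficiency ", signif(eta, 4),
         " exceeds 1 (unphysical)", call. = FALSE)
  }
  eta
}

#' Per-pixel SNSPD physics parameters
#'
#' Draws a bank of per-pixel parameters: critical currents from a narrow
#' normal distribution around ~10 uA, a saturation (plateau-onset) current
#' at a fixed fraction of I_c (~7.5 uA), dark rates and timing jitter.
#'
#' @param geometry An [array_geometry()].
#' @param eta_max Internal detection efficiency on the bias plateau.
#' @param i_c_mean_ua,i_c_sd_ua Critical current distribution (uA).
#' @param i_sat_frac Plateau onset as a fraction of I_c.
#' @param dark_rate_cps Dark-count rate per pixel (counts/s). The default
#'   divides the measured array total (9.7e3 s^-1) over the 36 elements,
#'   the "per pixel on average" convention; pass
#'   `9700 / sum(geometry$connected)` for the per-connected-channel
#'   convention.
#' @param jitter_sigma_ps Gaussian timing jitter sigma (ps); 16.99 ps
#'   corresponds to a 40 ps FWHM.
#' @param seed Integer seed for the parameter draws.
#' @return A tibble with one row per pixel: `pixel` (0-based id), `row`,
#'   `col`, `connected`, `eta_max`, `i_c_ua`, `i_sat_ua`, `dark_rate_cps`,
#'   `jitter_sigma_ps`.
#' @export
pixel_bank <- function(geometry = array_geometry(), eta_max = 0.61,
                       i_c_mean_ua = 10, i_c_sd_ua = 0.3,
                       i_sat_frac = 0.75, dark_rate_cps = 9700 / 36,
                       jitter_sigma_ps = 16.99, seed = 1L) {
  assert_fraction(eta_max, "eta_max")
  assert_scalar_pos(i_c_mean_ua, "i_c_mean_ua")
  assert_scalar_pos(i_c_sd_ua, "i_c_sd_ua", strict = FALSE)
  assert_fraction(i_sat_frac, "i_sat_frac")
  assert_scalar_pos(dark_rate_cps, "dark_rate_cps", strict = FALSE)
  assert_scalar_pos(jitter_sigma_ps, "jitter_sigma_ps", strict = FALSE)
  n <- geometry$rows * geometry$cols
  ids <- 0:(n - 1L)
  i_c <- with_seed(substream_seed(seed, "pixel-bank"), {
    pmax(stats::rnorm(n, i_c_mean_ua, i_c_sd_ua), i_c_mean_ua / 2)
  })
  tibble::tibble(
    pixel = ids,
    row = pixel_row(ids, geometry),
    col = pixel_col(ids, geometry),
    connected = geometry$connected[cbind(pixel_row(ids, geometry),
                                         pixel_col(ids, geometry))],
    eta_max = eta_max,
    i_c_ua = i_c,
    i_sat_ua = i_sat_frac * i_c,
    dark_rate_cps = dark_rate_cps,
    jitter_sigma_ps = jitter_sigma_ps)
}

#' Internal detection efficiency versus bias current
#'
#' Error-function sigmoid rising to the plateau: within 1% of `eta_max` for
#' bias >= I_sat, near zero at zero bias, and exactly zero above I_c where
#' superconductivity (and hence detection) is lost. Monotone non-decreasing
#' on `[0, I_c]`.
#'
#' @param bias_ua Bias current (uA), scalar or vector.
#' @param eta_max Plateau internal efficiency.
#' @param i_c_ua Critical current (uA).
#' @param i_sat_ua Plateau-onset current (uA), `0 < i_sat_ua < i_c_ua`.
#' @return Internal efficiency in `[0, eta_max]`.
#' @export
internal_efficiency <- function(bias_ua, eta_max = 0.61, i_c_ua = 10,
                                i_sat_ua = 7.5) {
  stopifnot(all(bias_ua >= 0), i_sat_ua > 0, i_sat_ua < i_c_ua)
  mid <- i_sat_ua / 2
  sc <- (i_sat_ua - mid) / stats::qnorm(0.995) # plateau: >= 0.99 eta at I_sat
  eta <- eta_max * stats::pnorm((bias_ua - mid) / sc)
  eta[bias_ua > i_c_ua] <- 0
  eta
}

# Per-pixel total detection efficiency (optics transmissions x internal
# efficiency at the operating bias), as a rows x cols matrix.
pixel_efficiency_matrix <- function(pixels, geometry, chain, bias_ua) {
  eta_int <- internal_efficiency(bias_ua, eta_max = pixels$eta_max,
                                 i_c_ua = pixels$i_c_ua,
                                 i_sat_ua = pixels$i_sat_ua)
  eta <- chain$window_transmission * chain$lens_transmission * eta_int
  m <- matrix(0, geometry$rows, geometry$cols)
  m[cbind(pixels$row, pixels$col)] <- eta
  m * geometry$connected
}

#' Detect one laser pulse on the array
#'
#' Per pixel, the detected photon number is Poisson with mean
#' `efficiency * expected_photons`; the pixel reports a (saturating) binary
#' hit iff at least one photon is detected. Unconnected pixels never report.
#' Hit times are the fluorescence arrival (exponential lifetime delay after
#' the pulse) plus Gaussian timing jitter.
#'
#' @param expected_photons rows x cols matrix of expected incident photons.
#' @param pixels A [pixel_bank()] tibble.
#' @param geometry An [array_geometry()].
#' @param chain An [efficiency_chain()] (its `detector_efficiency` is
#'   superseded by the per-pixel bias response).
#' @param bias_ua Operating bias current (uA).
#' @param lifetime_ns Fluorescence lifetime (ns), the mean emission delay.
#' @return List with `hits` (logical rows x cols) and `times_ns` (numeric
#'   rows x cols, NA where no hit): hit times after the laser pulse.
#' @export
detect_pulse <- function(expected_photons, pixels,
                         geometry = array_geometry(),
                         chain = efficiency_chain(), bias_ua = 9,
                         lifetime_ns = 1.5) {
  if (any(expected_photons < 0)) {
    stop("expected photon numbers must be non-negative", call. = FALSE)
  }
  eta <- pixel_efficiency_matrix(pixels, geometry, chain, bias_ua)
  p <- 1 - exp(-eta * expected_photons)
  hits <- matrix(stats::runif(length(p)) < p, geometry$rows, geometry$cols)
  times <- matrix(NA_real_, geometry$rows, geometry$cols)
  n <- sum(hits)
  if (n) {
    jit <- matrix(pixels$jitter_sigma_ps, geometry$rows,
                  geometry$cols)[hits] / 1000
    times[hits] <- stats::rexp(n, rate = 1 / lifetime_ns) +
      stats::rnorm(n, 0, jit)
  }
  list(hits = hits, times_ns = times)
}

#' Simulate dark-count events
#'
#' Homogeneous Poisson process on each connected pixel at its configured
#' dark rate.
#'
#' @param duration_s Observation time (s).
#' @param pixels A [pixel_bank()] tibble.
#' @return A tibble with `pixel` (0-based id) and `time_s`, sorted by time.
#' @export
dark_events <- function(duration_s, pixels) {
  assert_scalar_pos(duration_s, "duration_s")
  conn <- pixels[pixels$connected & pixels$dark_rate_cps > 0, ]
  if (!nrow(conn)) return(tibble::tibble(pixel = integer(), time_s = numeric()))
  counts <- stats::rpois(nrow(conn), conn$dark_rate_cps * duration_s)
  ev <- tibble::tibble(
    pixel = rep(conn$pixel, counts),
    time_s = stats::runif(sum(counts), 0, duration_s))
  ev[order(ev$time_s), ]
}

#' Average dark rate per pixel from an array total
#'
#' @param total_rate_cps Total array dark-count rate (counts/s).
#' @param n_elements Number of elements to average over; 36 for the
#'   per-element convention, 24 for per connected channel.
#' @return Counts per second per pixel.
#' @export
dark_rate_per_pixel <- function(total_rate_cps, n_elements = 36L) {
  assert_scalar_pos(total_rate_cps, "total_rate_cps", strict = FALSE)
  total_rate_cps / n_elements
}

#' Timing-jitter histogram with Gaussian fit
#'
#' Histograms the differences between measured and true arrival times and
#' fits a Gaussian; the timing jitter is reported as the fitted FWHM,
#' `2 * sqrt(2 log 2) * sigma ~= 2.3548 sigma`.
#'
#' @param true_times_ps,measured_times_ps Equal-length times (ps).
#' @param bin_ps Histogram bin width (ps).
#' @return List with `histogram` (tibble `delay_ps`, `count`), `sigma_ps`,
#'   `fwhm_ps`, `degenerate` (TRUE when the spread collapses to ~one bin).
#' @export
jitter_histogram <- function(true_times_ps, measured_times_ps, bin_ps = 4) {
  if (length(true_times_ps) != length(measured_times_ps)) {
    stop("time vectors must have equal length", call. = FALSE)
  }
  if (length(true_times_ps) < 100L) {
    stop("need at least 100 events for a reliable jitter fit", call. = FALSE)
  }
  assert_scalar_pos(bin_ps, "bin_ps")
  d <- measured_times_ps - true_times_ps
  rng <- range(d)
  breaks <- seq(floor(rng[1] / bin_ps) * bin_ps - bin_ps / 2,
                ceiling(rng[2] / bin_ps) * bin_ps + bin_ps, by = bin_ps)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  hist_tbl <- tibble::tibble(delay_ps = h$mids, count = h$counts)
  degenerate <- stats::sd(d) < bin_ps / 2
  if (degenerate) {
    warning("jitter spread below the bin width; FWHM limited by binning",
            call. = FALSE)
    return(list(histogram = hist_tbl, sigma_ps = fwhm_to_sigma(bin_ps),
                fwhm_ps = bin_ps, degenerate = TRUE))
  }
  start <- list(A = max(h$counts), mu = mean(d), s = stats::sd(d))
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(delay_ps - mu)^2 / (2 * s^2)),
    data = hist_tbl, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sigma <- abs(stats::coef(fit)[["s"]])
  list(histogram = hist_tbl, sigma_ps = sigma,
       fwhm_ps = sigma_to_fwhm(sigma), degenerate = FALSE)
}
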