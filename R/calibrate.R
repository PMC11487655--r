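# Background-coefficient calibration: solve for the out-of-focus background
# level that puts the image-statistic SBR at a chosen value (typically 1) at
# a chosen depth, using the closed-form expectation of the gated digital
# image rather than simulation.

#' Predicted image-statistic SBR of a gated digital slice
#'
#' Closed-form expectation of the per-slice SBR the pipeline would measure:
#' per dwell and connected pixel the per-pulse hit probability is
#' `1 - exp(-eta * lambda - r_dark * tau_gate)`; dwell values are sums of
#' `pulses_per_pixel * frames_averaged` Bernoulli draws, so the signal/
#' background means and the background standard deviation (shot variance
#' plus spatial variance of the mean) follow in closed form. No random
#' numbers are drawn.
#'
#' @param phantom An `snspd_phantom`.
#' @param depth_um Slice depth (um).
#' @param scan,laser,optics,detector,gate Pipeline configuration objects.
#' @param dilation_um Mask exclusion band for [ground_truth_masks()].
#' @return Predicted `mean_sbr` (scalar).
#' @export
predicted_slice_sbr <- function(phantom, depth_um, scan, laser, optics,
                                detector = detector_config(),
                                gate = gate_config(), dilation_um = 10) {
  lam <- dwell_lambda_matrix(phantom, depth_um, scan, laser, optics, detector)
  conn <- connected_ids(detector$geometry)
  pix <- detector$pixels[match(conn, detector$pixels$pixel), ]
  eta <- chain_efficiency_vector(pix, detector$chain, detector$bias_ua)
  tau_gate <- gate$width_bins * gate$bin_ns * 1e-9
  dark_gate <- pix$dark_rate_cps * tau_gate
  p <- 1 - exp(-(sweep(lam, 2, eta, `*`) +
                   matrix(dark_gate, nrow(lam), length(conn), byrow = TRUE)))
  n_draws <- scan$pulses_per_pixel * scan$frames_averaged
  mu <- n_draws * rowSums(p)
  v <- n_draws * rowSums(p * (1 - p))
  masks <- suppressWarnings(
    ground_truth_masks(phantom, depth_um, dilation_um,
                       grid = list(nx = scan$nx, ny = scan$ny,
                                   fov_um = scan$fov_um)))
  sig <- as.vector(masks$signal)
  bg <- as.vector(masks$background)
  if (!any(sig) || sum(bg) < 2) {
    stop("slice has no usable signal/background pixels for SBR prediction",
         call. = FALSE)
  }
  mu_s <- mean(mu[sig])
  mu_b <- mean(mu[bg])
  sigma_b <- sqrt(mean(v[bg]) + stats::var(mu[bg]))
  if (sigma_b == 0) return(0) # fully saturated image: no contrast left
  (mu_s - mu_b) / sigma_b
}

#' Calibrate the out-of-focus background coefficient
#'
#' Solves for the `background_coefficient` at which the predicted
#' image-statistic SBR ([predicted_slice_sbr()]) equals `target_sbr` at
#' `target_depth_um` — i.e. places the imaging depth limit at the target
#' depth. The calibrated value is recorded in the returned optics object
#' and should be stated in every downstream report.
#'
#' @inheritParams predicted_slice_sbr
#' @param target_depth_um Depth at which the SBR should equal the target.
#' @param target_sbr Target SBR (1 defines the depth limit).
#' @return The `optics_config` with `background_coefficient` replaced and a
#'   `calibration` attribute describing the fit.
#' @export
calibrate_background <- function(phantom, scan, laser, optics,
                                 detector = detector_config(),
                                 gate = gate_config(),
                                 target_depth_um = 1150, target_sbr = 1,
                                 dilation_um = 10) {
  f <- function(log10_bc) {
    o <- optics
    o$background_coefficient <- 10^log10_bc
    predicted_slice_sbr(phantom, target_depth_um, scan, laser, o,
                        detector, gate, dilation_um) - target_sbr
  }
  lo <- -10; hi <- 3
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0) {
    stop("predicted SBR below target even with negligible background; ",
         "increase brightness or reduce the target depth", call. = FALSE)
  }
  if (fhi > 0) {
    stop("predicted SBR above target even at maximal background",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-4)
  out <- optics
  out$background_coefficient <- 10^root$root
  attr(out, "calibration") <- list(target_depth_um = target_depth_um,
                                   target_sbr = target_sbr,
                                   background_coefficient = 10^root$root)
  out
}
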