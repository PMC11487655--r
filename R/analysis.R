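# Quantitative image analyses: signal-to-background ratio, threshold
# segmentation, vessel-width line profiles, depth-limit extraction,
# count-rate budget, count map and bias-sweep diagnostics.

#' Signal-to-background ratio of an image
#'
#' `mean_SBR = (mu_S - mu_BR) / sigma_BR` and
#' `max_SBR = (max_S - mu_BR) / sigma_BR`, where mu_S/max_S are the mean and
#' maximum over the signal mask and mu_BR/sigma_BR the mean and standard
#' deviation over the background mask. Invariant under affine rescaling of
#' the image intensities.
#'
#' @param image Numeric matrix or `snspd_image`.
#' @param signal_mask,background_mask Disjoint logical masks, background
#'   with at least 2 pixels.
#' @return One-row tibble: `mu_s`, `max_s`, `mu_br`, `sigma_br`,
#'   `mean_sbr`, `max_sbr`, `empty_signal`.
#' @export
compute_sbr <- function(image, signal_mask, background_mask) {
  if (inherits(image, "snspd_image")) image <- image$data
  stopifnot(all(dim(image) == dim(signal_mask)),
            all(dim(image) == dim(background_mask)))
  if (any(signal_mask & background_mask)) {
    stop("signal and background masks must be disjoint", call. = FALSE)
  }
  if (sum(background_mask) < 2L) {
    stop("background mask needs at least 2 pixels", call. = FALSE)
  }
  bg <- image[background_mask]
  mu_br <- mean(bg)
  sigma_br <- stats::sd(bg)
  if (sigma_br == 0) {
    stop("background standard deviation is zero; SBR undefined",
         call. = FALSE)
  }
  empty <- !any(signal_mask)
  if (empty) {
    warning("empty signal mask; SBR undefined for this slice", call. = FALSE)
    mu_s <- NA_real_; max_s <- NA_real_
  } else {
    sig <- image[signal_mask]
    mu_s <- mean(sig); max_s <- max(sig)
  }
  tibble::tibble(mu_s = mu_s, max_s = max_s, mu_br = mu_br,
                 sigma_br = sigma_br,
                 mean_sbr = (mu_s - mu_br) / sigma_br,
                 max_sbr = (max_s - mu_br) / sigma_br,
                 empty_signal = empty)
}

#' Segment vessels into signal and background masks
#'
#' `method = "threshold"`: the image is Gaussian-smoothed, pixels above the
#' `q` quantile become signal and pixels below the `q_b` quantile become
#' background; intermediate pixels are excluded (a conservative band,
#' mirroring high-probability thresholding). `method = "ground_truth"`
#' delegates to the phantom's [ground_truth_masks()].
#'
#' @param image Numeric matrix or `snspd_image`.
#' @param method `"threshold"` or `"ground_truth"`.
#' @param q,q_b Signal / background quantiles, `q > q_b`.
#' @param smooth_sigma_px Gaussian smoothing sigma (pixels).
#' @param phantom,slice_z_um,dilation_um,grid Passed to
#'   [ground_truth_masks()] for the ground-truth method.
#' @return `list(signal, background)` logical masks.
#' @export
segment_vessels <- function(image, method = c("threshold", "ground_truth"),
                            q = 0.95, q_b = 0.6, smooth_sigma_px = 1,
                            phantom = NULL, slice_z_um = NULL,
                            dilation_um = 0, grid = NULL) {
  method <- match.arg(method)
  if (method == "ground_truth") {
    stopifnot(!is.null(phantom), !is.null(slice_z_um))
    return(ground_truth_masks(phantom, slice_z_um, dilation_um, grid))
  }
  if (inherits(image, "snspd_image")) image <- image$data
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  if (q <= q_b) {
    stop("signal quantile `q` must exceed background quantile `q_b`",
         call. = FALSE)
  }
  sm <- if (smooth_sigma_px > 0.2) {
    EBImage::gblur(image, sigma = smooth_sigma_px)
  } else image
  thr_s <- stats::quantile(sm, q)
  thr_b <- stats::quantile(sm, q_b)
  if (thr_s <= thr_b) {
    stop("degenerate thresholds (signal cutoff <= background cutoff); ",
         "adjust `q`/`q_b`", call. = FALSE)
  }
  signal <- sm >= thr_s
  background <- sm <= thr_b
  if (!any(background)) {
    stop("threshold quantiles leave an empty background mask", call. = FALSE)
  }
  list(signal = signal, background = background)
}

# Jaccard overlap of two masks (used to compare segmentations).
mask_jaccard <- function(a, b) sum(a & b) / sum(a | b)

#' Vessel width from a line profile
#'
#' Extracts a profile across a vessel by averaging `line_width_px` parallel
#' samples (wider averaging can only broaden the profile, so the result is
#' an upper bound on the true width), fits a Gaussian plus constant offset,
#' and reports `fwhm = 2.3548 * sigma_fit * pixel_size`.
#'
#' @param image Numeric matrix or `snspd_image`.
#' @param line_endpoints 2 x 2 matrix, rows = profile start/end in (x, y)
#'   pixel coordinates; the profile should cross exactly one vessel.
#' @param line_width_px Number of parallel samples averaged (5 or 10 in the
#'   standard protocol).
#' @param pixel_size_um Image pixel size (um).
#' @param depth_um Optional slice depth carried into the result.
#' @return One-row tibble: `fwhm_um`, `fwhm_se_um`, `sigma_px`, `center_px`,
#'   `offset`, `amplitude`, `converged`, `depth_um`.
#' @export
vessel_width <- function(image, line_endpoints, line_width_px = 5,
                         pixel_size_um = 1, depth_um = NA_real_) {
  if (inherits(image, "snspd_image")) image <- image$data
  p0 <- as.numeric(line_endpoints[1, ]); p1 <- as.numeric(line_endpoints[2, ])
  len <- sqrt(sum((p1 - p0)^2))
  n_s <- max(ceiling(len) + 1L, 5L)
  t <- seq(0, 1, length.out = n_s)
  dirv <- (p1 - p0) / len
  perp <- c(-dirv[2], dirv[1])
  offs <- seq_len(line_width_px) - (line_width_px + 1) / 2
  prof_mat <- vapply(offs, function(o) {
    xs <- p0[1] + t * (p1[1] - p0[1]) + o * perp[1]
    ys <- p0[2] + t * (p1[2] - p0[2]) + o * perp[2]
    bilinear(image, xs, ys) # image indexed [x, y]
  }, numeric(n_s))
  profile <- rowMeans(prof_mat)
  pos <- t * len # pixels along the profile
  fail <- tibble::tibble(fwhm_um = NA_real_, fwhm_se_um = NA_real_,
                         sigma_px = NA_real_, center_px = NA_real_,
                         offset = NA_real_, amplitude = NA_real_,
                         converged = FALSE, depth_um = depth_um)
  if (stats::sd(profile) == 0) {
    warning("flat profile; width fit not possible", call. = FALSE)
    return(fail)
  }
  base <- min(profile)
  w <- pmax(profile - base, 0)
  mu0 <- sum(pos * w) / sum(w)
  s0 <- sqrt(pmax(sum((pos - mu0)^2 * w) / sum(w), 0.25))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      profile ~ k + A * exp(-(pos - mu)^2 / (2 * s^2)),
      data = data.frame(profile = profile, pos = pos),
      start = list(k = base, A = max(profile) - base, mu = mu0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("vessel width fit did not converge; entry flagged",
            call. = FALSE)
    return(fail)
  }
  cf <- stats::coef(fit)
  s_fit <- abs(cf[["s"]])
  se <- tryCatch(summary(fit)$coefficients["s", "Std. Error"],
                 error = function(e) NA_real_)
  if (cf[["A"]] <= 0 || s_fit > len) {
    warning("vessel width fit degenerate; entry flagged", call. = FALSE)
    return(fail)
  }
  tibble::tibble(fwhm_um = sigma_to_fwhm(s_fit) * pixel_size_um,
                 fwhm_se_um = sigma_to_fwhm(se) * pixel_size_um,
                 sigma_px = s_fit, center_px = cf[["mu"]],
                 offset = cf[["k"]], amplitude = cf[["A"]],
                 converged = TRUE, depth_um = depth_um)
}

#' Summarise vessel-width profiles
#'
#' @param widths Tibble of [vessel_width()] rows.
#' @return One-row tibble: `n`, `mean_fwhm_um`, `sd_fwhm_um`,
#'   `mean_depth_um` (non-converged entries are excluded).
#' @export
vessel_width_summary <- function(widths) {
  ok <- widths[widths$converged, ]
  if (!nrow(ok)) stop("no converged width fits to summarise", call. = FALSE)
  tibble::tibble(n = nrow(ok),
                 mean_fwhm_um = mean(ok$fwhm_um),
                 sd_fwhm_um = stats::sd(ok$fwhm_um),
                 mean_depth_um = mean(ok$depth_um))
}

#' Depth limit from an SBR-versus-depth curve
#'
#' The imaging depth limit is where the SBR falls to 1. The first crossing
#' is located by linear interpolation in (depth, log SBR); if the curve
#' never crosses, the deepest depth is returned with `limit_reached = FALSE`.
#' Noisy curves with several crossings use the first and warn.
#'
#' @param sbr_vs_depth Data frame with `depth_um` and `sbr` (positive),
#'   at least two rows.
#' @return One-row tibble: `depth_limit_um`, `limit_reached`, `n_crossings`.
#' @export
depth_limit <- function(sbr_vs_depth) {
  d <- sbr_vs_depth[order(sbr_vs_depth$depth_um), ]
  if (nrow(d) < 2L) stop("need at least two depths", call. = FALSE)
  if (any(d$sbr <= 0)) stop("SBR values must be positive", call. = FALSE)
  ls <- log(d$sbr)
  below <- ls < 0
  cross <- which(!below[-nrow(d)] & below[-1])
  n_cross <- length(cross)
  if (n_cross == 0L) {
    if (all(below)) {
      warning("SBR below 1 at every depth; returning the shallowest depth",
              call. = FALSE)
      return(tibble::tibble(depth_limit_um = d$depth_um[1],
                            limit_reached = TRUE, n_crossings = 0L))
    }
    return(tibble::tibble(depth_limit_um = max(d$depth_um),
                          limit_reached = FALSE, n_crossings = 0L))
  }
  if (n_cross > 1L) {
    warning("SBR curve crosses 1 more than once; using the first crossing",
            call. = FALSE)
  }
  i <- cross[1]
  z <- d$depth_um[i] + (0 - ls[i]) * (d$depth_um[i + 1] - d$depth_um[i]) /
    (ls[i + 1] - ls[i])
  tibble::tibble(depth_limit_um = z, limit_reached = TRUE,
                 n_crossings = n_cross)
}

#' Count-rate budget of an event stream
#'
#' Rates are referenced to the wall time implied by the repetition rate
#' (`n_pulses / rep_rate`). The centre rate averages the four central array
#' pixels; the peak estimate is the rate over the brightest decile of scan
#' dwells (the "brightest spots" figure); the dark fraction uses the
#' configured per-pixel dark rates when a pixel bank is supplied.
#'
#' @param stream An [event_stream()].
#' @param scan A [scan_config()]; defaults to the stream's.
#' @param pixels Optional [pixel_bank()] for the expected dark rate.
#' @return One-row tibble: `wall_time_s`, `array_total_cps`,
#'   `center_pixel_cps`, `mean_pixel_cps`, `peak_decile_cps`,
#'   `dark_fraction`.
#' @export
count_rate_budget <- function(stream, scan = NULL, pixels = NULL) {
  if (!nrow(stream$events)) stop("empty event stream", call. = FALSE)
  if (is.null(scan)) scan <- stream$scan
  geom <- stream$geometry
  wall <- stream$n_pulses / stream$rep_rate_hz
  ev <- stream$events
  # per detector pixel, at most one count per pulse (saturating readout)
  key <- ev$pulse * 64 + ev$pixel
  ev1 <- ev[!duplicated(key), ]
  per_pixel <- table(factor(ev1$pixel, levels = 0:(geom$rows * geom$cols - 1L)))
  rates <- as.numeric(per_pixel) / wall
  rc <- c(geom$rows / 2, geom$rows / 2 + 1)
  cc <- c(geom$cols / 2, geom$cols / 2 + 1)
  center_ids <- as.vector(outer(rc - 1, cc - 1,
                                function(r, c) r * geom$cols + c))
  conn <- connected_ids(geom)
  peak <- NA_real_
  if (!is.null(scan)) {
    pp <- scan$pulses_per_pixel
    dwell <- ev1$pulse %/% pp
    per_dwell <- table(dwell)
    n_top <- max(1L, floor(length(per_dwell) / 10))
    top <- sort(as.numeric(per_dwell), decreasing = TRUE)[seq_len(n_top)]
    peak <- sum(top) / (n_top * pp / stream$rep_rate_hz)
  }
  dark_frac <- NA_real_
  if (!is.null(pixels)) {
    exp_dark <- sum(pixels$dark_rate_cps[pixels$connected]) * wall
    dark_frac <- min(exp_dark / nrow(ev1), 1)
  }
  tibble::tibble(wall_time_s = wall,
                 array_total_cps = sum(rates),
                 center_pixel_cps = mean(rates[center_ids + 1L]),
                 mean_pixel_cps = mean(rates[conn + 1L]),
                 peak_decile_cps = peak,
                 dark_fraction = dark_frac)
}

#' Normalised per-pixel count map
#'
#' Per-pixel totals over the stream, normalised to a maximum of 1;
#' unconnected pixels are reported as `NA` (absent).
#'
#' @param stream An [event_stream()].
#' @param geometry An [array_geometry()]; defaults to the stream's.
#' @return An object of class `snspd_count_map`: `map` (rows x cols),
#'   `total_counts`.
#' @export
count_map <- function(stream, geometry = NULL) {
  if (!nrow(stream$events)) stop("empty event stream", call. = FALSE)
  if (is.null(geometry)) geometry <- stream$geometry
  ev <- stream$events
  key <- ev$pulse * 64 + ev$pixel
  ev1 <- ev[!duplicated(key), ]
  per_pixel <- table(factor(ev1$pixel, levels = 0:(geometry$rows * geometry$cols - 1L)))
  m <- matrix(NA_real_, geometry$rows, geometry$cols)
  ids <- connected_ids(geometry)
  counts <- as.numeric(per_pixel)
  m[cbind(pixel_row(ids, geometry), pixel_col(ids, geometry))] <-
    counts[ids + 1L]
  structure(list(map = m / max(m, na.rm = TRUE),
                 total_counts = sum(counts)),
            class = "snspd_count_map")
}

#' @export
print.snspd_count_map <- function(x, ...) {
  cat(sprintf("<snspd_count_map> total %s counts\n",
              format(x$total_counts, big.mark = ",")))
  print(round(x$map, 3))
  invisible(x)
}

#' Bias-current sweep of a pixel
#'
#' Simulates photon counting at a fixed illumination over a bias-current
#' grid: counts rise along the sigmoidal internal-efficiency curve, plateau
#' above the saturation current, and drop to exactly zero above the
#' critical current where superconductivity is lost. The critical current
#' is estimated as the first current with zero counts after the plateau.
#'
#' @param pixel One row of a [pixel_bank()] (or a list with `eta_max`,
#'   `i_c_ua`, `i_sat_ua`).
#' @param currents_ua Sorted bias currents (uA).
#' @param lambda Expected photons per trial at the pixel.
#' @param n_pulses Trials per bias point.
#' @return An object of class `snspd_bias_sweep`: tibble `sweep`
#'   (`bias_ua`, `counts`, `normalized`), `i_c_estimate_ua`, `i_c_true_ua`.
#' @export
bias_sweep <- function(pixel, currents_ua, lambda = 0.5, n_pulses = 2000L) {
  if (is.unsorted(currents_ua)) {
    stop("`currents_ua` must be sorted increasing", call. = FALSE)
  }
  eta <- internal_efficiency(currents_ua, eta_max = pixel$eta_max,
                             i_c_ua = pixel$i_c_ua,
                             i_sat_ua = pixel$i_sat_ua)
  counts <- stats::rbinom(length(currents_ua), n_pulses, 1 - exp(-eta * lambda))
  peak <- which.max(counts)
  zero_after <- which(counts == 0 & seq_along(counts) > peak)
  i_c_est <- if (length(zero_after)) currents_ua[zero_after[1]] else NA_real_
  structure(list(
    sweep = tibble::tibble(bias_ua = currents_ua, counts = counts,
                           normalized = counts / max(counts)),
    i_c_estimate_ua = i_c_est,
    i_c_true_ua = pixel$i_c_ua),
    class = "snspd_bias_sweep")
}

#' @export
print.snspd_bias_sweep <- function(x, ...) {
  cat(sprintf("<snspd_bias_sweep> %d bias points, I_c estimate %.3g uA (true %.3g)\n",
              nrow(x$sweep), x$i_c_estimate_ua, x$i_c_true_ua))
  invisible(x)
}
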