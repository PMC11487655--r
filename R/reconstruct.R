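# Image reconstruction from event streams (digital path) and per-dwell
# analog values (analog path), with trigger bookkeeping and digital/analog
# line alignment.

#' Raster scan configuration
#'
#' Unidirectional row-major raster: for each averaged frame, lines are
#' scanned top to bottom and pixels left to right, with a fixed number of
#' laser pulses per pixel dwell. The defaults mirror a deep-stack protocol
#' (256 x 256 pixels over a ~300 um field, 10 pulses per pixel, 10 frames
#' averaged, 5 um z steps), giving 6.55 s of dwell time per slice at 1 MHz.
#'
#' @param nx,ny Image size in pixels.
#' @param pulses_per_pixel Laser pulses per pixel dwell.
#' @param frames_averaged Frames accumulated per slice.
#' @param fov_um Lateral field of view (um).
#' @param z_step_um Axial step between slices (um).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(nx = 256L, ny = 256L, pulses_per_pixel = 10L,
                        frames_averaged = 10L, fov_um = 300, z_step_um = 5) {
  for (v in c("nx", "ny", "pulses_per_pixel", "frames_averaged")) {
    val <- get(v)
    if (length(val) != 1L || val < 1 || val != round(val)) {
      stop("`", v, "` must be a positive integer", call. = FALSE)
    }
  }
  assert_scalar_pos(fov_um, "fov_um")
  assert_scalar_pos(z_step_um, "z_step_um")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pulses_per_pixel = as.integer(pulses_per_pixel),
                 frames_averaged = as.integer(frames_averaged),
                 fov_um = fov_um, z_step_um = z_step_um),
            class = "scan_config")
}

#' Dwell time per z slice
#'
#' `nx * ny * pulses_per_pixel * frames_averaged / rep_rate`: the default
#' scan at 1 MHz gives 6.5536 s.
#'
#' @param scan A [scan_config()].
#' @param laser A [laser_config()].
#' @return Seconds of laser time per slice.
#' @export
dwell_time_per_slice <- function(scan, laser) {
  scan$nx * scan$ny * scan$pulses_per_pixel * scan$frames_averaged /
    laser$rep_rate_hz
}

# Expected trigger layout for a scan: line trigger on the first pulse of
# every line, frame trigger on the first pulse of every frame.
scan_triggers <- function(scan) {
  pp <- scan$pulses_per_pixel
  line_starts <- (seq_len(scan$ny * scan$frames_averaged) - 1) *
    (scan$nx * pp)
  frame_starts <- (seq_len(scan$frames_averaged) - 1) *
    (scan$nx * scan$ny * pp)
  tibble::tibble(pulse = line_starts,
                 frame = line_starts %in% frame_starts,
                 line = TRUE)
}

# Single-slice image container.
new_image <- function(data, mode, scan, depth_um = NA_real_) {
  structure(list(data = data, mode = mode, scan = scan, depth_um = depth_um),
            class = "snspd_image")
}

#' @export
print.snspd_image <- function(x, ...) {
  cat(sprintf("<snspd_image> %d x %d, mode %s, depth %s um, range [%.3g, %.3g]\n",
              nrow(x$data), ncol(x$data), x$mode, format(x$depth_um),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Reconstruct a digital image from gated/ungated counts
#'
#' Pixel values are the sums, over the pixel's laser pulses and all averaged
#' frames, of the per-pulse hit counts over the connected detector pixels
#' (the digital analogue of the analog channel summation). Lines are
#' delimited by the recorded line triggers; a line with fewer pulses than
#' `nx * pulses_per_pixel` before the next trigger is dropped with a
#' warning. Reconstruction is deterministic.
#'
#' @param counts An `snspd_counts` object from [gated_count()] or
#'   [ungated_count()].
#' @param scan A [scan_config()]; defaults to the one carried by the stream.
#' @return An `snspd_image` whose `data` is an `nx x ny` matrix (x = fast
#'   scan axis as rows).
#' @export
reconstruct_digital <- function(counts, scan = NULL) {
  stopifnot(inherits(counts, "snspd_counts"))
  if (is.null(scan)) scan <- counts$scan
  stopifnot(!is.null(scan))
  trg <- counts$triggers
  n_lines_exp <- scan$ny * scan$frames_averaged
  line_starts <- sort(trg$pulse[trg$line])
  n_frames_found <- sum(trg$frame)
  if (length(line_starts) != n_lines_exp ||
      n_frames_found != scan$frames_averaged) {
    stop(sprintf(paste0("trigger count inconsistent with scan geometry: ",
                        "expected %d line / %d frame triggers, found %d / %d"),
                 n_lines_exp, scan$frames_averaged, length(line_starts),
                 n_frames_found), call. = FALSE)
  }
  pp <- scan$pulses_per_pixel
  line_len <- scan$nx * pp
  line_end <- c(line_starts[-1], counts$n_pulses)
  short <- (line_end - line_starts) < line_len
  if (any(short)) {
    warning(sum(short), " partial trailing line(s) dropped", call. = FALSE)
  }
  img <- matrix(0, scan$nx, scan$ny)
  h <- counts$hits
  if (nrow(h)) {
    line_id <- findInterval(h$pulse, line_starts) # 1-based line index
    offset <- h$pulse - line_starts[line_id]
    ok <- offset < line_len & !short[line_id]
    if (any(ok)) {
      x <- offset[ok] %/% pp + 1L
      y <- (line_id[ok] - 1L) %% scan$ny + 1L
      acc <- rowsum(h$weight[ok], group = (y - 1L) * scan$nx + x)
      img[as.numeric(rownames(acc))] <- acc[, 1]
    }
  }
  new_image(img, counts$mode, scan)
}

#' Reconstruct an analog image from per-dwell values
#'
#' Frames are averaged; geometry conventions match the digital path.
#'
#' @param analog_values Tibble from [analog_sum()] (`frame`, `x`, `y`,
#'   `value_mv`), one row per pixel dwell per frame.
#' @param scan A [scan_config()].
#' @return An `snspd_image` (mode `"analog"`, values in mV averaged over
#'   frames).
#' @export
reconstruct_analog <- function(analog_values, scan) {
  expected <- scan$nx * scan$ny * scan$frames_averaged
  if (nrow(analog_values) != expected) {
    stop("expected ", expected, " dwell values (nx * ny * frames), got ",
         nrow(analog_values), call. = FALSE)
  }
  img <- matrix(0, scan$nx, scan$ny)
  acc <- rowsum(analog_values$value_mv,
                group = (analog_values$y - 1L) * scan$nx + analog_values$x)
  img[as.numeric(rownames(acc))] <- acc[, 1] / scan$frames_averaged
  new_image(img, "analog", scan)
}

#' Align a digital image line to its analog counterpart
#'
#' Residual synchronisation between the FPGA stream and the DAQ raster is
#' recovered by maximising the normalised cross-correlation between
#' corresponding lines over integer shifts; ties break toward zero shift.
#'
#' @param digital_line,analog_line Equal-length numeric vectors.
#' @param max_shift Maximum |shift| searched (pixels), < length / 4.
#' @return List with `shift` (analog -> digital displacement, pixels),
#'   `correlation` (at the optimum) and `low_confidence` (TRUE for
#'   zero-variance input or a weak correlation peak).
#' @export
align_lines <- function(digital_line, analog_line, max_shift = 8L) {
  n <- length(digital_line)
  stopifnot(length(analog_line) == n)
  if (max_shift >= n / 4) {
    stop("`max_shift` must be below a quarter of the line length",
         call. = FALSE)
  }
  if (stats::sd(digital_line) == 0 || stats::sd(analog_line) == 0) {
    return(list(shift = 0L, correlation = NA_real_, low_confidence = TRUE))
  }
  shifts <- seq.int(-max_shift, max_shift)
  shifts <- shifts[order(abs(shifts))] # zero-ward tie-break
  cors <- vapply(shifts, function(s) {
    if (s >= 0) {
      a <- digital_line[(1 + s):n]; b <- analog_line[1:(n - s)]
    } else {
      a <- digital_line[1:(n + s)]; b <- analog_line[(1 - s):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  best <- which.max(cors) # first max in zero-ordered candidates
  list(shift = shifts[best], correlation = cors[best],
       low_confidence = !is.finite(cors[best]) || cors[best] < 0.2)
}

#' Assemble reconstructed slices into an image stack
#'
#' @param images List of `snspd_image` objects (same mode and size).
#' @param depths_um Strictly increasing slice depths (um).
#' @return An object of class `snspd_image_stack`: `data` (nx x ny x nz
#'   array), `depths_um`, `mode`, `scan`.
#' @export
image_stack <- function(images, depths_um) {
  stopifnot(length(images) == length(depths_um), length(images) >= 1)
  if (is.unsorted(depths_um, strictly = TRUE)) {
    stop("`depths_um` must be strictly increasing", call. = FALSE)
  }
  modes <- unique(vapply(images, `[[`, character(1), "mode"))
  stopifnot(length(modes) == 1L)
  d1 <- dim(images[[1]]$data)
  data <- array(0, dim = c(d1, length(images)))
  for (k in seq_along(images)) data[, , k] <- images[[k]]$data
  structure(list(data = data, depths_um = as.numeric(depths_um),
                 mode = modes, scan = images[[1]]$scan),
            class = "snspd_image_stack")
}

#' @export
print.snspd_image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<snspd_image_stack> %d x %d x %d (%s), depths %.0f-%.0f um\n",
              d[1], d[2], d[3], x$mode, min(x$depths_um), max(x$depths_um)))
  invisible(x)
}

#' Save / load an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are 32-bit float, normalised by the stack maximum; the scale,
#' depths, mode and scan parameters live in `<path>.json`.
#'
#' @param stack An `snspd_image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_image_stack <- function(stack, path) {
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_along(stack$depths_um),
                  function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(mode = stack$mode, depths_um = stack$depths_um, scale = scale,
         scan = unclass(stack$scan)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_image_stack
#' @export
load_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * meta$scale
  scan <- do.call(scan_config, as.list(meta$scan))
  structure(list(data = data, depths_um = as.numeric(meta$depths_um),
                 mode = meta$mode, scan = scan),
            class = "snspd_image_stack")
}
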