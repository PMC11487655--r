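# Electronics chain emulation: TTL pulse standardisation, FPGA-style gated
# digital counting on an 8 ns time base, analog channel summation with
# noise, and the binary photon event-stream format.

#' FPGA gate configuration
#'
#' The counting time base is the FPGA clock (125 MHz -> 8 ns bins). A
#' user-defined delay and width, in bins, form the integration gate after
#' each laser pulse: within the gate up to one photon per pixel is recorded,
#' outside it nothing is.
#'
#' @param clock_hz FPGA clock rate.
#' @param delay_bins Gate delay after the laser pulse, in bins.
#' @param width_bins Gate width in bins (default 10 -> 80 ns).
#' @param long_pulse_double_count If TRUE, an extremely long TTL pulse
#'   (electrically two merged photons) is recorded as two.
#' @param long_pulse_threshold_ns Duration above which a pulse counts double.
#' @return An object of class `gate_config` with derived `bin_ns`.
#' @export
gate_config <- function(clock_hz = 125e6, delay_bins = 0L, width_bins = 10L,
                        long_pulse_double_count = FALSE,
                        long_pulse_threshold_ns = 100) {
  assert_scalar_pos(clock_hz, "clock_hz")
  if (delay_bins < 0) stop("`delay_bins` must be >= 0", call. = FALSE)
  if (width_bins < 1) stop("`width_bins` must be >= 1", call. = FALSE)
  structure(list(clock_hz = clock_hz, bin_ns = 1e9 / clock_hz,
                 delay_bins = as.integer(delay_bins),
                 width_bins = as.integer(width_bins),
                 long_pulse_double_count = isTRUE(long_pulse_double_count),
                 long_pulse_threshold_ns = long_pulse_threshold_ns),
            class = "gate_config")
}

#' Analog summation chain configuration
#'
#' The 24 channel pulses are scaled to ~300 mV, low-passed and summed into a
#' single analog signal; on top of the photon staircase the model adds a
#' sinusoidal ripple (RF pickup / ground loops), white noise, and uniform
#' ADC quantisation error. Ripple and white-noise amplitudes are free
#' parameters (the rig's values are not published) expressed in
#' photon-count equivalents (1 count = `per_channel_amplitude_mv`).
#'
#' @param per_channel_amplitude_mv Scaled per-photon pulse amplitude.
#' @param driver_pulse_length_ns,driver_pulse_peak_mv Raw driver pulse shape.
#' @param ttl_width_ns Standardised TTL pulse width.
#' @param ttl_level_v TTL logic level, 3.3 or 5 V.
#' @param ripple_amplitude Ripple amplitude, count equivalents.
#' @param ripple_freq_hz Ripple frequency.
#' @param white_noise_sigma White-noise sigma, count equivalents.
#' @param adc_bits,adc_fullscale_mv ADC resolution and full-scale range.
#' @return An object of class `analog_chain_config`.
#' @export
analog_chain_config <- function(per_channel_amplitude_mv = 300,
                                driver_pulse_length_ns = 20,
                                driver_pulse_peak_mv = 200,
                                ttl_width_ns = 50, ttl_level_v = 3.3,
                                ripple_amplitude = 0.6,
                                ripple_freq_hz = 37e3,
                                white_noise_sigma = 0.4,
                                adc_bits = 16L, adc_fullscale_mv = 20000) {
  assert_scalar_pos(per_channel_amplitude_mv, "per_channel_amplitude_mv")
  if (!ttl_level_v %in% c(3.3, 5)) {
    stop("`ttl_level_v` must be 3.3 or 5", call. = FALSE)
  }
  assert_scalar_pos(ripple_amplitude, "ripple_amplitude", strict = FALSE)
  assert_scalar_pos(ripple_freq_hz, "ripple_freq_hz", strict = FALSE)
  assert_scalar_pos(white_noise_sigma, "white_noise_sigma", strict = FALSE)
  if (adc_bits <= 0) stop("`adc_bits` must be positive", call. = FALSE)
  assert_scalar_pos(adc_fullscale_mv, "adc_fullscale_mv")
  structure(list(per_channel_amplitude_mv = per_channel_amplitude_mv,
                 driver_pulse_length_ns = driver_pulse_length_ns,
                 driver_pulse_peak_mv = driver_pulse_peak_mv,
                 ttl_width_ns = ttl_width_ns, ttl_level_v = ttl_level_v,
                 ripple_amplitude = ripple_amplitude,
                 ripple_freq_hz = ripple_freq_hz,
                 white_noise_sigma = white_noise_sigma,
                 adc_bits = as.integer(adc_bits),
                 adc_fullscale_mv = adc_fullscale_mv),
            class = "analog_chain_config")
}

#' Standardise raw driver pulses to fixed-width TTL pulses
#'
#' Every raw pulse is mapped to a TTL pulse of fixed width (default 50 ns)
#' and level, keeping its leading edge. Raw pulses on the same channel whose
#' leading edges fall within one TTL width merge into a single TTL pulse
#' (the comparator/monoflop cannot retrigger while high).
#'
#' @param raw_events Tibble/data.frame with `channel`, `time_ns` and
#'   optionally `duration_ns`.
#' @param chain An [analog_chain_config()].
#' @return A tibble `channel`, `time_ns`, `width_ns`, `level_v`, sorted by
#'   channel then time.
#' @export
standardize_pulses <- function(raw_events, chain = analog_chain_config()) {
  if (!nrow(raw_events)) {
    return(tibble::tibble(channel = integer(), time_ns = numeric(),
                          width_ns = numeric(), level_v = numeric()))
  }
  ev <- raw_events[order(raw_events$channel, raw_events$time_ns), ]
  keep <- logical(nrow(ev))
  last_end <- -Inf; last_ch <- NA
  for (i in seq_len(nrow(ev))) {
    if (!identical(ev$channel[i], last_ch) || ev$time_ns[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- ev$time_ns[i] + chain$ttl_width_ns
      last_ch <- ev$channel[i]
    }
  }
  tibble::tibble(channel = ev$channel[keep], time_ns = ev$time_ns[keep],
                 width_ns = chain$ttl_width_ns, level_v = chain$ttl_level_v)
}

# Event stream container --------------------------------------------------

#' Construct a photon event stream
#'
#' The stream is the FPGA's view of an acquisition: for each laser pulse,
#' which pixels saw at least one event and in which 8 ns bin (relative to
#' the pulse, whose time is rounded down to the clock bin so that bin-edge
#' events are deterministic), plus frame/line trigger flags.
#'
#' @param n_pulses Total number of laser pulses covered.
#' @param rep_rate_hz Laser repetition rate.
#' @param geometry An [array_geometry()].
#' @param events Tibble with `pulse` (0-based), `pixel` (0-based row-major
#'   id), `bin` (8 ns bin index within the pulse period).
#' @param triggers Tibble with `pulse`, `frame`, `line` (logical flags);
#'   only pulses carrying a trigger need appear.
#' @param gate A [gate_config()] describing the time base.
#' @param scan Optional [scan_config()] the stream was acquired with.
#' @param meta Optional list of extra metadata.
#' @return An object of class `snspd_event_stream`.
#' @export
event_stream <- function(n_pulses, rep_rate_hz, geometry, events,
                         triggers = NULL, gate = gate_config(),
                         scan = NULL, meta = list()) {
  period_bins <- floor(1e9 / rep_rate_hz / gate$bin_ns)
  if (nrow(events)) {
    stopifnot(all(events$pulse >= 0), all(events$pulse < n_pulses),
              all(events$bin >= 0))
    if (any(events$bin >= period_bins)) {
      stop("event time bins must be below the inter-pulse interval (",
           period_bins, " bins)", call. = FALSE)
    }
    conn <- connected_ids(geometry)
    if (!all(events$pixel %in% conn)) {
      stop("events recorded on unconnected pixels", call. = FALSE)
    }
  }
  if (is.null(triggers)) {
    triggers <- tibble::tibble(pulse = numeric(), frame = logical(),
                               line = logical())
  }
  structure(list(n_pulses = n_pulses, rep_rate_hz = rep_rate_hz,
                 geometry = geometry, events = events, triggers = triggers,
                 gate = gate, scan = scan, meta = meta),
            class = "snspd_event_stream")
}

#' @export
print.snspd_event_stream <- function(x, ...) {
  cat(sprintf("<snspd_event_stream> %s pulses @ %.3g Hz, %s events, %d trigger pulses\n",
              format(x$n_pulses, big.mark = ","), x$rep_rate_hz,
              format(nrow(x$events), big.mark = ","), nrow(x$triggers)))
  invisible(x)
}

# Counting -----------------------------------------------------------------

new_counts <- function(hits, stream, mode, gate) {
  structure(list(hits = hits, n_pulses = stream$n_pulses,
                 rep_rate_hz = stream$rep_rate_hz,
                 geometry = stream$geometry, triggers = stream$triggers,
                 scan = stream$scan, mode = mode, gate = gate),
            class = "snspd_counts")
}

#' Gated digital counting
#'
#' Per pixel and laser pulse, a hit is recorded iff at least one event falls
#' in the gate `[delay, delay + width)` in 8 ns bin arithmetic; at most one
#' photon per pixel per gate (saturating binary response), unless the
#' long-pulse double-count option is enabled and the event carries a
#' duration above threshold. Events outside the gate are never counted.
#'
#' @param stream An [event_stream()], or a data.frame of events with
#'   absolute `time_ns` (see `gated_count_times()`).
#' @param gate A [gate_config()].
#' @return An `snspd_counts` object: `hits` tibble (`pulse`, `pixel`,
#'   `weight`) with one row per recorded hit, plus acquisition metadata.
#' @export
gated_count <- function(stream, gate = gate_config()) {
  stopifnot(inherits(stream, "snspd_event_stream"))
  ev <- stream$events
  lo <- gate$delay_bins
  hi <- gate$delay_bins + gate$width_bins
  ev <- ev[ev$bin >= lo & ev$bin < hi, , drop = FALSE]
  if (nrow(ev)) {
    weight <- rep(1, nrow(ev))
    if (gate$long_pulse_double_count && !is.null(ev$duration_ns)) {
      weight[!is.na(ev$duration_ns) &
               ev$duration_ns > gate$long_pulse_threshold_ns] <- 2
    }
    key <- ev$pulse * 64 + ev$pixel
    o <- order(key, -weight) # per (pulse, pixel): keep one hit, widest pulse
    first <- !duplicated(key[o])
    hits <- tibble::tibble(pulse = ev$pulse[o][first],
                           pixel = ev$pixel[o][first],
                           weight = weight[o][first])
    hits <- hits[order(hits$pulse, hits$pixel), ]
  } else {
    hits <- tibble::tibble(pulse = numeric(), pixel = integer(),
                           weight = numeric())
  }
  new_counts(hits, stream, "digital_gated", gate)
}

#' Ungated digital counting
#'
#' Equivalent to [gated_count()] with zero delay and a gate spanning the
#' full inter-pulse interval: every event between excitation pulses
#' (fluorescence and dark counts alike) is integrated.
#'
#' @param stream An [event_stream()].
#' @return An `snspd_counts` object with mode `"digital_ungated"`.
#' @export
ungated_count <- function(stream) {
  period_bins <- floor(1e9 / stream$rep_rate_hz / stream$gate$bin_ns)
  g <- gate_config(clock_hz = stream$gate$clock_hz, delay_bins = 0L,
                   width_bins = period_bins,
                   long_pulse_double_count = stream$gate$long_pulse_double_count,
                   long_pulse_threshold_ns = stream$gate$long_pulse_threshold_ns)
  res <- gated_count(stream, g)
  res$mode <- "digital_ungated"
  res
}

#' Gated counting from absolute event times (reference path)
#'
#' Direct interval-membership implementation used as a cross-check of the
#' binned stream path: an event is gated into pulse i when its absolute time
#' bin falls inside `[floor(t_i / bin) + delay, ... + width)`.
#'
#' @param event_times_ns Absolute event times (ns), one entry per event.
#' @param event_pixels Pixel ids aligned with `event_times_ns`.
#' @param pulse_times_ns Monotone increasing laser pulse times (ns).
#' @param gate A [gate_config()].
#' @return Tibble `pulse` (0-based), `pixel` of recorded hits.
#' @export
gated_count_times <- function(event_times_ns, event_pixels, pulse_times_ns,
                              gate = gate_config()) {
  if (is.unsorted(pulse_times_ns, strictly = TRUE)) {
    stop("laser pulse times must be strictly increasing", call. = FALSE)
  }
  out_p <- numeric(0); out_px <- integer(0)
  ebin <- floor(event_times_ns / gate$bin_ns)
  for (i in seq_along(pulse_times_ns)) {
    start <- floor(pulse_times_ns[i] / gate$bin_ns) + gate$delay_bins
    inside <- ebin >= start & ebin < start + gate$width_bins
    px <- unique(event_pixels[inside])
    out_p <- c(out_p, rep(i - 1, length(px)))
    out_px <- c(out_px, px)
  }
  tibble::tibble(pulse = out_p, pixel = as.integer(out_px))
}

# Analog path ---------------------------------------------------------------

#' Analog summation readout
#'
#' Assigns every TTL pulse (photon or dark event; events on the same pixel
#' within one TTL width merge) to its scan dwell and integrates: the dwell
#' value is `count * per_channel_amplitude + ripple + white noise`,
#' quantised by the ADC. The ripple is a single sinusoid with a random phase
#' per frame, sampled at the dwell time.
#'
#' @param stream An [event_stream()] with a `scan` attached.
#' @param chain An [analog_chain_config()].
#' @param scan A [scan_config()]; defaults to the stream's.
#' @param noise If FALSE, returns the noise-free photon staircase.
#' @return A tibble `frame`, `x`, `y` (1-based scan pixel), `counts`
#'   (TTL pulses in the dwell), `value_mv`.
#' @export
analog_sum <- function(stream, chain = analog_chain_config(), scan = NULL,
                       noise = TRUE) {
  if (is.null(scan)) scan <- stream$scan
  stopifnot(!is.null(scan))
  pp <- scan$pulses_per_pixel
  dwells_per_frame <- scan$nx * scan$ny
  pulses_per_frame <- dwells_per_frame * pp
  n_frames <- scan$frames_averaged
  stopifnot(stream$n_pulses >= pulses_per_frame * n_frames)

  ev <- stream$events
  counts <- numeric(dwells_per_frame * n_frames)
  if (nrow(ev)) {
    # merge events on the same pixel & pulse closer than one TTL width
    merge_bins <- ceiling(chain$ttl_width_ns / stream$gate$bin_ns)
    o <- order(ev$pulse, ev$pixel, ev$bin)
    p <- ev$pulse[o]; px <- ev$pixel[o]; b <- ev$bin[o]
    same <- c(FALSE, p[-1] == p[-length(p)] & px[-1] == px[-length(px)] &
                (b[-1] - b[-length(b)]) < merge_bins)
    p <- p[!same]
    dwell_global <- p %/% pp # 0-based dwell across frames
    keep <- dwell_global < dwells_per_frame * n_frames
    tab <- table(dwell_global[keep])
    counts[as.numeric(names(tab)) + 1] <- as.numeric(tab)
  }
  dwell0 <- seq_len(dwells_per_frame * n_frames) - 1L
  frame <- dwell0 %/% dwells_per_frame
  within <- dwell0 %% dwells_per_frame
  y <- within %/% scan$nx + 1L
  x <- within %% scan$nx + 1L
  value <- counts * chain$per_channel_amplitude_mv
  if (noise) {
    dwell_s <- scan$pulses_per_pixel / stream$rep_rate_hz
    t_s <- dwell0 * dwell_s
    phase <- stats::runif(n_frames, 0, 2 * pi)[frame + 1L]
    ripple <- chain$ripple_amplitude * chain$per_channel_amplitude_mv *
      sin(2 * pi * chain$ripple_freq_hz * t_s + phase)
    white <- stats::rnorm(length(value), 0,
                          chain$white_noise_sigma * chain$per_channel_amplitude_mv)
    value <- value + ripple + white
    q <- chain$adc_fullscale_mv / 2^chain$adc_bits
    value <- round(value / q) * q
  }
  tibble::tibble(frame = frame + 1L, x = x, y = y, counts = counts,
                 value_mv = value)
}

# Binary event-stream file format -------------------------------------------
#
# Little-endian layout:
#   header (16 B): magic "SNEV" | version u16 | flags u16 | rep_rate u64
#     flags bit 0: time-bin side channel present
#   if side channel present: n_records u64
#   records (16 B each): pulse_index u64 | hit_mask u48 (6 B) | flags u8
#     (bit 0 frame trigger, bit 1 line trigger) | reserved u8
#     (records run to EOF when there is no side channel)
#   side channel: n_events u64, then 12 B entries:
#     pulse_index u64 | pixel u8 | reserved u8 | bin u16

# little-endian raw encoding: x (< 2^53) -> n_bytes x length(x) raw matrix
uint_raw <- function(x, n_bytes) {
  m <- matrix(0L, n_bytes, length(x))
  v <- x
  for (b in seq_len(n_bytes)) {
    m[b, ] <- as.integer(v %% 256)
    v <- v %/% 256
  }
  matrix(as.raw(m), n_bytes)
}

# vectorised little-endian decode: integer byte values, 1-based offsets of
# the first byte of each field
uint_from <- function(bytes, off, n_bytes) {
  v <- numeric(length(off))
  for (b in seq_len(n_bytes)) v <- v + bytes[off + b - 1L] * 2^(8 * (b - 1L))
  v
}

#' Write / read the binary photon event-stream file
#'
#' Bit-exact, documented little-endian format (see the package README):
#' a 16-byte header (magic `SNEV`, version, flags, repetition rate), fixed
#' 16-byte per-pulse records (pulse index, 48-bit hit mask, trigger flags),
#' and an optional time-bin side channel preserving the 8 ns bin of every
#' event. Only pulses with at least one event or trigger are materialised
#' as records; the round trip through write/read is lossless.
#'
#' @param stream An [event_stream()].
#' @param path File path.
#' @return `write_event_stream()`: `path` invisibly; `read_event_stream()`:
#'   an `snspd_event_stream` (geometry/scan metadata are not serialised and
#'   are restored as defaults unless supplied).
#' @export
write_event_stream <- function(stream, path) {
  ev <- stream$events
  trg <- stream$triggers
  rec_pulses <- sort(unique(c(ev$pulse, trg$pulse)))
  n_rec <- length(rec_pulses)

  header <- c(charToRaw("SNEV"),
              uint_raw(1, 2),                    # version
              uint_raw(1, 2),                    # flags: side channel present
              uint_raw(stream$rep_rate_hz, 8),
              uint_raw(n_rec, 8))

  # records: pulse u64 | hit_mask u48 | flags u8 | reserved u8
  rec_raw <- raw(0)
  if (n_rec) {
    masks <- matrix(0, n_rec, 6) # byte values of the 48-bit masks
    if (nrow(ev)) {
      key <- ev$pulse * 64 + ev$pixel
      dd <- !duplicated(key)
      ridx <- match(ev$pulse[dd], rec_pulses)
      byte <- ev$pixel[dd] %/% 8L + 1L
      bit <- 2^(ev$pixel[dd] %% 8L)
      acc <- rowsum(bit, group = (ridx - 1L) * 6L + byte)
      grp <- as.numeric(rownames(acc))
      masks[cbind((grp - 1L) %/% 6L + 1L, (grp - 1L) %% 6L + 1L)] <- acc[, 1]
    }
    fl <- integer(n_rec)
    fl[rec_pulses %in% trg$pulse[trg$frame]] <- 1L
    fl[rec_pulses %in% trg$pulse[trg$line]] <-
      fl[rec_pulses %in% trg$pulse[trg$line]] + 2L
    rec_raw <- as.vector(rbind(uint_raw(rec_pulses, 8),
                               matrix(as.raw(t(masks)), 6),
                               uint_raw(fl, 1),
                               uint_raw(0 * fl, 1)))
  }

  # side channel: n_events u64, entries pulse u64 | pixel u8 | pad u8 | bin u16
  side_raw <- uint_raw(nrow(ev), 8)
  if (nrow(ev)) {
    o <- order(ev$pulse, ev$pixel, ev$bin)
    side_raw <- c(side_raw,
                  as.vector(rbind(uint_raw(ev$pulse[o], 8),
                                  uint_raw(ev$pixel[o], 1),
                                  uint_raw(integer(nrow(ev)), 1),
                                  uint_raw(ev$bin[o], 2))))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, rec_raw, side_raw), con)
  invisible(path)
}

#' @rdname write_event_stream
#' @param n_pulses,geometry,gate,scan Metadata to attach to the restored
#'   stream (not stored in the file).
#' @export
read_event_stream <- function(path, n_pulses = NULL,
                              geometry = array_geometry(),
                              gate = gate_config(), scan = NULL) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  r <- readBin(con, "raw", n = sz)
  if (length(r) < 4L || !identical(rawToChar(r[1:4]), "SNEV")) {
    stop("bad event-stream magic at byte offset 0 (expected 'SNEV')",
         call. = FALSE)
  }
  if (length(r) < 16L) {
    stop("truncated event-stream header: ", length(r),
         " bytes, need 16", call. = FALSE)
  }
  bytes <- as.integer(r)
  flags <- uint_from(bytes, 7L, 2)
  rep_rate <- uint_from(bytes, 9L, 8)
  has_side <- bitwAnd(as.integer(flags), 1L) == 1L

  pos <- 17L # 1-based offset of the next unread byte
  if (has_side) {
    if (length(r) < 24L) {
      stop("truncated record count at byte offset 16", call. = FALSE)
    }
    n_rec <- uint_from(bytes, pos, 8)
    pos <- pos + 8L
  } else {
    n_rec <- (length(r) - 16L) %/% 16L
  }
  rec_bytes <- n_rec * 16
  if (length(r) < pos - 1L + rec_bytes) {
    stop("truncated event stream at byte offset ", length(r),
         ": expected ", n_rec, " records", call. = FALSE)
  }
  triggers <- tibble::tibble(pulse = numeric(), frame = logical(),
                             line = logical())
  mask_events <- NULL
  if (n_rec > 0) {
    off <- pos + (seq_len(n_rec) - 1L) * 16L
    rec_pulse <- uint_from(bytes, off, 8)
    rec_flags <- as.integer(bytes[off + 14L])
    has_trig <- rec_flags > 0L
    triggers <- tibble::tibble(
      pulse = rec_pulse[has_trig],
      frame = bitwAnd(rec_flags[has_trig], 1L) == 1L,
      line = bitwAnd(rec_flags[has_trig], 2L) == 2L)
    if (!has_side) {
      # expand the 48-bit masks into per-pixel events (bins unknown -> 0)
      hit <- lapply(0:5, function(b) {
        v <- bytes[off + 8L + b]
        lapply(0:7, function(k) {
          set <- bitwAnd(v, bitwShiftL(1L, k)) != 0L
          if (any(set)) tibble::tibble(pulse = rec_pulse[set],
                                       pixel = b * 8L + k, bin = 0L)
        })
      })
      mask_events <- dplyr::bind_rows(unlist(hit, recursive = FALSE))
    }
  }
  pos <- pos + as.integer(rec_bytes)

  if (has_side) {
    if (length(r) < pos + 7L) {
      stop("truncated side-channel count at byte offset ", pos - 1L,
           call. = FALSE)
    }
    n_ev <- uint_from(bytes, pos, 8)
    pos <- pos + 8L
    if (length(r) < pos - 1L + n_ev * 12) {
      stop("truncated side channel at byte offset ", length(r),
           ": expected ", n_ev, " entries", call. = FALSE)
    }
    if (n_ev > 0) {
      off <- pos + (seq_len(n_ev) - 1L) * 12L
      events <- tibble::tibble(pulse = uint_from(bytes, off, 8),
                               pixel = as.integer(bytes[off + 8L]),
                               bin = as.integer(uint_from(bytes, off + 10L, 2)))
    } else {
      events <- tibble::tibble(pulse = numeric(), pixel = integer(),
                               bin = integer())
    }
  } else if (!is.null(mask_events) && nrow(mask_events)) {
    events <- mask_events[order(mask_events$pulse, mask_events$pixel), ]
  } else {
    events <- tibble::tibble(pulse = numeric(), pixel = integer(),
                             bin = integer())
  }
  if (is.null(n_pulses)) {
    n_pulses <- if (nrow(events) || nrow(triggers)) {
      max(c(events$pulse, triggers$pulse)) + 1
    } else 0
  }
  event_stream(n_pulses = n_pulses, rep_rate_hz = rep_rate,
               geometry = geometry, events = events, triggers = triggers,
               gate = gate, scan = scan)
}
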