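test_that("pulse standardisation fixes width and merges overlapping pulses", {
  chain <- analog_chain_config()
  raw <- tibble::tibble(channel = 3L, time_ns = 100, duration_ns = 20)
  ttl <- standardize_pulses(raw, chain)
  expect_equal(nrow(ttl), 1L)
  expect_equal(ttl$time_ns, 100) # leading edge preserved
  expect_equal(ttl$width_ns, 50)
  expect_equal(ttl$level_v, 3.3)
  # two raw pulses 10 ns apart on one channel merge into one TTL pulse
  two <- tibble::tibble(channel = c(1L, 1L), time_ns = c(200, 210),
                        duration_ns = 20)
  expect_equal(nrow(standardize_pulses(two, chain)), 1L)
  # 60 ns apart: no merge; different channels never merge
  apart <- tibble::tibble(channel = c(1L, 1L), time_ns = c(200, 260),
                          duration_ns = 20)
  expect_equal(nrow(standardize_pulses(apart, chain)), 2L)
  cross <- tibble::tibble(channel = c(1L, 2L), time_ns = c(200, 210),
                          duration_ns = 20)
  expect_equal(nrow(standardize_pulses(cross, chain)), 2L)
  expect_equal(nrow(standardize_pulses(raw[0, ], chain)), 0L)
})

test_that("gated counting keeps in-gate events and saturates at one photon", {
  gate <- gate_config(delay_bins = 0L, width_bins = 10L) # 80 ns
  ev <- tibble::tibble(pulse = c(0, 0, 0, 1, 2),
                       pixel = c(14L, 14L, 14L, 15L, 20L),
                       bin = c(5L, 2L, 7L, 62L, 9L))
  st <- manual_stream(ev, n_pulses = 4)
  hits <- gated_count(st, gate)$hits
  # three in-gate events on one pixel in one gate -> a single hit
  expect_equal(nrow(hits[hits$pulse == 0, ]), 1L)
  expect_equal(hits$weight[hits$pulse == 0], 1)
  # 500 ns after the pulse (bin 62) falls outside the 80 ns gate
  expect_false(any(hits$pulse == 1))
  # 72 ns (bin 9) is the last in-gate bin
  expect_true(any(hits$pulse == 2 & hits$pixel == 20L))
})

test_that("stream gating agrees with the interval-membership oracle", {
  gate <- gate_config(delay_bins = 2L, width_bins = 8L)
  period <- 1000 # ns at 1 MHz; a multiple of the 8 ns clock bin
  for (seed in 1:5) {
    set.seed(seed)
    n_ev <- 300L
    pulse <- sample(0:49, n_ev, replace = TRUE)
    offset <- stats::runif(n_ev, 0, period)
    pixel <- sample(connected_ids(array_geometry()), n_ev, replace = TRUE)
    stream <- manual_stream(
      tibble::tibble(pulse = pulse, pixel = pixel,
                     bin = as.integer(floor(offset / 8))),
      n_pulses = 50)
    got <- gated_count(stream, gate)$hits
    oracle <- gated_count_times(pulse * period + offset, pixel,
                                (0:49) * period, gate)
    key <- function(d) sort(d$pulse * 64 + d$pixel)
    expect_equal(key(got), key(oracle))
  }
  expect_error(gated_count_times(1, 1L, c(1000, 500), gate_config()),
               "increasing")
})

test_that("ungated counting spans the full period and dominates gated hits", {
  geom <- array_geometry()
  for (seed in 1:4) {
    set.seed(seed)
    n_ev <- 200L
    ev <- tibble::tibble(
      pulse = sample(0:29, n_ev, replace = TRUE),
      pixel = sample(connected_ids(geom), n_ev, replace = TRUE),
      bin = sample(0:124, n_ev, replace = TRUE))
    st <- manual_stream(ev, n_pulses = 30)
    ung <- ungated_count(st)$hits
    gat <- gated_count(st, gate_config())$hits
    # equivalence with an explicit full-period gate
    full <- gated_count(st, gate_config(delay_bins = 0L,
                                        width_bins = 125L))$hits
    expect_equal(ung[c("pulse", "pixel")], full[c("pulse", "pixel")])
    # dark/stray events anywhere in the period are integrated
    expect_equal(nrow(ung), nrow(unique(ev[, c("pulse", "pixel")])))
    # gated hits are a subset of ungated hits, pulse by pulse
    expect_true(all(paste(gat$pulse, gat$pixel) %in%
                      paste(ung$pulse, ung$pixel)))
    expect_gte(nrow(ung), nrow(gat))
  }
})

test_that("gated output is invariant to ps-scale timing jitter", {
  ph <- uniform_phantom(conc = 0.5)
  scan <- scan_config(nx = 12L, ny = 12L, pulses_per_pixel = 3L,
                      frames_averaged = 1L, fov_um = 100)
  laser <- laser_config(); opt <- optics_config()
  geom <- array_geometry()
  args <- function(jit) {
    detector_config(geom, pixel_bank(geom, jitter_sigma_ps = jit,
                                     dark_rate_cps = 0, seed = 4L))
  }
  s_jit <- simulate_slice(ph, 60, scan, laser, opt, args(16.99), seed = 9L)
  s_none <- simulate_slice(ph, 60, scan, laser, opt, args(0), seed = 9L)
  g1 <- gated_count(s_jit)$hits
  g0 <- gated_count(s_none)$hits
  expect_equal(g1[c("pulse", "pixel")], g0[c("pulse", "pixel")])
})

test_that("analog summation is linear in photons and composes noise variances", {
  scan <- scan_config(nx = 8L, ny = 8L, pulses_per_pixel = 4L,
                      frames_averaged = 1L, fov_um = 100)
  chain <- analog_chain_config()
  # k photons in one dwell -> exactly k * amplitude without noise
  ev <- tibble::tibble(pulse = c(0, 1, 2, 8), pixel = c(14L, 15L, 20L, 14L),
                       bin = c(0L, 0L, 30L, 0L))
  st <- manual_stream(ev, n_pulses = 8 * 8 * 4, scan = scan)
  av <- analog_sum(st, chain, noise = FALSE)
  expect_equal(av$value_mv[1], 3 * 300) # pulses 0..3 -> dwell 1
  expect_equal(av$value_mv[3], 1 * 300) # pulse 8 -> dwell 3
  expect_equal(sum(av$counts), 4)
  # photon-free dwells: std matches ripple/white/quantisation composition
  empty <- manual_stream(ev[0, ], n_pulses = 8 * 8 * 4, scan = scan)
  set.seed(11)
  vals <- unlist(lapply(1:60, function(i) analog_sum(empty, chain)$value_mv))
  q <- chain$adc_fullscale_mv / 2^chain$adc_bits
  expected_sd <- sqrt((chain$ripple_amplitude * 300)^2 / 2 +
                        (chain$white_noise_sigma * 300)^2 + q^2 / 12)
  expect_lt(abs(stats::sd(vals) - expected_sd) / expected_sd, 0.1)
  expect_lt(abs(mean(vals)), 10) # ripple and white noise have zero mean
})

test_that("event-stream files round trip losslessly", {
  geom <- array_geometry()
  set.seed(21)
  n_ev <- 1e4L
  ev <- tibble::tibble(
    pulse = sort(sample(0:(5e4 - 1), n_ev, replace = TRUE)),
    pixel = sample(connected_ids(geom), n_ev, replace = TRUE),
    bin = sample(0:124, n_ev, replace = TRUE))
  ev <- dplyr::distinct(ev, pulse, pixel, bin)
  trig <- tibble::tibble(pulse = seq(0, 5e4 - 1, by = 500),
                         frame = c(TRUE, rep(FALSE, 99)),
                         line = TRUE)
  st <- event_stream(5e4, 1e6, geom, ev, triggers = trig)
  path <- file.path(tempdir(), "roundtrip.snev")
  write_event_stream(st, path)
  back <- read_event_stream(path, n_pulses = 5e4)
  o <- order(ev$pulse, ev$pixel, ev$bin)
  expect_equal(back$events$pulse, as.numeric(ev$pulse[o]))
  expect_equal(back$events$pixel, as.integer(ev$pixel[o]))
  expect_equal(back$events$bin, as.integer(ev$bin[o]))
  expect_equal(back$rep_rate_hz, 1e6)
  tb <- back$triggers[order(back$triggers$pulse), ]
  expect_equal(tb$pulse, as.numeric(trig$pulse))
  expect_equal(tb$frame, trig$frame)
  expect_equal(tb$line, trig$line)
  unlink(path)
})

test_that("empty streams and corrupted files are handled explicitly", {
  geom <- array_geometry()
  empty <- event_stream(0, 1e6, geom,
                        tibble::tibble(pulse = numeric(), pixel = integer(),
                                       bin = integer()))
  path <- file.path(tempdir(), "empty.snev")
  write_event_stream(empty, path)
  back <- read_event_stream(path)
  expect_equal(nrow(back$events), 0L)
  expect_equal(nrow(back$triggers), 0L)
  # corrupted magic byte -> explicit parse error, not silent garbage
  bytes <- readBin(path, "raw", file.size(path))
  bytes[2] <- as.raw(0xFF)
  writeBin(bytes, path)
  expect_error(read_event_stream(path), "magic")
  # truncation -> explicit error
  write_event_stream(empty, path)
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[1:10], path)
  expect_error(read_event_stream(path), "truncated")
  unlink(path)
})
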