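test_that("dwell time per slice follows the scan arithmetic", {
  expect_equal(dwell_time_per_slice(scan_config(), laser_config()), 6.5536)
  one <- scan_config(nx = 1L, ny = 1L, pulses_per_pixel = 1L,
                     frames_averaged = 1L)
  expect_equal(dwell_time_per_slice(one, laser_config()), 1e-6)
  big <- scan_config(nx = 512L, ny = 512L, pulses_per_pixel = 4L,
                     frames_averaged = 2L)
  expect_equal(dwell_time_per_slice(big, laser_config(rep_rate_hz = 2e6)),
               512 * 512 * 4 * 2 / 2e6) # = 1.048576 s
})

test_that("digital reconstruction localises hits at the raster position", {
  scan <- scan_config(nx = 8L, ny = 8L, pulses_per_pixel = 2L,
                      frames_averaged = 1L, fov_um = 100)
  # hits only during the dwell of pixel (x = 3, y = 5)
  target_pulses <- ((5 - 1) * 8 + (3 - 1)) * 2 + 0:1
  ev <- tibble::tibble(pulse = as.numeric(target_pulses),
                       pixel = c(14L, 21L), bin = 0L)
  st <- event_stream(8 * 8 * 2, 1e6, array_geometry(), ev,
                     triggers = snspdsim:::scan_triggers(scan),
                     scan = scan)
  img <- reconstruct_digital(gated_count(st), scan)
  expect_equal(img$data[3, 5], 2)
  expect_equal(sum(img$data), 2)
  # an all-zero hit stream reconstructs to an all-zero image
  st0 <- event_stream(8 * 8 * 2, 1e6, array_geometry(), ev[0, ],
                      triggers = snspdsim:::scan_triggers(scan), scan = scan)
  expect_true(all(reconstruct_digital(gated_count(st0), scan)$data == 0))
})

test_that("mean reconstructed value follows the Poisson saturation law", {
  scan <- scan_config(nx = 16L, ny = 16L, pulses_per_pixel = 5L,
                      frames_averaged = 2L, fov_um = 100)
  lambda <- 0.4
  n_pulses <- 16 * 16 * 5 * 2
  set.seed(17)
  hit <- stats::runif(n_pulses) < (1 - exp(-lambda))
  ev <- tibble::tibble(pulse = as.numeric(which(hit) - 1), pixel = 14L,
                       bin = 0L)
  st <- event_stream(n_pulses, 1e6, array_geometry(), ev,
                     triggers = snspdsim:::scan_triggers(scan), scan = scan)
  img <- reconstruct_digital(gated_count(st), scan)
  expected <- 5 * 2 * (1 - exp(-lambda))
  se <- sqrt(10 * (1 - exp(-lambda)) * exp(-lambda) / (16 * 16))
  expect_lt(abs(mean(img$data) - expected), 4 * se)
  # per-pulse binary summation bound over the connected array
  expect_true(all(img$data <= 5 * 2 * 24))
})

test_that("trigger bookkeeping: mismatches error, short lines warn", {
  scan <- scan_config(nx = 8L, ny = 8L, pulses_per_pixel = 2L,
                      frames_averaged = 1L, fov_um = 100)
  trg <- snspdsim:::scan_triggers(scan)
  ev <- tibble::tibble(pulse = 0, pixel = 14L, bin = 0L)
  st_bad <- event_stream(8 * 8 * 2, 1e6, array_geometry(), ev,
                         triggers = trg[-3, ], scan = scan)
  expect_error(reconstruct_digital(gated_count(st_bad), scan),
               "expected 8 line / 1 frame triggers, found 7")
  # final line shorter than nx * pulses_per_pixel -> dropped with warning
  st_short <- event_stream(8 * 8 * 2 - 6, 1e6, array_geometry(), ev,
                           triggers = trg, scan = scan)
  expect_warning(img <- reconstruct_digital(gated_count(st_short), scan),
                 "partial trailing line")
  expect_equal(sum(img$data), 1)
})

test_that("line alignment recovers integer shifts and flags degeneracy", {
  set.seed(23)
  base <- stats::filter(stats::rnorm(128), rep(1, 5), circular = TRUE)
  base <- as.numeric(base)
  expect_equal(align_lines(base, base)$shift, 0L)
  # analog line displaced by +3 px with noise at SNR ~ 5
  shifted <- c(base[-(1:3)], base[1:3]) +
    stats::rnorm(128, 0, stats::sd(base) / 5)
  res <- align_lines(base, shifted, max_shift = 8L)
  # brute-force argmax oracle over all shifts
  cors <- vapply(-8:8, function(s) {
    n <- 128
    if (s >= 0) stats::cor(base[(1 + s):n], shifted[1:(n - s)])
    else stats::cor(base[1:(n + s)], shifted[(1 - s):n])
  }, numeric(1))
  expect_equal(res$shift, (-8:8)[which.max(cors)])
  expect_equal(res$shift, 3L)
  expect_false(res$low_confidence)
  # zero-variance input -> shift 0, low confidence
  flat <- align_lines(rep(2, 64), stats::rnorm(64))
  expect_equal(flat$shift, 0L)
  expect_true(flat$low_confidence)
  # unrelated noise -> weak peak flagged
  weak <- align_lines(stats::rnorm(64), stats::rnorm(64), max_shift = 4L)
  expect_true(weak$low_confidence || abs(weak$correlation) < 0.5)
  expect_error(align_lines(base, shifted, max_shift = 64L), "quarter")
})

test_that("analog reconstruction averages frames with sqrt(N) noise gain", {
  scan <- scan_config(nx = 12L, ny = 12L, pulses_per_pixel = 1L,
                      frames_averaged = 16L, fov_um = 100)
  set.seed(31)
  n_dwell <- 12 * 12
  vals <- tibble::tibble(
    frame = rep(1:16, each = n_dwell),
    x = rep(rep(1:12, times = 12), 16),
    y = rep(rep(1:12, each = 12), 16),
    value_mv = stats::rnorm(16 * n_dwell))
  img <- reconstruct_analog(vals, scan)
  expect_lt(abs(stats::sd(as.vector(img$data)) - 1 / 4), 0.04)
  expect_error(reconstruct_analog(vals[-1, ], scan), "expected")
})

test_that("analog and digital reconstructions of one noiseless stream agree in rank", {
  ph <- uniform_phantom(conc = 1)
  # a phantom with structure: overwrite concentrations with a smooth ramp
  ph$concentration <- array(rep(seq(0.05, 1, length.out = 24), each = 24),
                            dim = dim(ph$concentration))
  scan <- scan_config(nx = 24L, ny = 24L, pulses_per_pixel = 6L,
                      frames_averaged = 1L, fov_um = 120)
  det <- detector_config(pixels = pixel_bank(dark_rate_cps = 0, seed = 2L))
  st <- simulate_slice(ph, 30, scan, laser_config(), optics_config(),
                       det, seed = 5L)
  dig <- reconstruct_digital(ungated_count(st), scan)
  av <- analog_sum(st, analog_chain_config(), noise = FALSE)
  ana <- reconstruct_analog(av, scan)
  rho <- stats::cor(as.vector(dig$data), as.vector(ana$data),
                    method = "spearman")
  expect_gt(rho, 0.99)
})
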