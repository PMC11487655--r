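test_that("SBR statistic matches the hand-computed formula", {
  img <- matrix(c(10, 12, 1, 1, 3, 3), nrow = 2)
  sig <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), nrow = 2)
  bg <- matrix(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE), nrow = 2)
  res <- compute_sbr(img, sig, bg)
  # mu_S = 11, mu_BR = 2, sigma_BR = sd(1,1,3,3) = 1.1547
  expect_equal(res$mean_sbr, (11 - 2) / stats::sd(c(1, 1, 3, 3)))
  expect_equal(res$mean_sbr, 7.794, tolerance = 1e-3)
  expect_equal(res$max_sbr, (12 - 2) / stats::sd(c(1, 1, 3, 3)))
  expect_equal(res$max_sbr, 8.660, tolerance = 1e-3)
})

test_that("SBR is affine-invariant and guards its preconditions", {
  set.seed(2)
  img <- matrix(stats::rnorm(100, 5), 10)
  sig <- matrix(FALSE, 10, 10); sig[4:6, 4:6] <- TRUE
  bg <- !sig; bg[1, ] <- FALSE
  a <- compute_sbr(img, sig, bg)
  b <- compute_sbr(3.7 * img + 11, sig, bg)
  expect_equal(a$mean_sbr, b$mean_sbr, tolerance = 1e-12)
  expect_equal(a$max_sbr, b$max_sbr, tolerance = 1e-12)
  # zero background spread is undefined
  expect_error(compute_sbr(matrix(1, 4, 4),
                           matrix(c(TRUE, rep(FALSE, 15)), 4),
                           matrix(c(FALSE, rep(TRUE, 15)), 4)), "zero")
  # overlapping masks are rejected
  expect_error(compute_sbr(img, sig, sig), "disjoint")
  # empty signal mask: flagged, not an error
  expect_warning(e <- compute_sbr(img, matrix(FALSE, 10, 10), bg), "empty")
  expect_true(e$empty_signal)
  expect_true(is.na(e$mean_sbr))
})

test_that("threshold segmentation recovers a binary image exactly", {
  img <- matrix(1, 20, 20)
  img[8:12, 6:10] <- 10
  masks <- segment_vessels(img, "threshold", q = 0.95, q_b = 0.5,
                           smooth_sigma_px = 0)
  truth <- img == 10
  expect_identical(masks$signal, truth)
  expect_identical(masks$background, !truth)
  expect_error(segment_vessels(img, "threshold", q = 0.4, q_b = 0.6,
                               smooth_sigma_px = 0), "exceed")
  # constant image: degenerate thresholds
  expect_error(segment_vessels(matrix(1, 8, 8), "threshold",
                               smooth_sigma_px = 0), "degenerate")
})

test_that("threshold masks overlap ground truth on a rendered slice", {
  cfg <- small_run_config(
    seed = 6,
    phantom = list(volume_shape = c(96L, 96L, 24L), voxel_size_um = 1.25,
                   vessel_count = 6L, diameter_range_um = c(6, 10),
                   axial_fraction = 1),
    scan = list(nx = 64L, ny = 64L, pulses_per_pixel = 6L,
                frames_averaged = 2L, fov_um = 120))
  comp <- snspdsim:::build_components(cfg)
  z <- 15
  st <- simulate_slice(comp$phantom, z, comp$scan, comp$laser, comp$optics,
                       comp$detector, comp$gate, seed = 6L)
  img <- reconstruct_digital(gated_count(st, comp$gate))
  gt <- ground_truth_masks(comp$phantom, z, dilation_um = 0,
                           grid = list(nx = comp$scan$nx, ny = comp$scan$ny,
                                       fov_um = comp$scan$fov_um))
  sbr <- compute_sbr(img, gt$signal, gt$background &
                       !EBImage::dilate(gt$signal, EBImage::makeBrush(5)))
  expect_gt(sbr$mean_sbr, 5) # the overlap guarantee applies at SBR > 5
  thr <- segment_vessels(img, "threshold",
                         q = 1 - sum(gt$signal) / length(gt$signal),
                         q_b = 0.5, smooth_sigma_px = 0.5)
  jac <- snspdsim:::mask_jaccard(thr$signal, gt$signal)
  expect_gt(jac, 0.7)
})

test_that("vessel width fit recovers a synthetic Gaussian ridge", {
  nx <- 41L
  sigma <- 2 # px; fwhm = 4.7096 px
  x <- seq_len(nx)
  img <- outer(x, seq_len(31), function(i, j) {
    0.5 + 3 * exp(-(i - 21)^2 / (2 * sigma^2))
  })
  res <- vessel_width(img, rbind(c(6, 16), c(36, 16)), line_width_px = 5,
                      pixel_size_um = 1)
  expect_true(res$converged)
  expect_lt(abs(res$fwhm_um - 2.3548 * sigma) / (2.3548 * sigma), 0.02)
  # wider averaging cannot narrow the profile
  res10 <- vessel_width(img, rbind(c(6, 16), c(36, 16)), line_width_px = 10,
                        pixel_size_um = 1)
  expect_gte(res10$fwhm_um, res$fwhm_um - 0.05)
  # flat image: flagged failure, excluded from summaries
  expect_warning(flat <- vessel_width(matrix(1, 41, 31),
                                      rbind(c(6, 16), c(36, 16))), "flat")
  expect_false(flat$converged)
  expect_error(vessel_width_summary(flat), "no converged")
})

test_that("depth limit interpolates log-linearly and handles edge cases", {
  # SBR 10 at 900 um and 0.1 at 1200 um -> crossing at exactly 1050 um
  dl <- depth_limit(tibble::tibble(depth_um = c(900, 1200),
                                   sbr = c(10, 0.1)))
  expect_equal(dl$depth_limit_um, 1050, tolerance = 1e-9)
  expect_true(dl$limit_reached)
  # never crossing: flagged
  no <- depth_limit(tibble::tibble(depth_um = c(100, 200, 300),
                                   sbr = c(9, 5, 2)))
  expect_false(no$limit_reached)
  expect_equal(no$depth_limit_um, 300)
  # noisy double crossing: first crossing wins, with a warning
  expect_warning(
    noisy <- depth_limit(tibble::tibble(
      depth_um = c(100, 200, 300, 400), sbr = c(2, 0.8, 1.4, 0.5))),
    "more than once")
  expect_lt(noisy$depth_limit_um, 200)
  expect_equal(noisy$n_crossings, 2L)
  expect_error(depth_limit(tibble::tibble(depth_um = 1, sbr = 2)),
               "two depths")
  expect_error(depth_limit(tibble::tibble(depth_um = c(1, 2),
                                          sbr = c(1, -2))), "positive")
})

test_that("depth limit is monotone in the background coefficient", {
  ph <- uniform_phantom(conc = 1, nz = 40L, voxel = 5)
  laser <- laser_config()
  limits <- vapply(c(0.005, 0.02, 0.08), function(bc) {
    opt <- optics_config(background_coefficient = bc)
    curve <- sbr_rate_curve(ph, seq(600, 1400, by = 25), laser, opt)
    suppressWarnings(depth_limit(
      tibble::tibble(depth_um = curve$depth_um,
                     sbr = curve$sbr))$depth_limit_um)
  }, numeric(1))
  expect_true(all(diff(limits) <= 0))
})

test_that("count-rate budget matches the saturating closed form", {
  geom <- array_geometry()
  scan <- scan_config(nx = 16L, ny = 16L, pulses_per_pixel = 4L,
                      frames_averaged = 1L, fov_um = 100)
  n_pulses <- 16 * 16 * 4
  lambda <- 0.15
  set.seed(9)
  conn <- connected_ids(geom)
  hit <- matrix(stats::runif(n_pulses * 24) < (1 - exp(-lambda)),
                n_pulses, 24)
  idx <- which(hit, arr.ind = TRUE)
  ev <- tibble::tibble(pulse = as.numeric(idx[, 1] - 1),
                       pixel = conn[idx[, 2]], bin = 0L)
  st <- event_stream(n_pulses, 1e6, geom, ev,
                     triggers = snspdsim:::scan_triggers(scan), scan = scan)
  budget <- count_rate_budget(st, scan)
  expected <- 1e6 * (1 - exp(-lambda))
  expect_lt(abs(budget$mean_pixel_cps - expected) / expected, 0.05)
  expect_true(budget$array_total_cps <= 24 * 1e6)
  expect_true(budget$peak_decile_cps <= 24 * 1e6)
  # dark-only stream: measured total matches the configured dark rate
  pixels <- pixel_bank(geom, dark_rate_cps = 5e4, seed = 3L)
  set.seed(10)
  dk <- dark_events(n_pulses / 1e6, pixels)
  ev_dark <- tibble::tibble(pulse = floor(dk$time_s * 1e6),
                            pixel = dk$pixel,
                            bin = sample(0:124, nrow(dk), replace = TRUE))
  st_dark <- event_stream(n_pulses, 1e6, geom, ev_dark,
                          triggers = snspdsim:::scan_triggers(scan),
                          scan = scan)
  b_dark <- count_rate_budget(st_dark, scan, pixels = pixels)
  total_dark <- sum(pixels$dark_rate_cps[pixels$connected])
  expect_lt(abs(b_dark$array_total_cps - total_dark) / total_dark, 0.15)
  expect_gt(b_dark$dark_fraction, 0.8)
  st_empty <- event_stream(100, 1e6, geom,
                           tibble::tibble(pulse = numeric(),
                                          pixel = integer(),
                                          bin = integer()))
  expect_error(count_rate_budget(st_empty), "empty")
})

test_that("count map normalises totals and tracks the footprint", {
  geom <- array_geometry()
  opt <- optics_config()
  fp <- detector_footprint(0, opt, geom)
  conn <- connected_ids(geom)
  w <- as.vector(t(fp$weights))[conn + 1L]
  lam <- 0.05
  n_pulses <- 4e4
  set.seed(12)
  p <- 1 - exp(-lam * w / max(w))
  hit <- matrix(stats::runif(n_pulses * 24), n_pulses, 24) <
    matrix(p, n_pulses, 24, byrow = TRUE)
  idx <- which(hit, arr.ind = TRUE)
  st <- event_stream(n_pulses, 1e6, geom,
                     tibble::tibble(pulse = as.numeric(idx[, 1] - 1),
                                    pixel = conn[idx[, 2]], bin = 0L))
  cm <- count_map(st, geom)
  expect_true(all(is.na(cm$map[!geom$connected])))
  expect_equal(max(cm$map, na.rm = TRUE), 1)
  # the brightest pixel is one of the four central ones
  centre <- cm$map[3:4, 3:4]
  expect_true(any(centre == 1))
  # edge/centre count ratio follows the footprint weight ratio
  ratio_obs <- cm$map[1, 3] / cm$map[3, 3]
  ratio_exp <- fp$weights[1, 3] / fp$weights[3, 3]
  expect_lt(abs(ratio_obs - ratio_exp), 0.05)
})

test_that("bias sweep recovers critical currents within one step", {
  geom <- array_geometry()
  pixels <- pixel_bank(geom, seed = 8L)
  conn <- pixels[pixels$connected, ]
  currents <- seq(0, 12, by = 0.25)
  set.seed(13)
  for (i in seq_len(nrow(conn))) {
    sw <- bias_sweep(conn[i, ], currents, lambda = 0.5, n_pulses = 2000L)
    # counts vanish above I_c and the plateau is flat within counting noise
    above <- sw$sweep$bias_ua > conn$i_c_ua[i]
    expect_true(all(sw$sweep$counts[above] == 0))
    plateau <- sw$sweep$bias_ua >= conn$i_sat_ua[i] &
      sw$sweep$bias_ua <= conn$i_c_ua[i]
    expect_true(all(sw$sweep$normalized[plateau] > 0.85))
    expect_lte(abs(sw$i_c_estimate_ua - conn$i_c_ua[i]), 0.25 + 1e-9)
  }
})
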