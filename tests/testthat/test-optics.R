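test_that("focal signal rate obeys identity, square law and closed forms", {
  ph <- uniform_phantom(conc = 1)
  laser <- laser_config()
  opt <- optics_config(brightness_scale = 5)
  ext <- ph$config$volume_shape * ph$config$voxel_size_um
  center <- c(ext[1] / 2, ext[2] / 2, ph$depth_axis_um[1])
  # z ~ 0 (first voxel plane), unit concentration, E = E_ref -> brightness
  r0 <- focal_signal_rate(ph, center, laser, opt,
                          surface_pulse_energy_nj = laser$e_ref_nj)
  z0 <- ph$depth_axis_um[1]
  expect_equal(r0, 5 * exp(-2 * z0 / opt$l_ex_um) * exp(-z0 / opt$l_em_um))
  # two-photon square law
  r2 <- focal_signal_rate(ph, center, laser, opt,
                          surface_pulse_energy_nj = 2 * laser$e_ref_nj)
  expect_equal(r2 / r0, 4)
  # z = l_ex / 2 with negligible emission attenuation -> e^-1
  opt_inf <- optics_config(brightness_scale = 5, l_ex_um = 100, l_em_um = 1e9)
  focus <- c(ext[1] / 2, ext[2] / 2, 50)
  r <- focal_signal_rate(ph, focus, laser, opt_inf,
                         surface_pulse_energy_nj = laser$e_ref_nj)
  expect_equal(r, 5 * exp(-1), tolerance = 1e-6)
  expect_error(focal_signal_rate(ph, c(-5, 10, 10), laser, opt), "outside")
})

test_that("depth sweep recovers the -2/l_ex - 1/l_em log slope within 1%", {
  ph <- uniform_phantom(conc = 1, nz = 40L, voxel = 5)
  laser <- laser_config()
  opt <- optics_config(l_ex_um = 365, l_em_um = 270)
  ext <- ph$config$volume_shape * ph$config$voxel_size_um
  zs <- seq(12.5, 187.5, by = 12.5)
  rates <- vapply(zs, function(z) {
    focal_signal_rate(ph, c(ext[1] / 2, ext[2] / 2, z), laser, opt,
                      surface_pulse_energy_nj = laser$e_ref_nj)
  }, numeric(1))
  expect_true(all(diff(rates) < 0)) # strictly decreasing
  slope <- stats::coef(stats::lm(log(rates) ~ zs))[[2]]
  expect_lt(abs(slope - (-2 / 365 - 1 / 270)) / abs(-2 / 365 - 1 / 270), 0.01)
})

test_that("surface power schedule compensates depth until the power cap", {
  laser <- laser_config() # cap: 100 mW / 1 MHz = 100 nJ
  opt <- optics_config(l_ex_um = 365)
  e_shallow <- surface_pulse_energy(0, laser, opt)
  expect_equal(as.numeric(e_shallow), laser$pulse_energy_focus_nj)
  z_cap <- 365 * log(100 / 2)
  expect_warning(e_deep <- surface_pulse_energy(z_cap + 50, laser, opt),
                 "cap")
  expect_equal(as.numeric(e_deep), 100)
})

test_that("background rate is zero without coefficient and grows with depth", {
  ph <- uniform_phantom(conc = 0.4)
  laser <- laser_config()
  expect_equal(background_rate(ph, 300, laser,
                               optics_config(background_coefficient = 0)), 0)
  opt <- optics_config(background_coefficient = 0.01)
  zs <- seq(0, 180, by = 20)
  bg <- background_rate(ph, zs, laser, opt)
  expect_true(all(diff(bg) >= 0))
})

test_that("rate-level SBR decays monotonically and yields the calibrated depth limit", {
  ph <- uniform_phantom(conc = 1, nz = 40L, voxel = 5)
  laser <- laser_config()
  # calibrate the background coefficient so the rate-ratio SBR is exactly 1
  # at 1150 um (surface energies cancel in the ratio, so this is closed form)
  target <- 1150
  opt0 <- optics_config()
  signal_1150 <- opt0$brightness_scale *
    exp(-2 * target / opt0$l_ex_um - target / opt0$l_em_um)
  bc <- signal_1150 / 1 # shallow concentration is 1 on the uniform phantom
  opt <- optics_config(background_coefficient = bc)
  curve <- sbr_rate_curve(ph, seq(900, 1300, by = 20), laser, opt,
                          concentration = 1)
  expect_true(all(diff(curve$sbr) <= 1e-12))
  dl <- depth_limit(tibble::tibble(depth_um = curve$depth_um,
                                   sbr = curve$sbr))
  expect_true(dl$limit_reached)
  # log SBR is exactly linear in depth, so interpolation is exact
  expect_equal(dl$depth_limit_um, target, tolerance = 0.1)
})

test_that("footprint matches quadrature, symmetry and the delta limit", {
  geom <- array_geometry()
  # delta limit: all light in the four centre pixels
  opt_delta <- optics_config(footprint_ballistic_fwhm_um = 1e-3,
                             footprint_halo_fraction = 0)
  fp <- detector_footprint(0, opt_delta, geom)
  expect_equal(sum(fp$weights[3:4, 3:4]), 1, tolerance = 1e-12)
  # pure ballistic Gaussian vs a fine-grid numerical quadrature oracle
  opt_g <- optics_config(footprint_ballistic_fwhm_um = 15,
                         footprint_halo_fraction = 0)
  fp <- detector_footprint(0, opt_g, geom)
  sigma <- 15 / (2 * sqrt(2 * log(2)))
  h <- 0.05
  gx <- seq(-30 + h / 2, 30 - h / 2, by = h)
  dens <- stats::dnorm(gx, 0, sigma) * h
  cell <- function(r, c) {
    ix <- gx >= (c - 4) * 10 & gx < (c - 3) * 10
    iy <- gx >= (r - 4) * 10 & gx < (r - 3) * 10
    sum(dens[ix]) * sum(dens[iy])
  }
  for (rc in list(c(3, 3), c(3, 4), c(1, 3), c(2, 5))) {
    num <- cell(rc[1], rc[2])
    expect_lt(abs(fp$weights[rc[1], rc[2]] - num) / num, 1e-3)
  }
  # 4-fold symmetry for a centred spot; weights + spill-over total 1
  fp_def <- detector_footprint(0, optics_config(), geom)
  w <- fp_def$weights
  expect_equal(w, w[6:1, ], tolerance = 1e-12)
  expect_equal(w, w[, 6:1], tolerance = 1e-12)
  expect_equal(w, t(w), tolerance = 1e-12)
  expect_true(all(w >= 0))
  expect_equal(sum(w) + fp_def$spill_over, 1, tolerance = 1e-12)
})

test_that("default footprint gives edge pixels ~10x fewer counts than centre", {
  fp <- detector_footprint(0, optics_config())
  ratio <- fp$weights[1, 3] / fp$weights[3, 3]
  expect_lt(abs(ratio - 0.1), 0.015)
  # the scattered halo broadens with depth: more light misses the array
  fp_deep <- detector_footprint(800, optics_config())
  expect_gt(fp_deep$spill_over, fp$spill_over)
})
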