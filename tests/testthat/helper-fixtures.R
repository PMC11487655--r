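# Shared fixtures: all inputs are generated in code at test time.

# A small uniform (vessel-free) phantom with unit concentration everywhere,
# handy for rate checks where geometry should not matter.
uniform_phantom <- function(conc = 1, nz = 40L, voxel = 5) {
  cfg <- phantom_config(volume_shape = c(24L, 24L, nz), voxel_size_um = voxel,
                        vessel_count = 0L, dye_concentration = conc,
                        background_concentration = conc, seed = 1L)
  generate_phantom(cfg)
}

# One straight axial vessel (along z) through the middle of a small volume.
axial_vessel_phantom <- function(radius_um = 2, voxel = 1, n_xy = 21L,
                                 nz = 9L, background = 0.01) {
  cfg <- phantom_config(volume_shape = c(n_xy, n_xy, nz),
                        voxel_size_um = voxel, vessel_count = 1L,
                        diameter_range_um = c(2 * radius_um,
                                              2 * radius_um + 1e-9),
                        dye_concentration = 1,
                        background_concentration = background, seed = 1L)
  mid <- n_xy * voxel / 2
  vessel <- list(radius_um = radius_um,
                 centerline = cbind(x = c(mid, mid), y = c(mid, mid),
                                    z = c(0, nz * voxel)))
  phantom_from_vessels(cfg, list(vessel))
}

# A compact run configuration that keeps simulations desk-scale in tests.
small_run_config <- function(seed = 1L, ...) {
  utils::modifyList(list(
    phantom = list(volume_shape = c(48L, 48L, 30L), voxel_size_um = 2.5,
                   vessel_count = 4L, diameter_range_um = c(3, 8),
                   axial_fraction = 1),
    scan = list(nx = 32L, ny = 32L, pulses_per_pixel = 4L,
                frames_averaged = 2L, fov_um = 120),
    depths_um = c(20, 40, 60),
    seed = seed), list(...))
}

# Hand-built event stream: explicit events/triggers on the default geometry.
manual_stream <- function(events, n_pulses, scan = NULL, triggers = NULL,
                          rep_rate = 1e6) {
  if (is.null(triggers) && !is.null(scan)) triggers <- NULL # derived later
  event_stream(n_pulses = n_pulses, rep_rate_hz = rep_rate,
               geometry = array_geometry(), events = events,
               triggers = triggers, gate = gate_config(), scan = scan)
}
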