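# Desk-scale demo configuration: a small vascular volume imaged at three
# shallow depths in all three readout modes. Unspecified blocks fall back to
# the package defaults (see default_run_config()).
phantom:
  volume_shape: [48, 48, 30]
  voxel_size_um: 2.5
  vessel_count: 4
  diameter_range_um: [3.0, 8.0]
  axial_fraction: 1.0
scan:
  nx: 32
  ny: 32
  pulses_per_pixel: 4
  frames_averaged: 2
  fov_um: 120
depths_um: [20.0, 40.0, 60.0]
modes: [analog, digital_gated, digital_ungated]
seed: 1
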