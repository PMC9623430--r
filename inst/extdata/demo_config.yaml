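# Demo configuration for run_pipeline(). All randomness derives from `seed`.
seed: 42
timelapse:
  enzyme: gapdh2        # gapdh2 or prk kinetic preset
  n_cells: 10
  image_shape: [192, 192]
  noise_sd: 0.05        # additive Gaussian intensity noise
nadph:
  baseline: 2.0
  amplitude: 1.0
  oxidation_rate: 0.5   # s^-1, true dark re-oxidation rate
  steady_offset: 1.5
  noise_sd: 0.02
  sample_interval: 0.02 # s
  n_replicates: 4
study:
  intensities: [0, 25, 50, 100, 200, 400]  # umol photons m^-2 s^-1
  n_cells: 10
  image_shape: [192, 192]
  noise_frac: 0.05
segmentation:
  min_area: 50          # px^2
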