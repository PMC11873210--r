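# Quickstart: small synthetic end-to-end run (synthetic HRTF cohort,
# synthetic corpus prior, 200-direction grid).
seed: 1
output_dir: soundloc-quickstart
filterbank: {f_lo: 300, f_hi: 12000, spacing_erb: 1}
grid:
  n_directions: 200
  min_elevation_deg: -45
  region: {max_lateral_deg: 30, max_polar_band_deg: 60}
hrtf: {type: synthetic, n_subjects: 2}
prior: {type: synthetic, n_frames: 5000}
noise: {sigma_itd_jnd: 1, sigma_channel_db: 1}
experiments:
  ripple:
    representations: [ISD, BIN_SG]
    depth_db: [40]
    density: [0.25, 1, 8]
    phase: [0]
  flat:
    variants: [ISD, BIN_SG]
plots: false
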