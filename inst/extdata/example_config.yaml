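# Example run configuration (all keys optional; defaults shown in ?lv_config)
geometry:
  target_h: 0.005          # m
  truncation_fraction: 0.75
material:
  a_f_sim: 1000            # Pa, fibre stiffness held fixed during sweeps
  b: 5
  b_f: 5
  gamma_grid: {n: 23, lo: 0.3, hi: 2.0}
bcs:
  mode: RV                 # NT or RV
  eps_e: 5.0e-6            # m/Pa
  eps_b: 5.0e-6            # m/Pa
estimation:
  n_refine: 8
  thetas: [50, 60, 70]     # deg
  ref_frames: [0, 2, 4]    # frames after end-systole
synthetic:
  preset: volunteer
  seed: 1
  sigma_mm: 0.5
  n_frames: 10
output_dir: results
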