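# Demo configuration for the command-line front end:
#   eptycho simulate --config demo-run.yaml --out cube/
#   eptycho reconstruct --config demo-run.yaml --data cube/ --out recon.rds
seed: 7
beam:
  energy_keV: 20
  alpha_mrad: 30
phantom:
  kind: lattice_patches
  n_pixels: 220
  pixel_size_pm: 100
  phase_max: 0.5
geometry:
  detector_pixels: 64
  pixel_pitch_um: 75
  frame_time_s: 0.005
  gain: 0.85
  beam_current_pA: 85
  scan_step_nm: 0.4
  grid_shape: [8, 8]
  defocus_nm: -20
  electrons_per_position: 100000
engine:
  probe_defocus_guess_nm: -20
  schedule:
    - algorithm: ePIE
      iterations: 30
    - algorithm: LSQML
      iterations: 10
distortion:
  tol_peak_pct: 1.0
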