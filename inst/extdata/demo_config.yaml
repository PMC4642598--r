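version: 1
seed: 1
simulate:
  preset: multi_tube
  n_frames: 10
  sweep_start_x: 10
  sweep_end_x: 90
  frame_width: 320
  frame_height: 240
  pixel_scale: [0.2, 0.2]
  jitter_translation_mm: 0.3
  jitter_rotation_deg: 0.3
  speckle_sigma: 8
  shadow_probability: 0.0
  misalignment:
    translation: [3.0, -2.0, 1.5]
    rotation_axis: [0.2, 1.0, 0.5]
    rotation_deg: 4.0
vesselness:
  beta: 1.0
  c_sensitivity: 10.0
dip:
  v_min: 20
  v_max: 50
  blur_sigma: 2.0
  stride: 2
segmentation:
  T_d_fraction: 0.5
  intensity_prior: [0, 80]
registration:
  mode: landmark_icp
  max_iterations: 100
  rms_change_tol: 1.0e-4
evaluation:
  radius: 35
  threshold: 10
  bin_width: 5
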