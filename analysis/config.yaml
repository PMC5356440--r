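# Study conditions for the full analysis workflow (scripts 01-06).
# Field and acquisition geometry mirror a confluent epithelial monolayer
# imaged at 0.1 um/px; every stochastic stage derives from `seed`.
seed: 42
field: [30.0, 30.0]
pixel_size: 0.1
stages: []               # set per script
mosaic:
  n_cells: 6
puncta:
  base_density: 0.2
  junction_density: 8.0
  band_width: 0.4
  amplitude: 100.0
  punct_sigma: 0.15
  background: 5.0
  noise_sd: 2.0
  arms:
    control: 1.0
    treated: 0.5
profiles:
  n_positions: 20
  span: 2.0
  n_samples: 21
filaments:
  n_filaments: 150
  target_angle: 70.0
  kappa: 2.0
  length_range: [2.0, 6.0]
targeting:
  box_side: 10.0
  lo: 45.0
  hi: 90.0
  d_contact: 0.25
comets:
  density: 25.0
  area_range: [0.3, 1.0]
  noise_sd: 2.0
  background_method: median
  threshold_method: otsu
  area_min: 0.2
  area_max: 1.2
  box_side: 10.0
tracks:
  cells_per_treatment: 4
  tracks_per_cell: 12
  v_growth: 12.0
  treated_v_growth: 6.3
  v_sd: 1.5
  p_gp: 0.1
  p_pg: 0.3
  frame_interval: 2.0
  n_frames: 60
  theta_max: 30.0
  pause_speed_max: 1.5
  min_pause_frames: 2
stats:
  alpha_normality: 0.05
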