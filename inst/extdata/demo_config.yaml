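# Demo pipeline configuration: a small synthetic scene carried through
# profiles, targeting, comet detection, track dynamics and statistics.
# Every stochastic stage derives its RNG stream from `seed`.
seed: 42
field: [20.0, 20.0]
pixel_size: 0.1
stages: [simulate, profiles, targeting, comets, tracks, stats]
mosaic:
  n_cells: 5
puncta:
  base_density: 0.2        # background puncta per um^2
  junction_density: 8.0    # junctional puncta per um at enrichment 1
  band_width: 0.4          # um
  amplitude: 100.0
  punct_sigma: 0.15        # um
  background: 5.0
  noise_sd: 2.0
  arms:                    # junctional enrichment factor per treatment arm
    control: 1.0
    treated: 0.5
profiles:
  n_positions: 8
  span: 2.0                # um
  n_samples: 21
filaments:
  n_filaments: 80
  target_angle: 70.0       # degrees to the junction tangent
  kappa: 2.0
  length_range: [2.0, 5.0]
targeting:
  box_side: 10.0           # um
  lo: 45.0
  hi: 90.0
  d_contact: 0.25          # um
comets:
  density: 25.0            # per 100 um^2
  area_range: [0.3, 1.0]   # um^2 true spot areas
  noise_sd: 2.0
  background_method: median
  threshold_method: otsu
  area_min: 0.2            # um^2 detection gate
  area_max: 1.2
  box_side: 10.0
tracks:
  cells_per_treatment: 3
  tracks_per_cell: 10
  v_growth: 12.0           # um/min, control
  treated_v_growth: 6.3    # um/min, treated arm
  v_sd: 1.5
  p_gp: 0.1
  p_pg: 0.3
  frame_interval: 2.0      # s
  n_frames: 40
  theta_max: 30.0          # degrees, bend split
  pause_speed_max: 1.5     # um/min
  min_pause_frames: 2
stats:
  alpha_normality: 0.05
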