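# Demonstration run: one simulated collared wolf (about 1300 four-hourly
# fixes over seven months) on a 40 km synthetic lowland landscape, analysed
# end to end. All stage parameters are at their reference values; only the
# seed needs choosing.
seed: 1
crs: EPSG:32632
fix_interval_h: 4
tolerance_min: 10
bbmm:
  delta: 30            # GPS location error SD, m
  grid_resolution: 100 # UD cell size, m
  integration_points: 30
  max_gap_days: 7
  level: 0.95
segmentation:
  exploration_min_h: 12
  predispersal_min_days: 6
  post_release_min_days: 2
  buffer_m: 0
stats:
  n_perm: 10000
resting:
  radius: 250          # m
  min_hours: 6
  merge_dist: 500      # m
  max_elev: 300        # m a.s.l.: the lowland plain
selection:
  n_avail: 25
  radii_density: [50, 100, 250, 500]
  radii_metrics: [250, 500]
  decay_scale: 500     # m
  cor_threshold: 0.7
  delta_aic: 2
simulate: {}           # sim_config() defaults
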