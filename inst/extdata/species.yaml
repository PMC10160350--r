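# Species-specific filter criteria for the video analysis.
# Areas are contour areas in square pixels; brightness is mean 8-bit grey
# level inside the object; the optimal percentile is the calibrated
# percentile of the per-video length distribution. All taxa share the
# global minimum sharpness (1.8) and minimum centre-to-edge distance
# (10 px). The daphnia row doubles as the default profile.
daphnia:
  min_area_px: 1500
  max_area_px: 4000
  min_lw_ratio: 1.2
  max_lw_ratio: 1.7
  min_brightness: 30
  optimal_percentile: 93
  min_sharpness: 1.8
  min_edge_distance_px: 10
eucyclops_mesocyclops:
  min_area_px: 290
  max_area_px: 850
  min_lw_ratio: 1.3
  max_lw_ratio: 1.9
  min_brightness: 20
  optimal_percentile: 90
  min_sharpness: 1.8
  min_edge_distance_px: 10
diaphanosoma:
  min_area_px: 300
  max_area_px: 2500
  min_lw_ratio: 1.5
  max_lw_ratio: 2.5
  min_brightness: 20
  optimal_percentile: 100
  min_sharpness: 1.8
  min_edge_distance_px: 10
heterocope:
  min_area_px: 600
  max_area_px: 4000
  min_lw_ratio: 1.6
  max_lw_ratio: 2.2
  min_brightness: 20
  optimal_percentile: 100
  min_sharpness: 1.8
  min_edge_distance_px: 10
polyphemus:
  min_area_px: 250
  max_area_px: 1000
  min_lw_ratio: 1.0
  max_lw_ratio: 1.7
  min_brightness: 20
  optimal_percentile: 98
  min_sharpness: 1.8
  min_edge_distance_px: 10
scapholebrius:
  min_area_px: 250
  max_area_px: 1800
  min_lw_ratio: 1.0
  max_lw_ratio: 1.7
  min_brightness: 20
  optimal_percentile: 96
  min_sharpness: 1.8
  min_edge_distance_px: 10
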