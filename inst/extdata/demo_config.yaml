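# Demonstration pipeline configuration: one synthetic 11.28-m plot with the
# default acquisition settings and a fixed seed. Point output_dir somewhere
# writable before running.
output_dir: demo_out
seed: 42
scene:
  n_trees: 8
  burned_fraction: 0.66
  color_noise_sd: 10
  shadow_fraction: 0.2
  point_density: 640
  plot_radius: 11.28
  ortho_cell: 0.0441
full_scorch_fraction: 0.75
params:
  chm_cell: 0.10
  sigma: 0.05
  min_height: 2.0
  plot_radius: 11.28
  min_area: 0.3
  match_dist: 2.0
  match_height_tol: 0.3
  gli_threshold: 0.5
  slice: 0.10
  smoothing: 0.65
  cbh_bin: 0.25
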