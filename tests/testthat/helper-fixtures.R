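# Shared fixtures, built once per test run. Everything is generated in code;
# the cache only avoids re-running the generator for every test block.

.fixtures <- new.env(parent = emptyenv())

# noiseless 6-tree plot with uniform (partial) scorch heights, fully analyzed
fx_clean <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- scene_config(n_trees = 6, color_noise_sd = 0, shadow_fraction = 0,
                        seed = 7)
    truths <- simulate_truths(cfg, full_scorch_fraction = 0)
    scene <- generate_scene(truths, cfg)
    res <- suppressWarnings(analyze_plot(scene$cloud, truth = scene$truth))
    .fixtures$clean <- list(cfg = cfg, truth = scene$truth,
                            cloud = scene$cloud, res = res)
  }
  .fixtures$clean
}

# one noiseless tree with a known scorch height, as a standalone cloud
fx_tree <- function(total_height = 12, cbh = 3, scorch = 6, radius = 1.5,
                    seed = 3, density = 640) {
  cfg <- scene_config(color_noise_sd = 0, shadow_fraction = 0, seed = seed,
                      point_density = density)
  tt <- tree_truth(1L, 0, 0, total_height, cbh, scorch, crown_radius = radius)
  generate_tree_points(tt, cfg, seed = seed)
}

# colors whose GLI is exactly the requested value (b = 0, solve for g)
color_for_gli <- function(v, r = 100) {
  g <- r * (1 + v) / (2 * (1 - v))
  list(r = r, g = g, b = 0)
}
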