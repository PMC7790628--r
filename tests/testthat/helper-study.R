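# Shared fixtures, generated in code. Landscapes are cached per seed so the
# heavier suites reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# planar ramp dipping south: z drops `drop` metres over the grid height
ramp_grid <- function(n = 11, cell = 10, drop = 100, base = 0) {
  vals <- matrix(rep(seq(base + drop, base, length.out = n), n), n, n)
  grid_raster(vals, origin = c(0, n * cell), cell_size = cell)
}

# small rugged DEM without the landscape generator (independent of it)
rugged_dem <- function(n = 50, cell = 30, seed = 42) {
  set.seed(seed)
  r <- outer(seq_len(n), seq_len(n), function(i, j)
    400 * sin(i / 5) + 300 * cos(j / 7))
  grid_raster(3500 + r + matrix(rnorm(n * n, 0, 40), n, n),
              origin = c(0, n * cell), cell_size = cell)
}

# compact synthetic study (smaller landscape, lighter effort) for unit tests
small_study <- function(seed, det = detection_model(), truth = population_truth()) {
  cached(sprintf("small_study_%d_%g_%g_%s_%g", seed, det$rate_per_m,
                 det$max_distance_m, det$require_line_of_sight,
                 truth$true_density_ind_per_km2), {
    cfg <- landscape_config(extent_m = c(7200, 7200), cell_size_m = 90,
                            ridge_count = 5, noise_amplitude_m = 120,
                            seed = seed)
    simulate_study(seed = seed, config = cfg, det = det, truth = truth,
                   n_transects = 12, target_length_m = 2100,
                   n_settlements = 2)
  })
}

# covariates used in model fits throughout the suite
model_covariates <- c("elevation", "slope_deg", "south_deviation_deg", "ndvi",
                      "dist_stream_m", "dist_settlement_m", "dist_trail_m",
                      "livestock_presence")
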