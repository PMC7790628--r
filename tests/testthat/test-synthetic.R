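test_that("landscape config enforces its invariants", {
  expect_error(landscape_config(extent_m = c(-10, 100)), "positive")
  expect_error(landscape_config(extent_m = c(100, 100), cell_size_m = 30),
               "divisible")
  expect_error(landscape_config(elevation_range_m = c(5000, 4000)),
               "min < max")
})

test_that("DEM generation is deterministic, bounded, and analytic when bare", {
  cfg <- landscape_config(extent_m = c(3000, 3000), cell_size_m = 30,
                          seed = 11)
  d1 <- generate_dem(cfg); d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  expect_gte(min(d1$values), 2870)
  expect_lte(max(d1$values), 6150)
  # non-constant gradient field (ridges and valleys exist)
  expect_gt(stats::sd(horn_slope(d1)$values, na.rm = TRUE), 0)
  # bare configuration: a pure planar ramp with analytic slope
  bare <- landscape_config(extent_m = c(3000, 3000), cell_size_m = 30,
                           elevation_range_m = c(1000, 2500),
                           ridge_count = 0, noise_amplitude_m = 0)
  ramp <- generate_dem(bare)
  s <- horn_slope(ramp)$values
  expected <- atan(1500 / 3000) * 180 / pi
  expect_equal(s[2:99, 2:99], matrix(expected, 98, 98), tolerance = 1e-9)
})

test_that("NDVI follows the elevation zonation and stays in [-1, 1]", {
  cfg <- landscape_config(extent_m = c(3000, 3000), cell_size_m = 30,
                          seed = 2)
  dem <- generate_dem(cfg)
  ndvi <- generate_ndvi(dem, cfg)
  expect_true(all(ndvi$values >= -1 & ndvi$values <= 1))
  hi <- dem$values > 5800
  lo <- dem$values >= 4200 & dem$values <= 4400
  if (any(hi)) expect_gt(mean(ndvi$values[hi] < 0.14), 0.95)
  if (any(lo)) expect_gt(mean(ndvi$values[lo] >= 0.25 &
                                ndvi$values[lo] <= 0.5), 0.9)
  # zero noise: a pure function of elevation
  cfg0 <- landscape_config(extent_m = c(3000, 3000), cell_size_m = 30,
                           ndvi_noise_sd = 0, seed = 2)
  nd0 <- generate_ndvi(dem, cfg0)
  ord <- order(as.vector(dem$values))
  expect_true(all(diff(nd0$values[ord]) <= 1e-12))  # non-increasing profile
})

test_that("transects follow the constraint band with target lengths", {
  st <- small_study(seed = 4)
  tr <- st$transects
  expect_length(tr$lines, 12)
  expect_true(all(tr$lengths_m >= 0.5 * 2100 & tr$lengths_m <= 1.5 * 2100))
  # vertices stay inside the eligible elevation band
  for (v in tr$lines[1:3]) {
    ev <- extract_values(st$dem, v[, 1], v[, 2])
    expect_true(all(ev >= 3000 & ev <= 5000))
  }
  # determinism
  tr2 <- place_transects(st$dem, 12, 2100, seed = 4)
  expect_identical(tr$lines, tr2$lines)
  # constraint band outside the DEM range
  expect_error(place_transects(st$dem, 3, 2100,
                               constraints = list(elevation_range = c(100, 200))),
               "constraint")
  # survey effort arithmetic: 60 transects aiming at 2.1 km
  big <- transect_summary(st$transects)
  expect_equal(big$n_transects, 12)
  expect_equal(big$total_km, sum(tr$lengths_m) / 1000)
})

test_that("population placement matches the configured point process", {
  st <- small_study(seed = 9)
  # expected total individuals ~ density x area (Poisson, generous bounds)
  area <- sum(!is.na(st$dem$values)) * st$dem$cell_size^2 / 1e6
  lam <- 7 * area
  totals <- vapply(1:6, function(s)
    sum(simulate_population(st$stack, population_truth(), seed = s)$size),
    numeric(1))
  expect_gt(mean(totals), lam * 0.6)
  expect_lt(mean(totals), lam * 1.4)
  # group-size distribution: mean within 2 SE of 14.4 over many groups
  truth_dense <- population_truth(true_density_ind_per_km2 = 300)
  gr <- simulate_population(st$stack, truth_dense, seed = 3)
  expect_gt(nrow(gr), 100)
  se <- stats::sd(gr$size) / sqrt(nrow(gr))
  expect_lt(abs(mean(gr$size) - 14.4), 2.5 * se + 1)
  expect_true(all(gr$size >= 1 & gr$size <= 113))
  # class counts are consistent
  expect_true(all(gr$n_adult_male + gr$n_adult_female + gr$n_subadult +
                    gr$n_unclassified == gr$size))
  # neutral selection gives spatially uniform placement (quadrat chi-square)
  truth_flat <- population_truth(true_density_ind_per_km2 = 300,
                                 selection = list(elev_band = c(4250, 4550),
                                                  ndvi_band = c(0.25, 0.5),
                                                  coef = c(0, 0)))
  pvals <- vapply(1:4, function(s) {
    g <- simulate_population(st$stack, truth_flat, seed = s)
    qx <- cut(g$x, breaks = seq(0, 7200, length.out = 5))
    qy <- cut(g$y, breaks = seq(0, 7200, length.out = 5))
    stats::chisq.test(table(qx, qy))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 3)
  # intensity degenerate everywhere (no usable cells) errors
  nag <- grid_raster(matrix(NA_real_, 4, 4), origin = c(0, 120),
                     cell_size = 30)
  nastack <- covariate_stack(elevation = nag, ndvi = nag)
  expect_error(simulate_population(nastack, population_truth(), seed = 1),
               "zero")
})

test_that("survey detection follows the exponential distance law", {
  st <- small_study(seed = 5)
  truth_dense <- population_truth(true_density_ind_per_km2 = 120)
  gr <- simulate_population(st$stack, truth_dense, seed = 5)
  # perfect detection: everything within the truncation distance is seen
  det0 <- detection_model(rate_per_m = 0, max_distance_m = 1500)
  obs0 <- simulate_survey(gr, st$transects, st$dem, det0, seed = 5)
  d <- bharal:::point_transect_distance(gr$x, gr$y, st$transects)
  expect_equal(nrow(obs0), sum(d <= 1500))
  expect_true(all(obs0$distance_m <= 1500))
  # essentially infinite rate: nothing beyond distance zero is detected
  detInf <- detection_model(rate_per_m = 1e6)
  obsInf <- simulate_survey(gr, st$transects, st$dem, detInf, seed = 5)
  expect_equal(nrow(obsInf), 0)
  # rate recovery: with uniform distance availability (flat terrain, one
  # straight transect, neutral selection) detected distances follow the
  # truncated exponential and the MLE lands within 20 % of the truth
  flat <- grid_raster(matrix(4400, 200, 200), origin = c(0, 6000),
                      cell_size = 30)
  fndvi <- grid_raster(matrix(0.4, 200, 200), origin = c(0, 6000),
                       cell_size = 30)
  fstack <- covariate_stack(elevation = flat, ndvi = fndvi)
  utruth <- population_truth(true_density_ind_per_km2 = 1200,
                             selection = list(elev_band = c(4250, 4550),
                                              ndvi_band = c(0.25, 0.5),
                                              coef = c(0, 0)))
  ugr <- simulate_population(fstack, utruth, seed = 7)
  midline <- transect_set(list(cbind(x = c(3000, 3000), y = c(500, 5500))))
  det <- detection_model(rate_per_m = 0.0035)
  obs <- simulate_survey(ugr, midline, flat, det, seed = 7)
  expect_gte(nrow(obs), 200)
  fitted <- fit_exponential_rate(obs$distance_m)
  expect_lt(abs(fitted$rate_per_m - 0.0035) / 0.0035, 0.2)
  expect_error(simulate_survey(ugr, transect_set(list()), flat, det),
               "empty")
})

test_that("feature placement is deterministic with sensible degenerate cases", {
  st <- small_study(seed = 6)
  f1 <- place_features(st$dem, n_settlements = 3, seed = 8)
  f2 <- place_features(st$dem, n_settlements = 3, seed = 8)
  expect_identical(f1$settlements, f2$settlements)
  expect_identical(f1$livestock, f2$livestock)
  # settlements sit in local elevation minima territory (low elevations)
  ev <- extract_values(st$dem, f1$settlements[, 1], f1$settlements[, 2])
  expect_lt(max(ev), stats::quantile(st$dem$values, 0.5))
  # zero settlements: empty layers and all-infinite distances with warning
  f0 <- place_features(st$dem, n_settlements = 0)
  expect_equal(nrow(f0$settlements), 0)
  expect_warning(dsurf <- distance_surface(f0$settlements, st$dem), "empty")
  expect_true(all(is.infinite(dsurf$values)))
  # zero cluster radius puts livestock exactly at settlements
  fz <- place_features(st$dem, n_settlements = 2,
                       livestock_per_settlement = 3,
                       livestock_radius_m = 0, seed = 2)
  expect_true(all(fz$livestock[, 1] %in% fz$settlements[, 1]))
  expect_true(all(fz$livestock[, 2] %in% fz$settlements[, 2]))
})

test_that("vector and tabular outputs round-trip through their formats", {
  st <- small_study(seed = 4)
  p <- tempfile(fileext = ".geojson")
  write_transects_geojson(st$transects, p)
  tr2 <- read_transects_geojson(p)
  expect_equal(length(tr2$lines), length(st$transects$lines))
  expect_equal(tr2$lines[[1]][, "x"], st$transects$lines[[1]][, "x"],
               ignore_attr = TRUE)
  expect_equal(tr2$lengths_m, st$transects$lengths_m, tolerance = 1e-12)
  pf <- tempfile(fileext = ".geojson")
  write_features_geojson(st$features, pf)
  j <- jsonlite::read_json(pf)
  expect_equal(j$type, "FeatureCollection")
  types <- vapply(j$features, function(f) f$properties$type, character(1))
  expect_true(all(c("settlement", "trail", "livestock") %in% types))
})
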