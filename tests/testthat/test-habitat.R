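test_that("exponential rate is the closed-form reciprocal mean", {
  expect_equal(fit_exponential_rate(rep(400, 10))$rate_per_m, 0.0025)
  # a sample with the mean of the published spring distances gives its rate
  d <- c(100, 200, 285.7142857, 400, 442.8571429)   # mean = 285.714...
  expect_equal(fit_exponential_rate(d)$rate_per_m, 0.0035, tolerance = 1e-9)
  # doubling the mean halves the rate
  r1 <- fit_exponential_rate(c(100, 300, 500))$rate_per_m
  r2 <- fit_exponential_rate(2 * c(100, 300, 500))$rate_per_m
  expect_equal(r1, 2 * r2)
  expect_error(fit_exponential_rate(numeric(0)), "two")
  expect_error(fit_exponential_rate(c(0, 0)), "zero")
})

test_that("pseudo-absence sampling is count-exact, seeded, and follows the law", {
  flat <- grid_raster(matrix(1000, 80, 80), origin = c(0, 4800),
                      cell_size = 60)
  tr <- transect_set(list(cbind(x = c(2400, 2400), y = c(400, 4400))))
  vs <- transect_viewshed(flat, tr, radius_m = 1500)
  pa <- generate_pseudo_absences(vs, tr, n_obs = 94, rate = 0.0035,
                                 n_candidates = 50000, seed = 21)
  expect_equal(nrow(pa), 9400)
  pa2 <- generate_pseudo_absences(vs, tr, n_obs = 94, rate = 0.0035,
                                  n_candidates = 50000, seed = 21)
  expect_identical(pa, pa2)
  # every point lies inside the viewshed
  expect_true(all(extract_values(vs$visible, pa$x, pa$y) == 1))
  expect_error(generate_pseudo_absences(vs, tr, n_obs = 94, rate = 0.0035,
                                        n_candidates = 500), "candidates")
  # rate 0: sampled distances match the candidate (uniform) distribution
  pa0 <- generate_pseudo_absences(vs, tr, n_obs = 40, rate = 0,
                                  n_candidates = 20000, seed = 3)
  ks <- suppressWarnings(
    stats::ks.test(pa0$distance_m, stats::runif(20000, 0, 1500)))
  expect_gt(ks$p.value, 0.01)
  # positive rate: binned sampled distances match the exponentially
  # reweighted availability of the viewshed (chi-square goodness of fit,
  # availability estimated from an independent uniform reference sample)
  set.seed(999)
  vis <- which(vs$visible$values == 1)
  cells <- vis[sample.int(length(vis), 200000, replace = TRUE)]
  rr <- (cells - 1) %% 80 + 1; cc <- (cells - 1) %/% 80 + 1
  rx <- (cc - 1) * 60 + runif(200000, 0, 60)
  ry <- 4800 - (rr - 1) * 60 - runif(200000, 0, 60)
  ref_d <- bharal:::point_transect_distance(rx, ry, tr)
  br <- seq(0, 1500, by = 150)
  ref_w <- exp(-0.0035 * ref_d)
  p_expected <- vapply(seq_len(length(br) - 1), function(b)
    sum(ref_w[ref_d >= br[b] & ref_d < br[b + 1]]), numeric(1))
  p_expected <- p_expected / sum(p_expected)
  ## sampling without replacement matches the target law when the sampling
  ## fraction is small (inclusion probabilities ~ weights); 1,000 of 50,000
  pvals <- vapply(1:3, function(s) {
    paX <- generate_pseudo_absences(vs, tr, n_obs = 10, rate = 0.0035,
                                    n_candidates = 50000, seed = s)
    obs_counts <- tabulate(cut(paX$distance_m, br, labels = FALSE),
                           nbins = length(br) - 1)
    suppressWarnings(stats::chisq.test(obs_counts,
                                       p = p_expected)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 2)
})

test_that("group size vs distance decides permute or linear attribution", {
  set.seed(5)
  n <- 80
  dist <- runif(n, 0, 1400)
  # uncorrelated case: sizes drawn from the observed support
  obs_u <- data.frame(distance_m = dist,
                      group_size = sample(c(1, 3, 7, 12, 30), n, TRUE))
  t_u <- test_groupsize_distance(obs_u)
  r_oracle <- sum((obs_u$group_size - mean(obs_u$group_size)) *
                    (obs_u$distance_m - mean(obs_u$distance_m))) /
    ((n - 1) * sd(obs_u$group_size) * sd(obs_u$distance_m))
  expect_equal(t_u$r, r_oracle, tolerance = 1e-12)
  pa <- data.frame(x = 0, y = 0, distance_m = runif(300, 0, 1400))
  if (t_u$p >= 0.05) {
    att <- attribute_group_sizes(pa, obs_u, seed = 2)
    expect_true(all(att$attributed_group_size %in% obs_u$group_size))
    expect_equal(attr(att, "groupsize_model")$strategy, "permute")
  }
  # strongly correlated case: linear attribution with OLS coefficients
  obs_c <- data.frame(distance_m = dist,
                      group_size = round(8.5 + 0.009 * dist + rnorm(n, 0, 1)))
  t_c <- test_groupsize_distance(obs_c)
  expect_lt(t_c$p, 0.05)
  att_c <- attribute_group_sizes(pa, obs_c, seed = 2)
  gm <- attr(att_c, "groupsize_model")
  expect_equal(gm$strategy, "linear")
  # OLS closed form as the oracle
  b_or <- cov(obs_c$distance_m, obs_c$group_size) / var(obs_c$distance_m)
  a_or <- mean(obs_c$group_size) - b_or * mean(obs_c$distance_m)
  expect_equal(gm$slope, b_or, tolerance = 1e-10)
  expect_equal(gm$intercept, a_or, tolerance = 1e-10)
  expect_equal(att_c$attributed_group_size,
               pmax(1, round_half_up(a_or + b_or * pa$distance_m, 0)))
  # the published coefficients imply 13 at 500 m and 8 at the transect
  expect_equal(pmax(1, round_half_up(8.498 + 0.009 * 500, 0)), 13)
  expect_equal(pmax(1, round_half_up(8.498 + 0.009 * 0, 0)), 8)
  # perfectly linear data
  obs_l <- data.frame(distance_m = 1:10, group_size = 2 * (1:10))
  t_l <- test_groupsize_distance(obs_l)
  expect_equal(t_l$r, 1)
  expect_lt(t_l$p, 1e-10)
  expect_error(test_groupsize_distance(
    data.frame(distance_m = 1:5, group_size = rep(3, 5))), "variance")
})

test_that("adult counts impute unclassified individuals by the global ratio", {
  obs <- data.frame(n_adult_male = c(2, 2, 0),
                    n_adult_female = c(2, 2, 0),
                    n_subadult = c(2, 2, 0),
                    n_unclassified = c(0, 3, 10))
  # R = (4 + 4) / (6 + 6) = 2/3
  expect_equal(adult_counts(obs), c(4, 4 + 3 * 2 / 3, 10 * 2 / 3))
  # dataset-level ratio 0.8
  obs8 <- data.frame(n_adult_male = 4, n_adult_female = 4, n_subadult = 2,
                     n_unclassified = 10)
  expect_equal(adult_counts(obs8), 8 + 10 * 0.8)
  expect_error(adult_counts(data.frame(n_adult_male = 0, n_adult_female = 0,
                                       n_subadult = 0, n_unclassified = 5)),
               "classified")
})

test_that("weights conserve the number of observations on both sides", {
  w <- compute_weights(rep(5, 10), rep(2, 40))
  expect_equal(w$presence, rep(1, 10))
  expect_equal(sum(w$pseudo_absence), 10)
  w2 <- compute_weights(c(2, 6), c(1, 2, 3))
  expect_equal(w2$presence, c(0.5, 1.5))
  expect_equal(sum(w2$presence), 2)
  expect_equal(sum(w2$pseudo_absence), 2)
  expect_error(compute_weights(c(0, 0), 1), "positive")
})

test_that("collinearity screen drops by priority at |r| >= 0.7", {
  set.seed(8)
  n <- 400
  slope <- runif(n, 0, 60)
  tri <- slope * 4 + rnorm(n, 0, 18)           # r ~ 0.95
  elev <- runif(n, 3000, 6000)
  fr <- data.frame(elevation = elev, slope_deg = slope, tri_m = tri)
  expect_gt(abs(cor(slope, tri)), 0.9)
  sc <- screen_collinearity(fr, retain_priority = c("elevation", "slope_deg"))
  expect_true("slope_deg" %in% sc$retained)
  expect_false("tri_m" %in% sc$retained)
  expect_equal(unname(sc$dropped["tri_m"]), "slope_deg")
  # a pair at exactly |r| = 0.7 is screened out
  x <- as.numeric(scale(rnorm(n)))
  z <- as.numeric(scale(residuals(lm(rnorm(n) ~ x))))
  y <- 0.7 * x + sqrt(1 - 0.49) * z
  fr2 <- data.frame(a = x, b = y)
  expect_equal(abs(cor(fr2$a, fr2$b)), 0.7, tolerance = 1e-10)
  sc2 <- screen_collinearity(fr2, threshold = 0.7 - 1e-12,
                             retain_priority = c("a", "b"))
  expect_equal(sc2$retained, "a")
  # weakly correlated variables all survive
  fr3 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_length(screen_collinearity(fr3)$retained, 3)
  # order stability: shuffling rows leaves the decision unchanged
  perm <- sample.int(n)
  sc_perm <- screen_collinearity(fr[perm, ],
                                 retain_priority = c("elevation", "slope_deg"))
  expect_equal(sc_perm$retained, sc$retained)
})

test_that("model frames filter forest presences and conserve weight", {
  st <- small_study(seed = 4)
  vs <- transect_viewshed(st$dem, st$transects, radius_m = 1500)
  rate <- fit_exponential_rate(st$obs$distance_m)
  pa <- generate_pseudo_absences(vs, st$transects, nrow(st$obs), rate,
                                 seed = 4)
  pa <- attribute_group_sizes(pa, st$obs, seed = 4)
  fr <- build_model_frame(st$obs, pa, st$stack,
                          covariates = model_covariates)
  np <- attr(fr, "n_presence"); na <- attr(fr, "n_pseudo_absence")
  expect_equal(nrow(fr), np + na)
  expect_equal(sum(fr$weight[fr$response == 1]), np)
  expect_equal(sum(fr$weight[fr$response == 0]), np)
  # forest exclusion via a class map drops presences and re-normalizes
  pts <- data.frame(
    class = rep(c("forest", "grassland", "barren"), each = 5),
    ndvi = c(seq(0.55, 0.8, length.out = 5), seq(0.25, 0.5, length.out = 5),
             seq(-0.1, 0.13, length.out = 5)))
  cr <- calibrate_ndvi_classes(pts, quantiles = c(0, 1))
  cm <- classify_ndvi(st$ndvi, cr,
                      priority = c("forest", "grassland", "barren"))
  fr_f <- build_model_frame(st$obs, pa, st$stack, classmap = cm,
                            exclude_forest = TRUE,
                            covariates = model_covariates)
  np_f <- attr(fr_f, "n_presence")
  expect_lte(np_f, np)
  expect_equal(sum(fr_f$weight[fr_f$response == 1]), np_f)
  expect_equal(sum(fr_f$weight[fr_f$response == 0]), np_f)
  # all presences in forest is degenerate
  allforest <- st$obs
  allforest_cm <- cm
  allforest_cm$values[] <- attr(cm, "legend")[["forest"]]
  expect_error(build_model_frame(allforest, pa, st$stack,
                                 classmap = allforest_cm,
                                 exclude_forest = TRUE,
                                 covariates = model_covariates),
               "presence")
  # points outside the raster extent are rejected
  obs_out <- st$obs
  obs_out$x[1] <- -50
  expect_error(build_model_frame(obs_out, pa, st$stack,
                                 covariates = model_covariates), "extent")
})

test_that("the weighted binomial GAM behaves at its analytic limits", {
  set.seed(77)
  n <- 5000
  frame <- data.frame(response = rbinom(n, 1, 0.3), weight = 1,
                      elevation = runif(n, 3000, 6000),
                      ndvi = runif(n, -0.2, 0.8))
  fit0 <- fit_habitat_gam(frame)
  expect_lt(fit0$deviance_explained, 0.02)   # response independent of covariates
  # step-function preference on elevation is recovered inside the band
  p <- ifelse(frame$elevation >= 4250 & frame$elevation <= 4550, 0.8, 0.1)
  frame2 <- frame
  frame2$response <- rbinom(n, 1, p)
  fit2 <- fit_habitat_gam(frame2)
  pk <- smooth_peak(fit2, "elevation")
  expect_gte(pk, 4250); expect_lte(pk, 4550)
  expect_gt(fit2$deviance_explained, 0.2)
  # doubling all weights leaves the fitted smooths unchanged once the
  # penalties scale with the likelihood (sp doubled alongside the weights)
  frame3 <- frame2
  frame3$weight <- 2
  fit3 <- fit_habitat_gam(frame3)
  fit3b <- mgcv::gam(response ~ s(elevation, k = 10) + s(ndvi, k = 10),
                     family = binomial(), weights = weight, data = frame3,
                     sp = 2 * fit2$gam$sp)
  sp2 <- smooth_partial(fit2, "elevation")
  nd <- fit2$gam$model
  prA <- predict(fit2$gam, newdata = nd, type = "link")
  prB <- predict(fit3b, newdata = nd, type = "link")
  expect_lt(max(abs(prA - prB)), 1e-4)
  # summary surface carries the Table-1 style quantities
  expect_true(all(c("edf", "ref_df", "chi_sq", "p") %in%
                    names(fit2$smooth_terms)))
  expect_true(fit2$adj_r2 <= 1)
  expect_true(fit2$deviance_explained >= 0 && fit2$deviance_explained <= 1)
})

test_that("prediction maps are consistent with row-level prediction", {
  set.seed(9)
  n <- 2000
  frame <- data.frame(response = rbinom(n, 1, 0.4), weight = 1,
                      elevation = runif(n, 3000, 6000),
                      ndvi = runif(n, -0.2, 0.8))
  frame$response <- rbinom(n, 1, plogis(-8 + 0.002 * frame$elevation))
  fit <- fit_habitat_gam(frame)
  g1 <- grid_raster(matrix(runif(100, 3000, 6000), 10, 10),
                    origin = c(0, 300), cell_size = 30)
  g2 <- grid_raster(matrix(runif(100, -0.2, 0.8), 10, 10),
                    origin = c(0, 300), cell_size = 30)
  stack <- covariate_stack(elevation = g1, ndvi = g2)
  pm <- predict_selection(fit, stack)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  nd <- data.frame(elevation = as.vector(g1$values),
                   ndvi = as.vector(g2$values))
  expect_equal(as.vector(pm$values),
               as.numeric(predict(fit$gam, newdata = nd, type = "response")),
               tolerance = 1e-12)
  # constant covariates give a constant map
  gc1 <- grid_raster(matrix(4400, 5, 5), cell_size = 30)
  gc2 <- grid_raster(matrix(0.4, 5, 5), cell_size = 30)
  pmc <- predict_selection(fit, covariate_stack(elevation = gc1, ndvi = gc2))
  expect_lt(diff(range(pmc$values)), 1e-10)
  expect_error(predict_selection(fit, covariate_stack(elevation = gc1)),
               "lacks")
})
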