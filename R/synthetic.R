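## Synthetic mountain landscapes, ungulate populations and transect surveys
## with known ground truth. Every generator is a pure function of
## (configuration, seed), so downstream estimators can be validated against
## the truth that produced the data.

#' Landscape generator configuration
#'
#' Describes a rugged high-mountain study area: a planar DEM built from a
#' north-south elevation ramp, parametric ridge/valley functions and
#' spectrally smoothed noise, plus an NDVI field that follows the elevation
#' zonation typical of the dry Trans-Himalaya (closed forest below timberline
#' around 4,000 m, grass/shrub to about 4,800 m, barren rock and snow above).
#'
#' @param extent_m width and height of the landscape in metres.
#' @param cell_size_m raster resolution (default 30 m, matching the commonly
#'   used spaceborne DEMs).
#' @param elevation_range_m minimum and maximum elevation; the default spans
#'   2,870-6,150 m.
#' @param ridge_count number of ridge/valley structures.
#' @param noise_amplitude_m amplitude of the smoothed random relief added on
#'   top of the parametric surface.
#' @param ndvi_profile piecewise-linear NDVI-against-elevation profile:
#'   a list with `knots_m` and `ndvi` of equal length.
#' @param ndvi_noise_sd standard deviation of cell-level NDVI noise.
#' @param seed integer seed; every generated artefact is deterministic in it.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent_m = c(6000, 6000),
                             cell_size_m = 30,
                             elevation_range_m = c(2870, 6150),
                             ridge_count = 5,
                             noise_amplitude_m = 120,
                             ndvi_profile = list(
                               knots_m = c(-Inf, 3800, 4000, 4800, 5100, Inf),
                               ndvi   = c(0.65, 0.65, 0.45, 0.28, 0.10, -0.05)),
                             ndvi_noise_sd = 0.03,
                             seed = 1L) {
  if (any(extent_m <= 0) || cell_size_m <= 0)
    stopf("extent and cell size must be positive")
  if (any(abs(extent_m / cell_size_m - round(extent_m / cell_size_m)) > 1e-9))
    stopf("extent must be divisible by the cell size")
  if (elevation_range_m[1] >= elevation_range_m[2])
    stopf("elevation range must have min < max")
  structure(list(extent_m = extent_m, cell_size_m = cell_size_m,
                 elevation_range_m = elevation_range_m,
                 ridge_count = ridge_count,
                 noise_amplitude_m = noise_amplitude_m,
                 ndvi_profile = ndvi_profile,
                 ndvi_noise_sd = ndvi_noise_sd,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

## separable boxcar-of-gaussians smoothing of a matrix (reflecting edges)
.smooth_matrix <- function(M, sd_cells = 3) {
  half <- max(1L, ceiling(3 * sd_cells))
  k <- dnorm(seq(-half, half), sd = sd_cells)
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1):n]))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  M <- apply(M, 2, sm1)
  t(apply(M, 1, sm1))
}

#' Generate a synthetic DEM
#'
#' Sum of a planar north-to-south elevation ramp, `ridge_count` oriented
#' Gaussian ridge/valley functions, and smoothed random relief, affinely
#' rescaled to the configured elevation range. With `ridge_count = 0` and
#' `noise_amplitude_m = 0` the surface is the pure planar ramp (no
#' rescaling), giving analytic limits for the terrain operators.
#'
#' @param config a [landscape_config()].
#' @return elevation `grid_raster` with origin `(0, extent_y)`.
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  cs <- config$cell_size_m
  w <- config$extent_m[1]; h <- config$extent_m[2]
  nc <- as.integer(round(w / cs)); nr <- as.integer(round(h / cs))
  emin <- config$elevation_range_m[1]; emax <- config$elevation_range_m[2]
  x <- (seq_len(nc) - 0.5) * cs
  y <- h - (seq_len(nr) - 0.5) * cs        # row 1 = north
  X <- matrix(rep(x, each = nr), nr, nc)
  Y <- matrix(rep(y, times = nc), nr, nc)

  Z <- emin + (emax - emin) * Y / h        # ramp rising northward
  if (config$ridge_count == 0 && config$noise_amplitude_m == 0)
    return(grid_raster(Z, origin = c(0, h), cell_size = cs))

  set.seed(derive_seed(config$seed, "dem"))
  rng <- emax - emin
  for (k in seq_len(config$ridge_count)) {
    theta <- stats::runif(1, 0, pi)
    px <- stats::runif(1, 0.15 * w, 0.85 * w)
    py <- stats::runif(1, 0.15 * h, 0.85 * h)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 0.45) * rng
    width <- stats::runif(1, 0.06, 0.15) * min(w, h)
    dperp <- abs(-sin(theta) * (X - px) + cos(theta) * (Y - py))
    Z <- Z + amp * exp(-(dperp / width)^2)
  }
  if (config$noise_amplitude_m > 0) {
    N <- .smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sd_cells = 3)
    N <- N / max(abs(N))
    Z <- Z + config$noise_amplitude_m * N
  }
  Z <- emin + (emax - emin) * (Z - min(Z)) / (max(Z) - min(Z))
  grid_raster(Z, origin = c(0, h), cell_size = cs)
}

## evaluate the piecewise-linear NDVI profile at elevations
.ndvi_profile_at <- function(elev, profile) {
  kn <- profile$knots_m; nd <- profile$ndvi
  kn_f <- kn
  kn_f[1] <- min(elev, kn[2]) - 1
  kn_f[length(kn)] <- max(elev, kn[length(kn) - 1]) + 1
  stats::approx(kn_f, nd, xout = elev, rule = 2)$y
}

#' Generate NDVI correlated with elevation
#'
#' NDVI at each cell is the configured elevation profile value plus Gaussian
#' noise, clamped to `[-1, 1]`. The default profile puts closed forest below
#' about 4,000 m (NDVI about 0.65), grass/shrub between 4,000 and 4,800 m
#' (NDVI declining through 0.45-0.28) and barren rock/snow above (below
#' 0.14, slightly negative on permanent snow). With `ndvi_noise_sd = 0`
#' NDVI is a pure function of elevation.
#'
#' @param dem elevation `grid_raster`.
#' @param config the [landscape_config()] used for the DEM.
#' @return NDVI `grid_raster` in `[-1, 1]`.
#' @export
generate_ndvi <- function(dem, config) {
  base <- .ndvi_profile_at(as.vector(dem$values), config$ndvi_profile)
  if (config$ndvi_noise_sd > 0) {
    set.seed(derive_seed(config$seed, "ndvi"))
    base <- base + stats::rnorm(length(base), sd = config$ndvi_noise_sd)
  }
  vals <- matrix(pmin(1, pmax(-1, base)), nrow(dem$values), ncol(dem$values))
  vals[is.na(dem$values)] <- NA_real_
  grid_like(dem, vals)
}

#' Transect set
#'
#' @param lines list of two-column vertex matrices (x, y in metres).
#' @return a `transect_set` with per-transect polyline lengths.
#' @export
transect_set <- function(lines) {
  lines <- lapply(lines, function(v) {
    v <- as.matrix(v); colnames(v) <- c("x", "y"); v
  })
  lens <- vapply(lines, function(v) {
    if (nrow(v) < 2) return(0)
    sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
  }, numeric(1))
  structure(list(lines = lines, lengths_m = lens), class = "transect_set")
}

#' @export
print.transect_set <- function(x, ...) {
  cat(sprintf("transect_set: %d transects, total %.1f km (mean %.2f km)\n",
              length(x$lines), sum(x$lengths_m) / 1000,
              mean(x$lengths_m) / 1000))
  invisible(x)
}

#' Place survey transects along ridges and valleys
#'
#' Transects follow paths of locally extreme elevation (ridgelines or valley
#' bottoms, chosen at random per transect) by a greedy walk over the 8-cell
#' neighbourhood, constrained to an elevation band, emulating the practice
#' of walking routes with good visibility. Each transect targets
#' `target_length_m`; walks shorter than half the target are re-seeded.
#'
#' @param dem elevation `grid_raster`.
#' @param n_transects number of transects.
#' @param target_length_m target polyline length per transect (m).
#' @param constraints list with `elevation_range` (eligible band in m).
#' @param seed integer seed.
#' @return a `transect_set`.
#' @export
place_transects <- function(dem, n_transects, target_length_m,
                            constraints = list(elevation_range = c(3000, 5000)),
                            seed = 1L) {
  band <- constraints$elevation_range %||% c(3000, 5000)
  Z <- dem$values
  eligible <- !is.na(Z) & Z >= band[1] & Z <= band[2]
  if (!any(eligible))
    stopf("no cells within the elevation constraint [%g, %g] m",
          band[1], band[2])
  set.seed(derive_seed(seed, "transects"))
  n <- nrow(Z); m <- ncol(Z)
  cs <- dem$cell_size
  elig_idx <- which(eligible)
  lines <- vector("list", n_transects)
  for (t in seq_len(n_transects)) {
    best <- NULL
    for (try in 1:25) {
      ridge <- stats::runif(1) < 0.5
      cur <- elig_idx[sample.int(length(elig_idx), 1)]
      visited <- cur
      len <- 0
      path <- cur
      while (len < target_length_m) {
        r <- (cur - 1L) %% n + 1L; c <- (cur - 1L) %/% n + 1L
        rr <- r + .d8$dr; cc <- c + .d8$dc
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
        nb <- (cc[ok] - 1L) * n + rr[ok]
        nb <- nb[eligible[nb] & !(nb %in% visited)]
        if (!length(nb)) break
        z <- Z[nb]
        nxt <- nb[if (ridge) which.max(z) else which.min(z)]
        rn <- (nxt - 1L) %% n + 1L; cn <- (nxt - 1L) %/% n + 1L
        len <- len + cs * sqrt((rn - r)^2 + (cn - c)^2)
        path <- c(path, nxt)
        visited <- c(visited, nxt)
        if (length(visited) > 40) visited <- visited[-1]
        cur <- nxt
      }
      if (is.null(best) || len > attr(best, "len")) {
        best <- path; attr(best, "len") <- len
      }
      if (len >= 0.5 * target_length_m) break
    }
    r <- (best - 1L) %% n + 1L; c <- (best - 1L) %/% n + 1L
    lines[[t]] <- cbind(x = dem$origin[1] + (c - 0.5) * cs,
                        y = dem$origin[2] - (r - 0.5) * cs)
  }
  transect_set(lines)
}

#' Transect survey-effort summary
#'
#' @param x a `transect_set`, or a numeric vector of transect lengths in km.
#' @return data.frame with `n_transects`, `total_km`, and `mean_km`
#'   (mean transect length, one decimal, half up).
#' @export
transect_summary <- function(x) {
  lens_km <- if (inherits(x, "transect_set")) x$lengths_m / 1000 else x
  data.frame(n_transects = length(lens_km),
             total_km = sum(lens_km),
             mean_km = round_half_up(sum(lens_km) / length(lens_km), 1))
}

#' Population ground truth
#'
#' Defines the simulated population: overall density, the habitat-selection
#' function that places groups, the group-size distribution, and the sex/age
#' composition. Defaults emulate a Trans-Himalayan blue sheep population:
#' about 7 individuals/km2, mean group size 14.4 (zero-truncated negative
#' binomial, maximum 113), and a preference for mid-alpine elevations and
#' the grass/shrub NDVI band.
#'
#' @param true_density_ind_per_km2 realized density target (individuals/km2).
#' @param selection list with `elev_band`, `ndvi_band` (preferred bands) and
#'   `coef` (length-2 log-intensity coefficients for the elevation and NDVI
#'   preference terms; `c(0, 0)` gives spatially uniform placement).
#' @param group_size list with `mean`, `dispersion` (negative-binomial size)
#'   and `max`.
#' @param class_mix proportions of adult males, adult females and subadults
#'   (must sum to 1).
#' @param unclassified_frac fraction of individuals whose class is masked to
#'   "unclassified" after generation.
#' @return a `population_truth` list.
#' @export
population_truth <- function(true_density_ind_per_km2 = 7,
                             selection = list(elev_band = c(4250, 4550),
                                              ndvi_band = c(0.25, 0.5),
                                              coef = c(3, 1.5)),
                             group_size = list(mean = 14.4, dispersion = 0.92,
                                               max = 113),
                             class_mix = c(adult_male = 0.25,
                                           adult_female = 0.45,
                                           subadult = 0.30),
                             unclassified_frac = 0.15) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stopf("class proportions must sum to 1")
  if (group_size$mean < 1) stopf("mean group size must be >= 1")
  structure(list(true_density_ind_per_km2 = true_density_ind_per_km2,
                 selection = selection, group_size = group_size,
                 class_mix = class_mix,
                 unclassified_frac = unclassified_frac),
            class = "population_truth")
}

## smooth band preference: 1 at band centre, exp(-1) at the band edges
.band_bump <- function(x, band) {
  mid <- mean(band); half <- diff(band) / 2
  exp(-((x - mid) / half)^2)
}

## log selection intensity over stack cells
.log_intensity <- function(stack, selection) {
  el <- stack$elevation$values
  nd <- stack$ndvi$values
  selection$coef[1] * .band_bump(el, selection$elev_band) +
    selection$coef[2] * .band_bump(nd, selection$ndvi_band)
}

## zero-truncated, capped negative-binomial group sizes
.rgroupsize <- function(n, gs) {
  mu <- gs$mean; size <- gs$dispersion
  out <- integer(0)
  while (length(out) < n) {
    draw <- stats::rnbinom(2 * n + 10, mu = mu, size = size)
    draw <- draw[draw >= 1 & draw <= gs$max]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

#' Simulate an ungulate population on a landscape
#'
#' Groups are placed by an inhomogeneous point process whose intensity is
#' proportional to `exp` of the selection function evaluated on the
#' covariate stack; the number of groups is Poisson with expectation
#' `density x area / E[group size]`. Individuals are assigned sex/age
#' classes multinomially, then a fraction is relabelled unclassified
#' (`true_adults` keeps the pre-masking adult count).
#'
#' @param stack a `covariate_stack` with `elevation` and `ndvi` layers.
#' @param truth a [population_truth()].
#' @param seed integer seed.
#' @return data.frame (group table): `group_id`, `x`, `y`, `size`,
#'   `n_adult_male`, `n_adult_female`, `n_subadult`, `n_unclassified`,
#'   `true_adults`.
#' @export
simulate_population <- function(stack, truth, seed = 1L) {
  set.seed(derive_seed(seed, "population"))
  logint <- .log_intensity(stack, truth$selection)
  w <- exp(logint)
  w[is.na(w)] <- 0
  if (sum(w) == 0) stopf("selection intensity is zero everywhere")
  g <- stack$elevation
  d <- dim(g$values)
  cs <- g$cell_size
  area_km2 <- sum(!is.na(g$values)) * cs^2 / 1e6
  mean_size <- mean(.rgroupsize(5000, truth$group_size))
  n_groups <- stats::rpois(1, truth$true_density_ind_per_km2 * area_km2 /
                             mean_size)
  if (n_groups == 0)
    return(data.frame(group_id = integer(0), x = numeric(0), y = numeric(0),
                      size = integer(0), n_adult_male = integer(0),
                      n_adult_female = integer(0), n_subadult = integer(0),
                      n_unclassified = integer(0), true_adults = integer(0)))
  cells <- sample.int(length(w), n_groups, replace = TRUE,
                      prob = as.vector(w))
  r <- (cells - 1L) %% d[1] + 1L; c <- (cells - 1L) %/% d[1] + 1L
  x <- g$origin[1] + (c - 1) * cs + stats::runif(n_groups, 0, cs)
  y <- g$origin[2] - (r - 1) * cs - stats::runif(n_groups, 0, cs)
  size <- .rgroupsize(n_groups, truth$group_size)
  cls <- t(vapply(size, function(s)
    as.integer(stats::rmultinom(1, s, truth$class_mix)), integer(3)))
  uncl <- vapply(seq_len(n_groups), function(i)
    as.integer(stats::rbinom(3, cls[i, ], truth$unclassified_frac)),
    integer(3))
  uncl <- t(uncl)
  data.frame(group_id = seq_len(n_groups), x = x, y = y, size = size,
             n_adult_male = cls[, 1] - uncl[, 1],
             n_adult_female = cls[, 2] - uncl[, 2],
             n_subadult = cls[, 3] - uncl[, 3],
             n_unclassified = rowSums(uncl),
             true_adults = cls[, 1] + cls[, 2])
}

#' Detection model for transect counts
#'
#' @param rate_per_m exponential decline of detection probability with
#'   perpendicular distance to the transect (`p = exp(-rate x d)`); 0 means
#'   perfect detection out to the truncation distance.
#' @param max_distance_m truncation distance (m).
#' @param require_line_of_sight if `TRUE`, a group is only detectable when a
#'   sight line from the nearest transect vertex is unobstructed.
#' @return a `detection_model` list.
#' @export
detection_model <- function(rate_per_m = 0.0035, max_distance_m = 1500,
                            require_line_of_sight = FALSE) {
  if (rate_per_m < 0) stopf("rate must be >= 0")
  if (max_distance_m <= 0) stopf("max distance must be positive")
  structure(list(rate_per_m = rate_per_m, max_distance_m = max_distance_m,
                 require_line_of_sight = require_line_of_sight),
            class = "detection_model")
}

## perpendicular distance from points to the nearest transect segment
point_transect_distance <- function(x, y, transects) {
  best <- rep(Inf, length(x))
  for (v in transects$lines) {
    if (nrow(v) < 2) next
    for (i in seq_len(nrow(v) - 1)) {
      vx <- v[i + 1, 1] - v[i, 1]; vy <- v[i + 1, 2] - v[i, 2]
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) 0 else
        pmin(1, pmax(0, ((x - v[i, 1]) * vx + (y - v[i, 2]) * vy) / L2))
      best <- pmin(best, sqrt((x - (v[i, 1] + t * vx))^2 +
                              (y - (v[i, 2] + t * vy))^2))
    }
  }
  best
}

#' Simulate a transect survey of a group table
#'
#' Each group is detected with probability `exp(-rate x d)` for perpendicular
#' distance `d` to the nearest transect, truncated at the maximum sighting
#' distance, and (optionally) only when line-of-sight from the nearest
#' transect vertex holds. Detection is per group, as survey teams record
#' group sightings.
#'
#' @param groups group table from [simulate_population()].
#' @param transects a `transect_set`.
#' @param dem elevation `grid_raster` (used for line-of-sight).
#' @param det a [detection_model()].
#' @param season season label attached to the observations.
#' @param seed integer seed.
#' @param observer_height_m eye height above ground for line-of-sight.
#' @return observation table: `id`, `season`, `x`, `y`, `distance_m`,
#'   `group_size`, `n_adult_male`, `n_adult_female`, `n_subadult`,
#'   `n_unclassified`, `true_adults`, `on_transect`.
#' @export
simulate_survey <- function(groups, transects, dem, det,
                            season = "spring", seed = 1L,
                            observer_height_m = 1.7) {
  if (!length(transects$lines)) stopf("empty transect set")
  set.seed(derive_seed(seed, "survey"))
  if (!nrow(groups))
    return(data.frame(id = integer(0), season = character(0), x = numeric(0),
                      y = numeric(0), distance_m = numeric(0),
                      group_size = integer(0), n_adult_male = integer(0),
                      n_adult_female = integer(0), n_subadult = integer(0),
                      n_unclassified = integer(0), true_adults = integer(0),
                      on_transect = logical(0)))
  d <- point_transect_distance(groups$x, groups$y, transects)
  p <- exp(-det$rate_per_m * d) * (d <= det$max_distance_m)
  detected <- stats::runif(nrow(groups)) < p
  if (det$require_line_of_sight && any(detected)) {
    verts <- do.call(rbind, transects$lines)
    gi <- which(detected)
    for (i in gi) {
      dv <- sqrt((verts[, 1] - groups$x[i])^2 + (verts[, 2] - groups$y[i])^2)
      vstar <- verts[which.min(dv), ]
      fc <- cell_index(dem, vstar[1], vstar[2])
      tc <- cell_index(dem, groups$x[i], groups$y[i])
      if (is.na(fc$row) || is.na(tc$row) ||
          !line_of_sight(dem, c(fc$row, fc$col), c(tc$row, tc$col),
                         observer_height_m))
        detected[i] <- FALSE
    }
  }
  g <- groups[detected, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(id = integer(0), season = character(0), x = numeric(0),
                      y = numeric(0), distance_m = numeric(0),
                      group_size = integer(0), n_adult_male = integer(0),
                      n_adult_female = integer(0), n_subadult = integer(0),
                      n_unclassified = integer(0), true_adults = integer(0),
                      on_transect = logical(0)))
  data.frame(id = seq_len(nrow(g)), season = season, x = g$x, y = g$y,
             distance_m = d[detected], group_size = g$size,
             n_adult_male = g$n_adult_male, n_adult_female = g$n_adult_female,
             n_subadult = g$n_subadult, n_unclassified = g$n_unclassified,
             true_adults = g$true_adults, on_transect = TRUE,
             row.names = NULL)
}

#' Simulate a complete survey study with known truth
#'
#' Convenience wrapper generating one self-consistent study: landscape
#' (DEM + NDVI), anthropogenic features, covariate stack, ridge/valley
#' transects, a population placed by the configured selection function, and
#' the transect survey of it. The defaults define a 14.4 x 14.4 km
#' landscape at 90-m resolution surveyed by 60 transects of about 2.1 km —
#' an effort comparable, per unit area, to a real total-count survey — with
#' the default [population_truth()] and [detection_model()].
#'
#' @param seed integer master seed.
#' @param config a [landscape_config()]; default the study landscape above.
#' @param truth a [population_truth()].
#' @param det a [detection_model()].
#' @param n_transects,target_length_m survey effort.
#' @param n_settlements settlements for [place_features()].
#' @param season season label for the observations.
#' @return list with `config`, `dem`, `ndvi`, `features`, `stack`,
#'   `transects`, `groups`, `obs`.
#' @export
simulate_study <- function(seed = 1L,
                           config = landscape_config(
                             extent_m = c(14400, 14400), cell_size_m = 90,
                             ridge_count = 8, noise_amplitude_m = 150,
                             seed = seed),
                           truth = population_truth(),
                           det = detection_model(),
                           n_transects = 60, target_length_m = 2100,
                           n_settlements = 3, season = "spring") {
  dem <- generate_dem(config)
  ndvi <- generate_ndvi(dem, config)
  features <- place_features(dem, n_settlements = n_settlements, seed = seed)
  stack <- build_covariates(dem, ndvi, features)
  transects <- place_transects(dem, n_transects, target_length_m, seed = seed)
  groups <- simulate_population(stack, truth, seed = seed)
  obs <- simulate_survey(groups, transects, dem, det, season = season,
                         seed = seed)
  list(config = config, dem = dem, ndvi = ndvi, features = features,
       stack = stack, transects = transects, groups = groups, obs = obs)
}

#' Feature set (settlements, trails, livestock)
#'
#' @param settlements two-column matrix of settlement locations (m).
#' @param trails list of two-column polyline vertex matrices.
#' @param livestock two-column matrix of livestock locations (m).
#' @return a `feature_set`.
#' @export
feature_set <- function(settlements = NULL, trails = NULL, livestock = NULL) {
  as_pts <- function(p) {
    if (is.null(p) || !length(p)) return(matrix(numeric(0), 0, 2,
                                                dimnames = list(NULL, c("x", "y"))))
    p <- as.matrix(as.data.frame(p)[, 1:2]); colnames(p) <- c("x", "y"); p
  }
  structure(list(settlements = as_pts(settlements),
                 trails = lapply(trails %||% list(), as.matrix),
                 livestock = as_pts(livestock)),
            class = "feature_set")
}

#' Place anthropogenic features on a landscape
#'
#' Settlements are placed at valley bottoms (the lowest local elevation
#' minima), trails connect consecutive settlements by straight polylines,
#' and livestock points cluster uniformly within `livestock_radius_m` of
#' their settlement.
#'
#' @param dem elevation `grid_raster`.
#' @param n_settlements number of settlements (0 gives empty layers).
#' @param livestock_per_settlement livestock points per settlement.
#' @param livestock_radius_m clustering radius (0 puts livestock exactly at
#'   settlements).
#' @param seed integer seed.
#' @return a `feature_set`.
#' @export
place_features <- function(dem, n_settlements = 3,
                           livestock_per_settlement = 8,
                           livestock_radius_m = 800, seed = 1L) {
  if (n_settlements == 0) return(feature_set())
  set.seed(derive_seed(seed, "features"))
  Z <- dem$values
  n <- nrow(Z); m <- ncol(Z)
  ## local minima of the 3x3 neighbourhood, preferring the lowest
  isminloc <- matrix(FALSE, n, m)
  ctr <- .nb(Z, 0, 0)
  lower <- matrix(TRUE, n - 2, m - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    lower <- lower & (ctr <= .nb(Z, dr, dc))
  }
  isminloc[2:(n - 1), 2:(m - 1)] <- lower & !is.na(ctr)
  cand <- which(isminloc)
  if (!length(cand)) cand <- which(!is.na(Z))
  cand <- cand[order(Z[cand])]
  ## thin candidates so settlements do not share one valley floor
  pick <- integer(0)
  cs <- dem$cell_size
  for (i in cand) {
    r <- (i - 1L) %% n + 1L; c <- (i - 1L) %/% n + 1L
    if (length(pick)) {
      pr <- (pick - 1L) %% n + 1L; pc <- (pick - 1L) %/% n + 1L
      if (any(sqrt((pr - r)^2 + (pc - c)^2) * cs < 0.1 * min(dim(Z)) * cs))
        next
    }
    pick <- c(pick, i)
    if (length(pick) == n_settlements) break
  }
  r <- (pick - 1L) %% n + 1L; c <- (pick - 1L) %/% n + 1L
  setl <- cbind(x = dem$origin[1] + (c - 0.5) * cs,
                y = dem$origin[2] - (r - 0.5) * cs)
  trails <- list()
  if (nrow(setl) >= 2)
    for (i in seq_len(nrow(setl) - 1))
      trails[[i]] <- setl[i:(i + 1), , drop = FALSE]
  k <- livestock_per_settlement * nrow(setl)
  ang <- stats::runif(k, 0, 2 * pi)
  rad <- livestock_radius_m * sqrt(stats::runif(k))
  base <- setl[rep(seq_len(nrow(setl)), each = livestock_per_settlement), ,
               drop = FALSE]
  lvstk <- cbind(x = base[, 1] + rad * cos(ang),
                 y = base[, 2] + rad * sin(ang))
  feature_set(settlements = setl, trails = trails, livestock = lvstk)
}
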