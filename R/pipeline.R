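## Configuration, vector-format I/O and the end-to-end pipeline driver:
## covariates -> viewshed density -> habitat selection -> importance,
## plus the sensitivity-analysis harness.

#' Write / read transects as GeoJSON
#'
#' Planar coordinates in metres are stored as GeoJSON LineString features
#' (one per transect).
#'
#' @param transects a `transect_set`.
#' @param path output file.
#' @return `read_transects_geojson` returns a `transect_set`.
#' @export
write_transects_geojson <- function(transects, path) {
  feats <- lapply(seq_along(transects$lines), function(i) {
    list(type = "Feature",
         properties = list(id = i,
                           length_m = transects$lengths_m[i]),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(transects$lines[[i]], 1,
                                                    function(p) as.list(unname(p)),
                                                    simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transects_geojson
#' @export
read_transects_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lines <- lapply(j$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(x = p[[1]], y = p[[2]])))
  })
  transect_set(lines)
}

#' Write a feature set as GeoJSON
#'
#' Settlements and livestock become Point features (property `type`),
#' trails become LineStrings.
#'
#' @param features a `feature_set`.
#' @param path output file.
#' @export
write_features_geojson <- function(features, path) {
  feats <- list()
  pt_feats <- function(m, type) lapply(seq_len(nrow(m)), function(i)
    list(type = "Feature", properties = list(type = type),
         geometry = list(type = "Point",
                         coordinates = list(m[i, 1], m[i, 2]))))
  feats <- c(feats, pt_feats(features$settlements, "settlement"))
  feats <- c(feats, lapply(features$trails, function(v)
    list(type = "Feature", properties = list(type = "trail"),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(v, 1, function(p)
                           as.list(unname(p)), simplify = FALSE))))))
  feats <- c(feats, pt_feats(features$livestock, "livestock"))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## tagged CSV: first line records provenance, readable with comment.char "#"
.write_tagged_csv <- function(df, path, tag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", tag), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles inputs (in-memory objects or file paths), analysis parameters and
#' the seed for a full run. Inputs given as paths are loaded on run
#' (`.asc` grids, GeoJSON transects, CSV observations); referenced files
#' must exist.
#'
#' @param dem,ndvi elevation / NDVI `grid_raster`s or `.asc` paths.
#' @param transects a `transect_set` or GeoJSON path.
#' @param observations observation table (data.frame) or CSV path.
#' @param features optional `feature_set`.
#' @param landcover_points optional calibration points (`x`, `y`, `class`).
#' @param params named list of analysis parameters; defaults:
#'   `radii_m = c(1000, 1500)`, `livestock_buffer_m = 500`,
#'   `stream_threshold_km2 = 0.5`, `cliff_threshold_deg = 45`,
#'   `cliff_min_area_m2 = 90`, `n_candidates = 50000`, `multiplier = 100`,
#'   `alpha = 0.05`, `n_reps = 100`, `exclude_forest = TRUE`, `k = 10`.
#' @param seed integer master seed for every stochastic stage.
#' @param out_dir output directory (`NULL` for no file output).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dem, ndvi, transects, observations,
                            features = NULL, landcover_points = NULL,
                            params = list(), seed = 1L, out_dir = NULL) {
  defaults <- list(radii_m = c(1000, 1500), livestock_buffer_m = 500,
                   stream_threshold_km2 = 0.5, cliff_threshold_deg = 45,
                   cliff_min_area_m2 = 90, n_candidates = 50000,
                   multiplier = 100, alpha = 0.05, n_reps = 100,
                   exclude_forest = TRUE, k = 10)
  params <- utils::modifyList(defaults, params)
  if (any(params$radii_m <= 0)) stopf("buffer radii must be positive")
  for (nm in c("dem", "ndvi", "transects", "observations")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v))
      stopf("input file for '%s' does not exist: %s", nm, v)
  }
  structure(list(dem = dem, ndvi = ndvi, transects = transects,
                 observations = observations, features = features,
                 landcover_points = landcover_points, params = params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.load_input <- function(x, kind) {
  if (!is.character(x)) return(x)
  switch(kind,
         grid = read_ascii_grid(x),
         transects = read_transects_geojson(x),
         table = utils::read.csv(x, comment.char = "#"))
}

#' Run the full analysis pipeline
#'
#' Executes covariate derivation, transect viewsheds and minimum-density
#' estimation, pseudo-absence construction, the weighted binomial GAM and
#' permutation importance, in order. When `out_dir` is set, writes the
#' density table, a model-summary table (coefficient/SE/z/p for categorical
#' terms, edf/Ref.df/chi-square/p for smooths), the importance table, the
#' predicted-selection raster and a `report.yaml` carrying the seed and the
#' MD5 hash of the configuration; tabular artifacts carry the same tag as a
#' comment line.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `covariates`, `classmap`, `viewsheds`,
#'   `density`, `inclusion`, `rate`, `pseudo_absences`, `screen`, `frame`,
#'   `fit`, `importance`, `prediction`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dem <- .load_input(config$dem, "grid")
  ndvi <- .load_input(config$ndvi, "grid")
  transects <- .load_input(config$transects, "transects")
  obs <- .load_input(config$observations, "table")

  stack <- build_covariates(dem, ndvi, features = config$features,
                            livestock_buffer_m = p$livestock_buffer_m,
                            stream_threshold_km2 = p$stream_threshold_km2,
                            cliff_threshold_deg = p$cliff_threshold_deg,
                            cliff_min_area_m2 = p$cliff_min_area_m2)

  classmap <- NULL
  if (!is.null(config$landcover_points)) {
    lp <- config$landcover_points
    lp$ndvi <- extract_values(ndvi, lp$x, lp$y)
    ranges <- calibrate_ndvi_classes(lp[!is.na(lp$ndvi), ])
    classmap <- classify_ndvi(ndvi, ranges)
  }

  viewsheds <- lapply(p$radii_m, function(r)
    transect_viewshed(dem, transects, radius_m = r))
  names(viewsheds) <- as.character(p$radii_m)
  dens <- minimum_density(obs, viewsheds,
                          season = obs$season[1] %||% NA_character_)
  incl <- vapply(p$radii_m, function(r)
    buffer_inclusion_fraction(obs, r), numeric(1))

  rate <- fit_exponential_rate(obs$distance_m,
                               season = obs$season[1] %||% NA_character_)
  pa <- generate_pseudo_absences(viewsheds[[as.character(max(p$radii_m))]],
                                 transects, n_obs = nrow(obs), rate = rate,
                                 n_candidates = p$n_candidates,
                                 multiplier = p$multiplier,
                                 seed = config$seed)
  pa <- attribute_group_sizes(pa, obs, alpha = p$alpha, seed = config$seed)

  model_covs <- intersect(
    c("elevation", "slope_deg", "tri_m", "south_deviation_deg", "ndvi",
      "dist_cliff_m", "dist_stream_m", "dist_settlement_m", "dist_trail_m",
      "livestock_presence"), names(stack))
  ## degenerate layers cannot enter the model: all-infinite distance
  ## surfaces (no feature anywhere) or constant covariates
  degenerate <- Filter(function(nm) {
    v <- stack[[nm]]$values
    fin <- v[is.finite(v)]
    length(fin) == 0 || any(is.infinite(v), na.rm = TRUE) ||
      length(unique(fin)) < 2
  }, model_covs)
  model_covs <- setdiff(model_covs, degenerate)
  frame <- build_model_frame(obs, pa, stack, classmap = classmap,
                             exclude_forest = p$exclude_forest,
                             covariates = model_covs)
  retain_priority <- c("elevation", "slope_deg", "ndvi",
                       "south_deviation_deg", "dist_settlement_m",
                       "dist_stream_m", "dist_trail_m", "dist_cliff_m",
                       "livestock_presence", "tri_m")
  screen <- screen_collinearity(frame[model_covs], threshold = 0.7,
                                retain_priority = retain_priority)
  frame2 <- frame[c("response", "weight", screen$retained)]
  for (a in c("n_presence", "n_pseudo_absence", "n_dropped_forest",
              "n_dropped_na"))
    attr(frame2, a) <- attr(frame, a)
  fit <- fit_habitat_gam(frame2, k = p$k)
  imp <- permutation_importance(fit, frame2, n_reps = p$n_reps,
                                seed = config$seed)
  predmap <- predict_selection(fit, stack)

  report <- list(seed = config$seed, params = p,
                 n_observations = nrow(obs),
                 n_presence = attr(frame2, "n_presence"),
                 n_pseudo_absence = attr(frame2, "n_pseudo_absence"),
                 n_dropped_forest = attr(frame2, "n_dropped_forest"),
                 dropped_collinear = as.list(screen$dropped),
                 dropped_degenerate = degenerate,
                 rate_per_m = rate$rate_per_m,
                 deviance_explained = fit$deviance_explained,
                 adj_r2 = fit$adj_r2,
                 r_version = as.character(getRversion()))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cfgfile <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(list(params = p, seed = config$seed), cfgfile)
    hash <- unname(tools::md5sum(cfgfile))
    report$config_md5 <- hash
    tag <- sprintf("config_md5=%s seed=%d", hash, config$seed)
    .write_tagged_csv(dens, file.path(config$out_dir, "density.csv"), tag)
    model_tab <- rbind(
      data.frame(kind = "categorical", term = fit$parametric_terms$term,
                 coefficient = fit$parametric_terms$coefficient,
                 se = fit$parametric_terms$se, z = fit$parametric_terms$z,
                 edf = NA, ref_df = NA, chi_sq = NA,
                 p = fit$parametric_terms$p),
      data.frame(kind = "smooth", term = fit$smooth_terms$term,
                 coefficient = NA, se = NA, z = NA,
                 edf = fit$smooth_terms$edf, ref_df = fit$smooth_terms$ref_df,
                 chi_sq = fit$smooth_terms$chi_sq, p = fit$smooth_terms$p))
    .write_tagged_csv(model_tab,
                      file.path(config$out_dir, "model_summary.csv"), tag)
    .write_tagged_csv(as.data.frame(imp),
                      file.path(config$out_dir, "importance.csv"), tag)
    write_ascii_grid(predmap, file.path(config$out_dir, "prediction.asc"))
    for (nm in names(viewsheds))
      write_ascii_grid(viewsheds[[nm]]$visible,
                       file.path(config$out_dir,
                                 sprintf("viewshed_%s.asc", nm)))
    yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  }

  invisible(list(covariates = stack, classmap = classmap,
                 viewsheds = viewsheds, density = dens,
                 inclusion = stats::setNames(incl, names(viewsheds)),
                 rate = rate, pseudo_absences = pa, screen = screen,
                 frame = frame2, fit = fit, importance = imp,
                 prediction = predmap, report = report))
}

#' Sensitivity analysis over configuration variants
#'
#' Re-runs the pipeline under named parameter variants (e.g. other livestock
#' buffer widths, forest inclusion, alternative pseudo-absence seeds) and
#' tabulates, per variant, the change in standardized importances and in
#' the elevation/NDVI smooth peaks relative to the base run.
#'
#' @param config a [pipeline_config()] (the base run).
#' @param variants named list; each element is a list of `params` overrides
#'   and/or a `seed` override.
#' @return list with `base` (the base bundle) and `comparison` data.frame
#'   (variant, variable, standardized importance base/variant/delta), plus
#'   `peaks` (smooth-peak shifts).
#' @export
run_sensitivity <- function(config, variants) {
  base <- run_pipeline(config)
  comp <- list(); peaks <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    cfg <- config
    if (!is.null(v$params))
      cfg$params <- utils::modifyList(cfg$params, v$params)
    if (!is.null(v$seed)) cfg$seed <- as.integer(v$seed)
    if (!is.null(cfg$out_dir))
      cfg$out_dir <- file.path(config$out_dir, nm)
    res <- run_pipeline(cfg)
    m <- merge(as.data.frame(base$importance)[c("variable", "standardized")],
               as.data.frame(res$importance)[c("variable", "standardized")],
               by = "variable", suffixes = c("_base", "_variant"), all = TRUE)
    m$delta <- m$standardized_variant - m$standardized_base
    m$variant <- nm
    comp[[nm]] <- m
    shared <- intersect(base$fit$smooth_vars, res$fit$smooth_vars)
    peaks[[nm]] <- data.frame(
      variant = nm, variable = shared,
      peak_base = vapply(shared, function(s) smooth_peak(base$fit, s),
                         numeric(1)),
      peak_variant = vapply(shared, function(s) smooth_peak(res$fit, s),
                            numeric(1)))
  }
  list(base = base, comparison = do.call(rbind, c(comp, make.row.names = FALSE)),
       peaks = do.call(rbind, c(peaks, make.row.names = FALSE)))
}
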