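## Used-available habitat-selection design: distance-weighted pseudo-absence
## sampling inside the surveyed viewshed, group-size attribution, adult
## weighting, a collinearity screen, and weighted binomial GAMs (mgcv).

#' Exponential detection-distance rate by maximum likelihood
#'
#' The MLE of the exponential rate is the reciprocal mean of the observed
#' perpendicular distances; it parameterises the availability weighting of
#' pseudo-absence points.
#'
#' @param distances_m observed distances to the transect (m), at least two.
#' @param season optional season label.
#' @return an `exponential_rate`: list with `rate_per_m`, `n`, `season`.
#' @export
fit_exponential_rate <- function(distances_m, season = NA_character_) {
  distances_m <- distances_m[!is.na(distances_m)]
  if (length(distances_m) < 2) stopf("need at least two distances")
  if (all(distances_m == 0)) stopf("all distances are zero")
  if (any(distances_m < 0)) stopf("distances must be >= 0")
  structure(list(rate_per_m = 1 / mean(distances_m),
                 n = length(distances_m), season = season),
            class = "exponential_rate")
}

#' Sample pseudo-absence points in the surveyed viewshed
#'
#' Scatters `n_candidates` uniform random points over the visible cells of
#' the 1,500-m viewshed, then draws `multiplier x n_obs` of them *without
#' replacement* with probability proportional to the exponential density
#' `exp(-rate x distance-to-transect)`, so available points mirror the
#' distance distribution of the sightings.
#'
#' @param vs1500 a `viewshed_result` (the availability region).
#' @param transects a `transect_set` (distances are measured to it).
#' @param n_obs number of presence observations.
#' @param rate an `exponential_rate` (or a bare rate per metre; 0 gives
#'   uniform sampling over the viewshed).
#' @param n_candidates number of uniform candidate points (default 50,000).
#' @param multiplier pseudo-absences per observation (default 100).
#' @param seed integer seed.
#' @return data.frame (`pseudo_absence_table`): `x`, `y`, `distance_m`.
#' @export
generate_pseudo_absences <- function(vs1500, transects, n_obs, rate,
                                     n_candidates = 50000, multiplier = 100,
                                     seed = 1L) {
  g <- vs1500$visible
  vis <- which(!is.na(g$values) & g$values == 1)
  if (!length(vis)) stopf("viewshed is empty")
  n_sample <- multiplier * n_obs
  if (n_sample > n_candidates)
    stopf("requested %d points from only %d candidates", n_sample,
          n_candidates)
  lambda <- if (inherits(rate, "exponential_rate")) rate$rate_per_m else rate
  set.seed(derive_seed(seed, "pseudoabsence"))
  d <- dim(g$values)
  cs <- g$cell_size
  cells <- vis[sample.int(length(vis), n_candidates, replace = TRUE)]
  r <- (cells - 1L) %% d[1] + 1L; c <- (cells - 1L) %/% d[1] + 1L
  x <- g$origin[1] + (c - 1) * cs + stats::runif(n_candidates, 0, cs)
  y <- g$origin[2] - (r - 1) * cs - stats::runif(n_candidates, 0, cs)
  dist <- point_transect_distance(x, y, transects)
  w <- exp(-lambda * dist)
  keep <- sample.int(n_candidates, n_sample, replace = FALSE, prob = w)
  out <- data.frame(x = x[keep], y = y[keep], distance_m = dist[keep])
  class(out) <- c("pseudo_absence_table", "data.frame")
  out
}

#' Correlation between group size and distance to transect
#'
#' Pearson correlation with its two-sided t-test, deciding whether group
#' sizes can be attributed to pseudo-absences by random permutation or must
#' be modelled against distance.
#'
#' @param obs observation table with `group_size` and `distance_m`.
#' @return list with `r`, `p`, `n`.
#' @export
test_groupsize_distance <- function(obs) {
  if (nrow(obs) < 3) stopf("need at least three observations")
  if (stats::sd(obs$group_size) == 0 || stats::sd(obs$distance_m) == 0)
    stopf("zero variance in group size or distance")
  ct <- stats::cor.test(obs$group_size, obs$distance_m, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(obs))
}

#' Attribute group sizes to pseudo-absence points
#'
#' If group size and distance to transect are uncorrelated (two-sided
#' p >= `alpha`), observed group sizes are attributed at random (sampled
#' with replacement); otherwise attributed sizes come from an ordinary
#' least-squares fit of group size on distance, rounded to the nearest
#' integer (halves up) and floored at 1. An attributed adult count
#' (size x the dataset-level adult fraction) is added for weighting.
#'
#' @param pa `pseudo_absence_table` from [generate_pseudo_absences()].
#' @param obs observation table.
#' @param alpha significance level for the strategy switch.
#' @param seed integer seed for the permutation strategy.
#' @return `pa` with columns `attributed_group_size` and
#'   `attributed_adult_count`; attribute `"groupsize_model"` records the
#'   strategy (`permute` or `linear`), `intercept`, `slope`, `r`, `p`.
#' @export
attribute_group_sizes <- function(pa, obs, alpha = 0.05, seed = 1L) {
  if (!nrow(obs)) stopf("empty observation table")
  ts <- test_groupsize_distance(obs)
  if (ts$p < alpha) {
    fit <- stats::lm(group_size ~ distance_m, data = obs)
    co <- stats::coef(fit)
    sz <- pmax(1, round_half_up(co[1] + co[2] * pa$distance_m, 0))
    model <- list(strategy = "linear", intercept = unname(co[1]),
                  slope = unname(co[2]), r = ts$r, p = ts$p)
  } else {
    set.seed(derive_seed(seed, "groupsize"))
    sz <- sample(obs$group_size, nrow(pa), replace = TRUE)
    model <- list(strategy = "permute", intercept = NA_real_,
                  slope = NA_real_, r = ts$r, p = ts$p)
  }
  class_cols <- c("n_adult_male", "n_adult_female", "n_subadult",
                  "n_unclassified")
  adult_frac <- if (all(class_cols %in% names(obs)))
    sum(adult_counts(obs)) / sum(obs$group_size) else 1
  pa$attributed_group_size <- as.numeric(sz)
  pa$attributed_adult_count <- pa$attributed_group_size * adult_frac
  attr(pa, "groupsize_model") <- model
  pa
}

#' Adult counts with imputation of unclassified individuals
#'
#' The per-observation number of adults is the count of identified adults
#' plus the unclassified count times the dataset-level ratio of adults among
#' all classified individuals:
#' `adults_i = (males_i + females_i) + unclassified_i x R` with
#' `R = sum(males + females) / sum(males + females + subadults)`.
#'
#' @param obs observation table with `n_adult_male`, `n_adult_female`,
#'   `n_subadult`, `n_unclassified`.
#' @return numeric vector of adult counts per row.
#' @export
adult_counts <- function(obs) {
  classified <- obs$n_adult_male + obs$n_adult_female + obs$n_subadult
  if (sum(classified) == 0)
    stopf("no classified individuals in the dataset")
  R <- sum(obs$n_adult_male + obs$n_adult_female) / sum(classified)
  obs$n_adult_male + obs$n_adult_female + obs$n_unclassified * R
}

#' Observation and pseudo-absence weights
#'
#' Each presence row gets weight `adults_i / sum(adults) x n_obs`, so the
#' presence weights sum to the number of observations (the weighting adjusts
#' for group size without inflating the sample size). Pseudo-absence weights
#' are proportional to their attributed adult counts and rescaled so their
#' total equals the presence total.
#'
#' @param presence_adults adult counts per presence row (see
#'   [adult_counts()]).
#' @param pa_adults attributed adult counts per pseudo-absence row.
#' @return list with `presence` and `pseudo_absence` weight vectors.
#' @export
compute_weights <- function(presence_adults, pa_adults) {
  if (sum(presence_adults) <= 0) stopf("total adult count must be positive")
  n_obs <- length(presence_adults)
  wp <- presence_adults / sum(presence_adults) * n_obs
  wa <- pa_adults / sum(pa_adults) * n_obs
  list(presence = wp, pseudo_absence = wa)
}

#' Collinearity screen on a covariate table
#'
#' Walks the variables in retention-priority order and keeps each one only
#' if its absolute Pearson correlation with every already-kept variable is
#' below `threshold` (pairs at exactly the threshold are screened out).
#' The result depends only on the correlation matrix and the priority
#' order, not on row order.
#'
#' @param frame data.frame of numeric covariates.
#' @param threshold absolute correlation at or above which a pair offends.
#' @param retain_priority character vector; earlier names win their pair.
#'   Variables not listed rank after listed ones, in column order.
#' @return list with `retained`, `dropped` (named by the variable each lost
#'   to) and the full `correlations` matrix.
#' @export
screen_collinearity <- function(frame, threshold = 0.7,
                                retain_priority = names(frame)) {
  vars <- names(frame)
  if (length(vars) < 2) stopf("need at least two variables")
  ord <- c(intersect(retain_priority, vars),
           setdiff(vars, retain_priority))
  cm <- stats::cor(frame, use = "pairwise.complete.obs")
  kept <- character(0)
  dropped <- character(0)
  for (v in ord) {
    conflict <- kept[!is.na(cm[v, kept]) & abs(cm[v, kept]) >= threshold]
    if (length(conflict)) {
      dropped[v] <- conflict[1]
    } else kept <- c(kept, v)
  }
  list(retained = kept, dropped = dropped, correlations = cm)
}

#' Assemble the used-available model frame
#'
#' Binds presence (response 1) and pseudo-absence rows (response 0),
#' extracts the covariate stack at every point, optionally drops presence
#' rows in forest (detection there is unreliable), removes rows with
#' incomplete covariates (kernel-border cells), and computes the adult
#' weights so that presence and pseudo-absence totals both equal the number
#' of retained observations.
#'
#' @param obs observation table (presences).
#' @param pa attributed `pseudo_absence_table` (see
#'   [attribute_group_sizes()]).
#' @param stack a `covariate_stack`.
#' @param classmap optional classified land-cover `grid_raster` (from
#'   [classify_ndvi()]) used to identify forest.
#' @param exclude_forest drop presence rows classified as forest?
#' @param covariates character vector of stack layers to use; default all.
#' @return data.frame with `response`, `weight` and covariate columns;
#'   attributes `n_presence`, `n_pseudo_absence`, `n_dropped_forest`,
#'   `n_dropped_na`.
#' @export
build_model_frame <- function(obs, pa, stack, classmap = NULL,
                              exclude_forest = TRUE, covariates = NULL) {
  covariates <- covariates %||% names(stack)
  ext <- grid_extent(stack[[1]])
  allx <- c(obs$x, pa$x); ally <- c(obs$y, pa$y)
  if (any(allx < ext["xmin"] | allx >= ext["xmax"] |
          ally <= ext["ymin"] | ally > ext["ymax"]))
    stopf("points outside the raster extent")
  n_forest <- 0L
  if (exclude_forest && !is.null(classmap)) {
    lc <- landcover_at(classmap, obs$x, obs$y)
    n_forest <- sum(lc == "forest", na.rm = TRUE)
    obs <- obs[is.na(lc) | lc != "forest", , drop = FALSE]
  } else if (exclude_forest && !is.null(obs$landcover)) {
    n_forest <- sum(obs$landcover == "forest", na.rm = TRUE)
    obs <- obs[is.na(obs$landcover) | obs$landcover != "forest", ,
               drop = FALSE]
  }
  if (!nrow(obs)) stopf("no presence rows left after forest exclusion")
  Xp <- extract_covariates(stack, obs$x, obs$y)[covariates]
  Xa <- extract_covariates(stack, pa$x, pa$y)[covariates]
  okp <- stats::complete.cases(Xp)
  oka <- stats::complete.cases(Xa)
  n_na <- sum(!okp) + sum(!oka)
  obs <- obs[okp, , drop = FALSE]; Xp <- Xp[okp, , drop = FALSE]
  pa <- pa[oka, , drop = FALSE]; Xa <- Xa[oka, , drop = FALSE]
  if (!nrow(obs)) stopf("no presence rows with complete covariates")
  ad <- adult_counts(obs)
  pa_ad <- pa$attributed_adult_count %||% rep(1, nrow(pa))
  w <- compute_weights(ad, pa_ad)
  frame <- rbind(
    cbind(data.frame(response = 1, weight = w$presence), Xp),
    cbind(data.frame(response = 0, weight = w$pseudo_absence), Xa))
  rownames(frame) <- NULL
  attr(frame, "n_presence") <- nrow(Xp)
  attr(frame, "n_pseudo_absence") <- nrow(Xa)
  attr(frame, "n_dropped_forest") <- n_forest
  attr(frame, "n_dropped_na") <- n_na
  frame
}

#' Fit the weighted binomial habitat-selection GAM
#'
#' One penalized thin-plate smooth per continuous covariate and a linear
#' term for each binary covariate, binomial family with logit link,
#' observation weights from the adult weighting, smoothness selected by
#' REML (configurable). Built on mgcv.
#'
#' @param frame model frame from [build_model_frame()].
#' @param k basis dimension per smooth term.
#' @param method smoothness-selection method passed to [mgcv::gam()].
#' @param linear_vars covariates forced into linear terms; by default any
#'   covariate with at most two distinct values (e.g. livestock presence).
#' @return a `habitat_gam`: list with the mgcv fit (`gam`), `smooth_terms`
#'   (edf, ref_df, chi_sq, p per smooth), `parametric_terms` (coefficient,
#'   se, z, p), `deviance_explained`, `adj_r2`, `n`, `n_presence`,
#'   `converged`.
#' @export
fit_habitat_gam <- function(frame, k = 10, method = "REML",
                            linear_vars = NULL) {
  covs <- setdiff(names(frame), c("response", "weight"))
  if (!length(covs)) stopf("no covariates in frame")
  if (is.null(linear_vars))
    linear_vars <- covs[vapply(frame[covs], function(v)
      length(unique(v[!is.na(v)])) <= 2, logical(1))]
  smooth_vars <- setdiff(covs, linear_vars)
  kuse <- vapply(smooth_vars, function(v)
    min(k, length(unique(frame[[v]])) - 1), numeric(1))
  if (any(kuse < 3)) stopf("covariate(s) too coarse for a smooth term: %s",
                           paste(smooth_vars[kuse < 3], collapse = ", "))
  terms <- c(sprintf("s(%s, k = %d)", smooth_vars, kuse), linear_vars)
  form <- stats::as.formula(paste("response ~", paste(terms, collapse = " + ")))
  ## mgcv warns about non-integer binomial successes under adult weighting;
  ## that is the design, not a defect
  fit <- withCallingHandlers(
    mgcv::gam(form, family = stats::binomial(), weights = frame$weight,
              data = frame, method = method, select = FALSE),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) warning("GAM fit did not converge")
  sm <- summary(fit)
  st <- as.data.frame(sm$s.table)
  names(st) <- c("edf", "ref_df", "chi_sq", "p")
  st$term <- rownames(sm$s.table); rownames(st) <- NULL
  pt <- as.data.frame(sm$p.table)
  names(pt) <- c("coefficient", "se", "z", "p")
  pt$term <- rownames(sm$p.table); rownames(pt) <- NULL
  structure(list(gam = fit,
                 smooth_terms = st[c("term", "edf", "ref_df", "chi_sq", "p")],
                 parametric_terms = pt[c("term", "coefficient", "se", "z",
                                         "p")],
                 deviance_explained = unname(sm$dev.expl),
                 adj_r2 = unname(sm$r.sq),
                 n = nrow(frame),
                 n_presence = attr(frame, "n_presence") %||%
                   sum(frame$response == 1),
                 smooth_vars = smooth_vars, linear_vars = linear_vars,
                 converged = fit$converged),
            class = "habitat_gam")
}

#' @export
print.habitat_gam <- function(x, ...) {
  cat(sprintf("habitat_gam: n = %d (%d presences), deviance explained %.1f%%, adj. R2 = %.3f\n",
              x$n, x$n_presence, 100 * x$deviance_explained, x$adj_r2))
  print(x$smooth_terms, digits = 3)
  if (nrow(x$parametric_terms)) print(x$parametric_terms, digits = 3)
  invisible(x)
}

#' Partial effect of one smooth term
#'
#' Evaluates the centred smooth `s(var)` over a grid of covariate values
#' (other covariates held at their frame medians, linear terms at 0), on
#' the link scale.
#'
#' @param fit a `habitat_gam`.
#' @param var covariate name.
#' @param n grid resolution.
#' @param range optional covariate range (default observed range).
#' @return data.frame with `x` and `partial`.
#' @export
smooth_partial <- function(fit, var, n = 200, range = NULL) {
  if (!var %in% fit$smooth_vars) stopf("'%s' has no smooth term", var)
  mf <- fit$gam$model
  rng <- range %||% range(mf[[var]])
  nd <- as.data.frame(lapply(mf[setdiff(names(mf), c("response", "(weights)"))],
                             function(col) rep(stats::median(col), n)))
  nd[[var]] <- seq(rng[1], rng[2], length.out = n)
  pr <- stats::predict(fit$gam, newdata = nd, type = "terms")
  col <- grep(sprintf("s\\(%s\\)", var), colnames(pr))
  data.frame(x = nd[[var]], partial = pr[, col])
}

#' Location of a smooth term's maximum
#'
#' @inheritParams smooth_partial
#' @return covariate value at which the fitted partial effect peaks.
#' @export
smooth_peak <- function(fit, var, n = 400, range = NULL) {
  sp <- smooth_partial(fit, var, n = n, range = range)
  sp$x[which.max(sp$partial)]
}

#' Predict relative selection over a covariate stack
#'
#' @param fit a `habitat_gam`.
#' @param stack `covariate_stack` containing every model covariate.
#' @return `grid_raster` of predicted selection on the probability scale;
#'   cells with missing covariates are `NA`.
#' @export
predict_selection <- function(fit, stack) {
  need <- c(fit$smooth_vars, fit$linear_vars)
  miss <- setdiff(need, names(stack))
  if (length(miss))
    stopf("stack lacks covariate layer(s): %s", paste(miss, collapse = ", "))
  d <- dim(stack[[1]]$values)
  nd <- as.data.frame(lapply(stack[need], function(g) as.vector(g$values)))
  ok <- stats::complete.cases(nd)
  out <- rep(NA_real_, nrow(nd))
  if (any(ok))
    out[ok] <- as.numeric(stats::predict(fit$gam, newdata = nd[ok, , drop = FALSE],
                                         type = "response"))
  grid_like(stack[[1]], matrix(out, d[1], d[2]))
}
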