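## NDVI-based land-cover calibration and classification. In the absence of a
## fine-scale land-cover map, NDVI ranges are calibrated per class against
## ground-truthed points and used to classify the NDVI raster.

.landcover_classes <- c("grassland", "shrubland", "agricultural", "forest",
                        "settlement", "barren", "water", "snow")

#' Calibrate per-class NDVI ranges from labelled points
#'
#' Assigns each land-cover class the NDVI interval between two configurable
#' quantiles of its calibration points (default the central 90 %), and
#' reports pairwise overlaps between class ranges.
#'
#' @param points data.frame with columns `class` (from the fixed class
#'   vocabulary) and `ndvi` (in `[-1, 1]`); location columns are ignored
#'   here.
#' @param quantiles lower/upper quantile defining each range; `c(0, 1)`
#'   gives min/max.
#' @param min_points minimum calibration points required per class.
#' @return a `class_ranges` object: data.frame with `class`, `ndvi_low`,
#'   `ndvi_high`, `n`; attribute `"overlaps"` lists overlapping class pairs.
#' @export
calibrate_ndvi_classes <- function(points, quantiles = c(0.05, 0.95),
                                   min_points = 3) {
  bad <- setdiff(unique(points$class), .landcover_classes)
  if (length(bad))
    stopf("unknown land-cover class(es): %s", paste(bad, collapse = ", "))
  if (any(points$ndvi < -1 | points$ndvi > 1, na.rm = TRUE))
    stopf("NDVI must lie in [-1, 1]")
  cl <- split(points$ndvi, points$class)
  small <- names(cl)[vapply(cl, length, integer(1)) < min_points]
  if (length(small))
    stopf("class(es) with fewer than %d points: %s", min_points,
          paste(small, collapse = ", "))
  out <- data.frame(
    class = names(cl),
    ndvi_low = vapply(cl, function(v)
      unname(stats::quantile(v, quantiles[1], type = 7)), numeric(1)),
    ndvi_high = vapply(cl, function(v)
      unname(stats::quantile(v, quantiles[2], type = 7)), numeric(1)),
    n = vapply(cl, length, integer(1)),
    row.names = NULL)
  ov <- list()
  if (nrow(out) > 1)
    for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out))
      if (out$ndvi_low[j] <= out$ndvi_high[i] &&
          out$ndvi_low[i] <= out$ndvi_high[j])
        ov[[length(ov) + 1]] <- c(out$class[i], out$class[j])
  attr(out, "overlaps") <- ov
  class(out) <- c("class_ranges", "data.frame")
  out
}

#' Wilcoxon rank-sum test with midranks
#'
#' Rank-sum statistic (sum of midranks of `x` in the pooled sample) with an
#' exact p-value by complete enumeration of group assignments when the
#' combined sample size is at most 20 (valid under ties), and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @param exact_max combined sample size up to which the exact enumeration
#'   is used.
#' @return list with `W` (rank-sum of `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_max = 20) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))                     # midranks
  W <- sum(r[seq_len(nx)])
  if (N <= exact_max) {
    combs <- utils::combn(N, nx)
    Wall <- colSums(matrix(r[combs], nrow = nx))
    tol <- 1e-9
    p <- switch(alternative,
      less = mean(Wall <= W + tol),
      greater = mean(Wall >= W - tol),
      two.sided = min(1, 2 * min(mean(Wall <= W + tol),
                                 mean(Wall >= W - tol))))
    return(list(W = W, p = p, method = "exact enumeration"))
  }
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  if (sigma == 0)                        # all observations tied
    return(list(W = W, p = 1, method = "normal approximation"))
  z <- W - mu
  p <- switch(alternative,
    less = stats::pnorm((z + 0.5) / sigma),
    greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
    two.sided = {
      zc <- (abs(z) - 0.5) / sigma
      min(1, 2 * stats::pnorm(max(zc, 0), lower.tail = FALSE))
    })
  list(W = W, p = p, method = "normal approximation")
}

#' Classify an NDVI raster by calibrated class ranges
#'
#' Each cell gets the first class, in `priority` order, whose inclusive
#' NDVI range contains the cell value; cells matching no range are
#' `"unclassified"`. An explicit priority order resolves the overlapping
#' ranges typical of NDVI-only calibration.
#'
#' @param ndvi NDVI `grid_raster`.
#' @param ranges a `class_ranges` from [calibrate_ndvi_classes()].
#' @param priority character vector of class names, highest priority first;
#'   defaults to the row order of `ranges`.
#' @return `grid_raster` of integer class codes with a `legend` attribute
#'   (named vector mapping code to class; 0 = unclassified).
#' @export
classify_ndvi <- function(ndvi, ranges, priority = NULL) {
  priority <- priority %||% ranges$class
  if (!all(priority %in% ranges$class))
    stopf("priority lists unknown classes")
  v <- ndvi$values
  out <- matrix(0, nrow(v), ncol(v))
  codes <- stats::setNames(seq_along(priority), priority)
  for (cl in rev(priority)) {            # higher priority overwrites later
    i <- match(cl, ranges$class)
    hit <- !is.na(v) & v >= ranges$ndvi_low[i] & v <= ranges$ndvi_high[i]
    out[hit] <- codes[[cl]]
  }
  out[is.na(v)] <- NA_real_
  g <- grid_like(ndvi, out)
  attr(g, "legend") <- c(unclassified = 0, codes)
  g
}

#' Look up class labels at point locations on a classified map
#'
#' @param classmap classified `grid_raster` from [classify_ndvi()].
#' @param x,y point coordinates (m).
#' @return character vector of class labels (`NA` outside the map).
#' @export
landcover_at <- function(classmap, x, y) {
  leg <- attr(classmap, "legend")
  code <- extract_values(classmap, x, y)
  names(leg)[match(code, leg)]
}
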