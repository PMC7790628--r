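## Line-of-sight viewsheds and minimum-density estimation from total counts.
## Sight lines are rasterised with Bresenham's algorithm; a target is visible
## when no intermediate cell rises above the straight line from the observer
## eye to the target's ground elevation. Slope comparison (rise over
## horizontal run from the observer) is equivalent and avoids trigonometry.

#' Line of sight between two cells
#'
#' @param dem elevation `grid_raster`.
#' @param from_cell,to_cell integer `c(row, col)` cell indices.
#' @param observer_height_m eye height above the ground at `from_cell` (m);
#'   the target is taken at ground level.
#' @return `TRUE` iff no intermediate cell along the rasterised sight line
#'   rises strictly above the straight sight line. Adjacent or identical
#'   cells are always visible; a `NA` endpoint or blocking `NA` cell gives
#'   `FALSE`.
#' @export
line_of_sight <- function(dem, from_cell, to_cell, observer_height_m = 1.7) {
  d <- dim(dem$values)
  if (any(from_cell < 1) || any(to_cell < 1) ||
      from_cell[1] > d[1] || to_cell[1] > d[1] ||
      from_cell[2] > d[2] || to_cell[2] > d[2])
    stopf("cells outside the grid")
  z0 <- dem$values[from_cell[1], from_cell[2]] + observer_height_m
  zt <- dem$values[to_cell[1], to_cell[2]]
  if (is.na(z0) || is.na(zt)) return(FALSE)
  line <- bresenham_cells(from_cell[1], from_cell[2], to_cell[1], to_cell[2])
  n <- nrow(line)
  if (n <= 2) return(TRUE)
  cs <- dem$cell_size
  dist <- cs * sqrt((line[, 1] - from_cell[1])^2 +
                    (line[, 2] - from_cell[2])^2)
  z <- dem$values[line]
  st <- (zt - z0) / dist[n]
  si <- (z[2:(n - 1)] - z0) / dist[2:(n - 1)]
  if (anyNA(si)) return(FALSE)
  all(si <= st)
}

## Precomputed sight-line structure for a disk of radius `rad` cells:
## offsets of all disk cells, their horizontal distances, and a padded
## chain matrix giving for each target the indices (into the offset list)
## of its intermediate Bresenham cells. Cached per radius.
.vs_cache <- new.env(parent = emptyenv())

.disk_chains <- function(rad) {
  key <- as.character(round(rad, 6))
  if (!is.null(.vs_cache[[key]])) return(.vs_cache[[key]])
  radc <- as.integer(ceiling(rad))
  offs <- expand.grid(dr = -radc:radc, dc = -radc:radc)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 &
                 !(offs$dr == 0 & offs$dc == 0), ]
  K <- nrow(offs)
  idx_of <- new.env(parent = emptyenv(), size = K)
  for (i in seq_len(K))
    assign(sprintf("%d,%d", offs$dr[i], offs$dc[i]), i, envir = idx_of)
  chains <- vector("list", K)
  maxlen <- 0L
  for (i in seq_len(K)) {
    line <- bresenham_cells(0L, 0L, offs$dr[i], offs$dc[i])
    if (nrow(line) > 2) {
      mid <- line[2:(nrow(line) - 1), , drop = FALSE]
      chains[[i]] <- vapply(seq_len(nrow(mid)), function(j)
        get(sprintf("%d,%d", mid[j, 1], mid[j, 2]), envir = idx_of),
        integer(1))
    } else chains[[i]] <- integer(0)
    maxlen <- max(maxlen, length(chains[[i]]))
  }
  CM <- matrix(0L, K, maxlen)
  for (i in seq_len(K))
    if (length(chains[[i]])) CM[i, seq_along(chains[[i]])] <- chains[[i]]
  res <- list(dr = offs$dr, dc = offs$dc,
              dist_cells = sqrt(offs$dr^2 + offs$dc^2), chain = CM)
  .vs_cache[[key]] <- res
  res
}

## visibility of all disk cells around one observer cell; returns linear
## indices of visible cells (target ground level, observer eye height h)
.observer_viewshed <- function(Z, n, m, cs, r0, c0, rad, h) {
  ch <- .disk_chains(rad)
  rr <- r0 + ch$dr; cc <- c0 + ch$dc
  ingrid <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
  z0 <- Z[r0, c0] + h
  if (is.na(z0)) return(integer(0))
  slope <- rep(-Inf, length(ch$dr))       # off-grid cells never block
  zi <- Z[cbind(rr[ingrid], cc[ingrid])]
  s <- (zi - z0) / (ch$dist_cells[ingrid] * cs)
  s[is.na(s)] <- Inf                       # nodata blocks and is not visible
  slope[ingrid] <- s
  slope_ext <- c(-Inf, slope)
  blockmax <- rep(-Inf, length(slope))
  for (l in seq_len(ncol(ch$chain)))
    blockmax <- pmax(blockmax, slope_ext[ch$chain[, l] + 1L])
  vis <- ingrid & is.finite(slope) & blockmax <= slope
  (cc[vis] - 1L) * n + rr[vis]
}

## observer points every spacing_m along a polyline (arc-length), incl. ends
.sample_along <- function(v, spacing) {
  if (nrow(v) < 2) return(v)
  seglen <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  L <- sum(seglen)
  s <- unique(c(seq(0, L, by = spacing), L))
  cum <- c(0, cumsum(seglen))
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(v) - 1)
  t <- (s - cum[i]) / pmax(seglen[i], 1e-12)
  cbind(v[i, 1] + t * (v[i + 1, 1] - v[i, 1]),
        v[i, 2] + t * (v[i + 1, 2] - v[i, 2]))
}

#' Viewshed of a transect set
#'
#' Union of single-point viewsheds from observer points sampled every
#' `spacing_m` along each transect (default one cell size, approximating
#' continuous movement), clipped to the Euclidean buffer of `radius_m`
#' around the transect polylines. Observer eye height defaults to 1.7 m,
#' targets are at ground level; no curvature or refraction correction is
#' applied at these sub-1.5-km ranges.
#'
#' @param dem elevation `grid_raster`.
#' @param transects a `transect_set` (or a single vertex matrix).
#' @param radius_m buffer radius in metres (1,000 or 1,500 in the survey
#'   design).
#' @param observer_height_m observer eye height (m).
#' @param spacing_m observer spacing along the transect (m); default one
#'   cell.
#' @return a `viewshed_result`: list with binary `visible` grid, `radius_m`,
#'   `observer_height_m`, `spacing_m`.
#' @export
transect_viewshed <- function(dem, transects, radius_m,
                              observer_height_m = 1.7, spacing_m = NULL) {
  if (inherits(transects, "matrix")) transects <- transect_set(list(transects))
  if (!length(transects$lines)) stopf("empty transect set")
  spacing_m <- spacing_m %||% dem$cell_size
  Z <- dem$values
  n <- nrow(Z); m <- ncol(Z)
  cs <- dem$cell_size
  ## each observer's sight disk extends two cells beyond the buffer radius
  ## so cell-centre discretisation never truncates the clipped union
  rad <- (radius_m + 2 * cs) / cs
  vis <- logical(n * m)
  for (v in transects$lines) {
    obs <- .sample_along(v, spacing_m)
    idx <- cell_index(dem, obs[, 1], obs[, 2])
    idx <- unique(stats::na.omit(idx))
    for (i in seq_len(nrow(idx))) {
      r0 <- idx$row[i]; c0 <- idx$col[i]
      vis[.observer_viewshed(Z, n, m, cs, r0, c0, rad, observer_height_m)] <-
        TRUE
      vis[(c0 - 1L) * n + r0] <- TRUE      # observer's own cell
    }
  }
  ## clip to the metric buffer around the polylines
  ctr <- cell_centers(dem)
  X <- matrix(rep(ctr$x, each = n), n, m)
  Y <- matrix(rep(ctr$y, times = m), n, m)
  dbuf <- point_transect_distance(as.vector(X), as.vector(Y), transects)
  vis <- vis & dbuf <= radius_m
  out <- matrix(0, n, m)
  out[vis] <- 1
  out[is.na(Z)] <- NA_real_
  structure(list(visible = grid_like(dem, out), radius_m = radius_m,
                 observer_height_m = observer_height_m,
                 spacing_m = spacing_m),
            class = "viewshed_result")
}

#' @export
print.viewshed_result <- function(x, ...) {
  cat(sprintf("viewshed_result: radius %g m, %.2f km2 visible\n",
              x$radius_m, visible_area(x)))
  invisible(x)
}

#' Visible area of a viewshed
#'
#' @param vs a `viewshed_result` (or binary `grid_raster`).
#' @return visible surface in km2 (visible cells x cell area).
#' @export
visible_area <- function(vs) {
  g <- if (inherits(vs, "viewshed_result")) vs$visible else vs
  sum(g$values == 1, na.rm = TRUE) * g$cell_size^2 / 1e6
}

#' Minimum density from total counts in viewsheds
#'
#' The conservative density estimator of total-count surveys: all
#' individuals (every sex/age class) whose group location lies inside the
#' visible surveyed surface, divided by that surface. Two buffer radii give
#' the upper (smaller area) and lower (larger area) limits of the estimate.
#'
#' @param obs observation table with columns `x`, `y`, `group_size`.
#' @param viewsheds named list of `viewshed_result`s, one per radius (names
#'   are the radii in metres, e.g. `"1000"`, `"1500"`).
#' @param season optional season label.
#' @return data.frame of class `density_estimate` with one row per radius:
#'   `season`, `buffer_radius_m`, `individuals_counted`, `visible_area_km2`,
#'   `density_ind_per_km2` (exact ratio) and `density_reported` (one
#'   decimal, half up).
#' @export
minimum_density <- function(obs, viewsheds, season = NA_character_) {
  rows <- lapply(names(viewsheds), function(nm) {
    vs <- viewsheds[[nm]]
    g <- vs$visible
    inside <- extract_values(g, obs$x, obs$y)
    counted <- sum(obs$group_size[!is.na(inside) & inside == 1])
    area <- visible_area(vs)
    density_estimate(counted, area, buffer_radius_m = vs$radius_m,
                     season = season)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("density_estimate", "data.frame")
  out
}

#' Build a density estimate from a count and a visible area
#'
#' The arithmetic core of [minimum_density()], usable directly when counts
#' and visible areas are already known (e.g. from a published survey
#' summary): `density = individuals / area`, reported to one decimal with
#' halves rounding up.
#'
#' @param individuals_counted total individuals counted (>= 0).
#' @param visible_area_km2 visible surveyed area in km2 (> 0).
#' @param buffer_radius_m buffer radius label (m).
#' @param season optional season label.
#' @return one-row data.frame of class `density_estimate`.
#' @export
density_estimate <- function(individuals_counted, visible_area_km2,
                             buffer_radius_m = NA_real_,
                             season = NA_character_) {
  if (visible_area_km2 <= 0) stopf("visible area must be positive")
  if (individuals_counted < 0) stopf("individual count must be >= 0")
  dens <- individuals_counted / visible_area_km2
  out <- data.frame(season = season, buffer_radius_m = buffer_radius_m,
                    individuals_counted = individuals_counted,
                    visible_area_km2 = visible_area_km2,
                    density_ind_per_km2 = dens,
                    density_reported = round_half_up(dens, 1))
  class(out) <- c("density_estimate", "data.frame")
  out
}

#' Fraction of observed groups within a buffer radius
#'
#' @param obs observation table with a `distance_m` column.
#' @param radius_m buffer radius (m).
#' @return share of groups with `distance_m <= radius_m`.
#' @export
buffer_inclusion_fraction <- function(obs, radius_m) {
  if (!nrow(obs)) stopf("empty observation table")
  mean(obs$distance_m <= radius_m)
}
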