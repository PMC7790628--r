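## Terrain operators on grid_raster DEMs. All 3x3 kernel operators return
## NA on the one-cell border and propagate NA from any neighbour.

## neighbour view helpers: interior of Z shifted by (dr, dc)
.nb <- function(Z, dr, dc) {
  n <- nrow(Z); m <- ncol(Z)
  Z[(2 + dr):(n - 1 + dr), (2 + dc):(m - 1 + dc), drop = FALSE]
}

## Horn's third-order finite differences (1-2-1 weights) at interior cells;
## returns list(dzdx eastward, dzdy northward) per metre.
.horn_gradient <- function(dem) {
  Z <- dem$values
  cs <- dem$cell_size
  a <- .nb(Z, -1, -1); b <- .nb(Z, -1, 0); cc <- .nb(Z, -1, 1)
  d <- .nb(Z,  0, -1);                      f <- .nb(Z,  0, 1)
  g <- .nb(Z,  1, -1); h <- .nb(Z,  1, 0);  i <- .nb(Z,  1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  ## the kernel skips the centre cell, but nodata there must still propagate
  ctr_na <- is.na(.nb(Z, 0, 0))
  dzdx[ctr_na] <- NA_real_
  dzdy[ctr_na] <- NA_real_
  list(dzdx = dzdx, dzdy = dzdy)
}

.with_border_na <- function(dem, interior) {
  out <- matrix(NA_real_, nrow(dem$values), ncol(dem$values))
  out[2:(nrow(out) - 1), 2:(ncol(out) - 1)] <- interior
  grid_like(dem, out)
}

.check_kernel_dem <- function(dem) {
  if (!inherits(dem, "grid_raster")) stopf("`dem` must be a grid_raster")
  if (nrow(dem$values) < 3 || ncol(dem$values) < 3)
    stopf("DEM must be at least 3 x 3 for a 3 x 3 kernel")
}

#' Slope from a DEM (Horn's method)
#'
#' Per-cell slope in degrees from Horn's 3x3 third-order finite difference
#' (1-2-1 weights), the estimator used by standard GIS slope tools.
#'
#' @param dem a `grid_raster` of elevations in metres, at least 3x3.
#' @return `grid_raster` of slope in degrees, `[0, 90)`; border cells `NA`.
#' @export
horn_slope <- function(dem) {
  .check_kernel_dem(dem)
  gr <- .horn_gradient(dem)
  .with_border_na(dem, atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi)
}

#' Aspect from a DEM (Horn's method)
#'
#' Downslope direction in degrees clockwise from north, `[0, 360)`.
#' Flat cells (zero gradient) are `NA`.
#'
#' @inheritParams horn_slope
#' @return `grid_raster` of aspect in degrees; border and flat cells `NA`.
#' @export
horn_aspect <- function(dem) {
  .check_kernel_dem(dem)
  gr <- .horn_gradient(dem)
  # downslope vector is -grad; compass angle = atan2(east, north)
  asp <- atan2(-gr$dzdx, -gr$dzdy) * 180 / pi
  asp <- (asp + 360) %% 360
  asp[which(gr$dzdx == 0 & gr$dzdy == 0)] <- NA_real_
  .with_border_na(dem, asp)
}

#' Deviation of aspect from due south
#'
#' Circular distance of an aspect from 180 degrees:
#' `min(|a - 180|, 360 - |a - 180|)`, in `[0, 180]`. Used in place of raw
#' aspect so a circular covariate is not fed to a smooth term.
#'
#' @param aspect `grid_raster` of aspects in degrees `[0, 360)` (or `NA`).
#' @return `grid_raster` of deviations in degrees; `NA` propagates.
#' @export
south_deviation <- function(aspect) {
  a <- abs(aspect$values - 180)
  grid_like(aspect, pmin(a, 360 - a))
}

#' Terrain ruggedness index (Riley)
#'
#' Square root of the summed squared elevation differences between each cell
#' and its eight neighbours, in metres.
#'
#' @inheritParams horn_slope
#' @return `grid_raster` of TRI in metres; border cells `NA`.
#' @export
riley_tri <- function(dem) {
  .check_kernel_dem(dem)
  Z <- dem$values
  ctr <- .nb(Z, 0, 0)
  ss <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ss <- ss + (.nb(Z, dr, dc) - ctr)^2
  }
  .with_border_na(dem, sqrt(ss))
}

## 8-connected component labelling of a logical matrix; returns integer
## matrix of labels (0 where FALSE/NA).
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  nextlab <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% n + 1L
      c <- (cur - 1L) %/% n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * n + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nextlab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Cliff detection from a slope raster
#'
#' Cliffs are 8-connected components of cells with slope strictly above
#' `threshold_deg` whose area (cells x cell size squared) strictly exceeds
#' `min_area_m2`. Defaults follow the common escape-terrain definition for
#' mountain ungulates (> 45 degrees, > 90 m2).
#'
#' @param slope `grid_raster` of slope in degrees.
#' @param threshold_deg slope threshold (strict).
#' @param min_area_m2 minimum component area in m2 (strict).
#' @return binary `grid_raster` (1 = cliff); `NA` slope cells stay `NA`.
#' @export
detect_cliffs <- function(slope, threshold_deg = 45, min_area_m2 = 90) {
  steep <- slope$values > threshold_deg
  lab <- label_components(steep)
  cell_area <- slope$cell_size^2
  keep <- which(tabulate(lab) * cell_area > min_area_m2)
  out <- matrix(0, nrow(lab), ncol(lab))
  out[lab %in% keep] <- 1
  out[is.na(slope$values)] <- NA_real_
  grid_like(slope, out)
}

#' Fill depressions in a DEM
#'
#' Raises every closed depression to its spill elevation so that each cell
#' has a non-ascending 8-neighbour path to the grid border. Idempotent and
#' the identity on sink-free inputs (flats are left untouched). `NA` cells
#' act as outlets.
#'
#' @param dem a `grid_raster` of elevations.
#' @return `grid_raster` with `filled >= dem` everywhere.
#' @export
fill_sinks <- function(dem) {
  Z <- dem$values
  n <- nrow(Z); m <- ncol(Z)
  if (n < 3 || m < 3) return(dem)
  na <- is.na(Z)
  Zw <- Z
  Zw[na] <- -Inf                 # nodata drains everything adjacent
  W <- matrix(Inf, n, m)
  border <- row(Z) == 1 | row(Z) == n | col(Z) == 1 | col(Z) == m
  W[border | na] <- Zw[border | na]
  pad <- function(M) rbind(Inf, cbind(Inf, M, Inf), Inf)
  repeat {
    P <- pad(W)
    nbmin <- matrix(Inf, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbmin <- pmin(nbmin, P[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)])
    }
    Wnew <- pmax(Zw, nbmin)
    Wnew[border | na] <- Zw[border | na]
    if (all(Wnew == W)) break
    W <- Wnew
  }
  W[na] <- NA_real_
  grid_like(dem, W)
}

## D8 neighbour table in direction-code order (ESRI codes)
.d8 <- data.frame(
  code = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
  dr   = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
  dc   = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
  dist = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))

#' D8 flow direction
#'
#' Each cell drains to its steepest-descent 8-neighbour (drop divided by
#' centre distance, diagonals by `sqrt(2)`). Direction codes follow the
#' usual GIS convention (E = 1, SE = 2, S = 4, SW = 8, W = 16, NW = 32,
#' N = 64, NE = 128); border cells that drain off-grid get code 0. Ties go
#' to the lowest code. Flats remaining after [fill_sinks()] are resolved
#' deterministically by a breadth-first sweep from their spill and border
#' cells, so every plateau cell points along a shortest same-elevation path
#' toward where drainage leaves the flat.
#'
#' @param dem_filled a sink-filled `grid_raster` (see [fill_sinks()]).
#' @return integer-coded `grid_raster` of directions; `NA` cells stay `NA`.
#' @export
d8_flow_direction <- function(dem_filled) {
  Z <- dem_filled$values
  n <- nrow(Z); m <- ncol(Z)
  dir <- matrix(NA_real_, n, m)
  na <- is.na(Z)
  rowm <- row(Z); colm <- col(Z)
  border <- rowm == 1 | rowm == n | colm == 1 | colm == m

  bestdrop <- matrix(-Inf, n, m)
  for (k in seq_len(nrow(.d8))) {
    rr <- rowm + .d8$dr[k]; cc <- colm + .d8$dc[k]
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
    drop <- matrix(-Inf, n, m)
    nbz <- matrix(NA_real_, n, m)
    nbz[ok] <- Z[cbind(rr[ok], cc[ok])]
    drop <- (Z - nbz) / (.d8$dist[k] * dem_filled$cell_size)
    drop[!ok | is.na(drop)] <- -Inf
    better <- drop > bestdrop        # strict: earlier (lower) code wins ties
    bestdrop[better] <- drop[better]
    dir[better] <- .d8$code[k]
  }
  dir[bestdrop <= 0] <- NA_real_     # flats: no strictly lower neighbour
  resolved <- !is.na(dir)
  dir[border & !resolved & !na] <- 0 # flat border cells drain off-grid
  resolved <- !is.na(dir)

  ## breadth-first flat resolution: point at the equal-elevation neighbour
  ## through which the spill is reached first; lowest code breaks ties.
  repeat {
    newdir <- matrix(NA_real_, n, m)
    for (k in seq_len(nrow(.d8))) {
      rr <- rowm + .d8$dr[k]; cc <- colm + .d8$dc[k]
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
      cand <- !resolved & !na & ok & is.na(newdir)
      if (!any(cand)) next
      nbi <- cbind(rr[cand], cc[cand])
      good <- resolved[nbi] & !na[nbi] & Z[nbi] == Z[cand]
      w <- which(cand)[good]
      if (length(w)) newdir[w] <- .d8$code[k]
    }
    w <- which(!is.na(newdir))
    if (!length(w)) break
    dir[w] <- newdir[w]
    resolved[w] <- TRUE
  }
  if (any(!resolved & !na))
    stopf("unresolvable flow direction: DEM contains unfilled sinks")
  grid_like(dem_filled, dir)
}

## receiver linear index per cell from a direction grid; 0 = outlet
.d8_receivers <- function(dirgrid) {
  D <- dirgrid$values
  n <- nrow(D); m <- ncol(D)
  recv <- rep(NA_integer_, n * m)
  rowm <- as.vector(row(D)); colm <- as.vector(col(D))
  dv <- as.vector(D)
  recv[!is.na(dv) & dv == 0] <- 0L
  for (k in seq_len(nrow(.d8))) {
    sel <- which(!is.na(dv) & dv == .d8$code[k])
    if (!length(sel)) next
    rr <- rowm[sel] + .d8$dr[k]; cc <- colm[sel] + .d8$dc[k]
    out <- rr < 1 | rr > n | cc < 1 | cc > m
    recv[sel[out]] <- 0L
    recv[sel[!out]] <- (cc[!out] - 1L) * n + rr[!out]
  }
  recv
}

#' D8 flow accumulation
#'
#' Number of upstream cells draining through each cell (the cell itself not
#' counted), computed in topological order over the direction graph.
#'
#' @param directions a direction-coded `grid_raster` from
#'   [d8_flow_direction()].
#' @return `grid_raster` of upstream cell counts; `NA` direction cells stay
#'   `NA` and neither drain nor count.
#' @export
flow_accumulation <- function(directions) {
  recv <- .d8_receivers(directions)
  active <- which(!is.na(recv))
  ncells <- length(recv)
  acc <- rep(0, ncells)
  indeg <- rep(0L, ncells)
  to <- recv[active]
  to <- to[to > 0L]
  ## receivers pointing into NA cells would be malformed
  if (any(is.na(recv[to])))
    stopf("flow directed into a nodata cell")
  t1 <- tabulate(to, nbins = ncells)
  indeg <- t1
  queue <- active[indeg[active] == 0L]
  head <- 1L
  nproc <- 0L
  queue <- c(queue, integer(length(active)))
  tail <- sum(indeg[active] == 0L)
  while (head <= tail) {
    c0 <- queue[head]; head <- head + 1L; nproc <- nproc + 1L
    r0 <- recv[c0]
    if (r0 > 0L) {
      acc[r0] <- acc[r0] + acc[c0] + 1
      indeg[r0] <- indeg[r0] - 1L
      if (indeg[r0] == 0L) { tail <- tail + 1L; queue[tail] <- r0 }
    }
  }
  if (nproc != length(active))
    stopf("cycle detected in flow directions")
  out <- matrix(acc, nrow(directions$values), ncol(directions$values))
  out[is.na(recv)] <- NA_real_
  grid_like(directions, out)
}

#' Stream extraction by accumulation threshold
#'
#' @param accum `grid_raster` of flow accumulation (upstream cell counts).
#' @param threshold_cells cells with accumulation `>= threshold_cells`
#'   become streams.
#' @return binary `grid_raster` (1 = stream); `NA` propagates.
#' @export
extract_streams <- function(accum, threshold_cells) {
  grid_like(accum, (accum$values >= threshold_cells) * 1)
}

## exact 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

## exact EDT (in metres) from TRUE cells of a logical matrix
.edt <- function(mask, cell_size) {
  n <- nrow(mask); m <- ncol(mask)
  ## large finite stand-in for +Inf keeps the parabola intersections finite
  f <- matrix(1e15, n, m)
  f[mask] <- 0
  if (n > 1) f <- apply(f, 2, .dt1d) else f
  if (m > 1) f <- t(apply(f, 1, .dt1d))
  sqrt(f) * cell_size
}

#' Euclidean distance surface
#'
#' Distance in metres from every cell centre to the nearest feature. Features
#' may be point coordinates (two-column matrix or data.frame with `x`, `y`),
#' polylines (a `transect_set` or list of vertex matrices; distance to the
#' nearest segment), or a binary `grid_raster` (distance to the nearest
#' centre of a 1-cell, via an exact distance transform).
#'
#' @param features feature geometry as described above.
#' @param template `grid_raster` defining the output frame.
#' @return `grid_raster` of distances in metres (0 on features). An empty
#'   feature set yields all-`Inf` with a warning.
#' @export
distance_surface <- function(features, template) {
  d <- dim(template$values)
  ctr <- cell_centers(template)
  X <- matrix(rep(ctr$x, each = d[1]), d[1], d[2])
  Y <- matrix(rep(ctr$y, times = d[2]), d[1], d[2])

  if (inherits(features, "grid_raster")) {
    if (!same_frame(features, template))
      stopf("binary feature grid must share the template frame")
    mask <- !is.na(features$values) & features$values == 1
    if (!any(mask)) {
      warning("empty feature set: distance surface is all Inf")
      return(grid_like(template, matrix(Inf, d[1], d[2])))
    }
    return(grid_like(template, .edt(mask, template$cell_size)))
  }

  segs <- NULL
  pts <- NULL
  if (inherits(features, "transect_set") ||
      (is.list(features) && !is.data.frame(features) && !is.matrix(features))) {
    lines <- if (inherits(features, "transect_set")) features$lines else features
    segs <- do.call(rbind, lapply(lines, function(v) {
      v <- as.matrix(v)
      if (nrow(v) < 2) return(NULL)
      cbind(v[-nrow(v), 1], v[-nrow(v), 2], v[-1, 1], v[-1, 2])
    }))
  } else {
    pts <- as.matrix(as.data.frame(features)[, 1:2])
  }

  if ((is.null(pts) || nrow(pts) == 0) && (is.null(segs) || nrow(segs) == 0)) {
    warning("empty feature set: distance surface is all Inf")
    return(grid_like(template, matrix(Inf, d[1], d[2])))
  }

  best <- matrix(Inf, d[1], d[2])
  if (!is.null(pts)) {
    for (i in seq_len(nrow(pts)))
      best <- pmin(best, sqrt((X - pts[i, 1])^2 + (Y - pts[i, 2])^2))
  } else {
    for (i in seq_len(nrow(segs))) {
      x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx^2 + vy^2
      if (L2 == 0) {
        best <- pmin(best, sqrt((X - x1)^2 + (Y - y1)^2))
      } else {
        t <- pmin(1, pmax(0, ((X - x1) * vx + (Y - y1) * vy) / L2))
        best <- pmin(best, sqrt((X - (x1 + t * vx))^2 + (Y - (y1 + t * vy))^2))
      }
    }
  }
  grid_like(template, best)
}

#' Livestock presence raster
#'
#' Binary surface marking cells whose centre lies within `buffer_m` of any
#' livestock location, the buffer convention used to contrast shared and
#' livestock-free pasture.
#'
#' @param points two-column matrix or data.frame of livestock locations (m).
#' @param template `grid_raster` defining the output frame.
#' @param buffer_m buffer radius in metres (inclusive).
#' @return binary `grid_raster` (1 = livestock present).
#' @export
livestock_presence <- function(points, template, buffer_m = 500) {
  pts <- as.matrix(as.data.frame(points))
  if (nrow(pts) == 0)
    return(grid_like(template, matrix(0, nrow(template$values),
                                      ncol(template$values))))
  dsurf <- distance_surface(pts, template)
  grid_like(template, (dsurf$values <= buffer_m) * 1)
}

#' Build the standard covariate stack
#'
#' Derives every DEM-based covariate used by the habitat-selection analysis
#' and assembles them with NDVI and the feature distance surfaces.
#'
#' @param dem elevation `grid_raster`.
#' @param ndvi NDVI `grid_raster` in the same frame.
#' @param features a `feature_set` (settlements, trails, livestock), or
#'   `NULL` to skip the anthropogenic layers.
#' @param livestock_buffer_m buffer radius for [livestock_presence()].
#' @param stream_threshold_km2 drainage area (km2) above which a cell is a
#'   stream.
#' @param cliff_threshold_deg,cliff_min_area_m2 passed to [detect_cliffs()].
#' @return a `covariate_stack` with layers `elevation`, `slope_deg`, `tri_m`,
#'   `aspect_deg`, `south_deviation_deg`, `ndvi`, `dist_cliff_m`,
#'   `dist_stream_m` and, when features are given, `dist_settlement_m`,
#'   `dist_trail_m`, `livestock_presence`.
#' @export
build_covariates <- function(dem, ndvi, features = NULL,
                             livestock_buffer_m = 500,
                             stream_threshold_km2 = 0.5,
                             cliff_threshold_deg = 45,
                             cliff_min_area_m2 = 90) {
  slope <- horn_slope(dem)
  aspect <- horn_aspect(dem)
  layers <- list(
    elevation = dem,
    slope_deg = slope,
    tri_m = riley_tri(dem),
    aspect_deg = aspect,
    south_deviation_deg = south_deviation(aspect),
    ndvi = ndvi)
  cliffs <- detect_cliffs(slope, cliff_threshold_deg, cliff_min_area_m2)
  layers$dist_cliff_m <- distance_surface(cliffs, dem)
  filled <- fill_sinks(dem)
  accum <- flow_accumulation(d8_flow_direction(filled))
  thr <- max(1, round(stream_threshold_km2 * 1e6 / dem$cell_size^2))
  streams <- extract_streams(accum, thr)
  layers$dist_stream_m <- distance_surface(streams, dem)
  if (!is.null(features)) {
    layers$dist_settlement_m <- distance_surface(features$settlements, dem)
    layers$dist_trail_m <- distance_surface(features$trails, dem)
    layers$livestock_presence <-
      livestock_presence(features$livestock, dem, livestock_buffer_m)
  }
  covariate_stack(layers)
}
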