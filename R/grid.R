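#' Planar single-band raster grid
#'
#' The central raster container: a numeric matrix in a planar metric
#' coordinate frame. Row 1 is the northernmost row, column 1 the westernmost
#' column; `origin` is the (x, y) of the *upper-left corner* of cell
#' \[1, 1\] in metres. Missing cells are `NA`.
#'
#' @param values numeric matrix (rows north to south).
#' @param origin numeric length-2, (x, y) of the upper-left grid corner in m.
#' @param cell_size cell edge length in metres (> 0).
#' @return an object of class `grid_raster`.
#' @examples
#' g <- grid_raster(matrix(runif(12), 3, 4), origin = c(0, 300), cell_size = 30)
#' dim(g)
#' grid_extent(g)
#' @export
grid_raster <- function(values, origin = c(0, 0), cell_size = 30) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !(is.numeric(values) || is.logical(values)))
    stopf("`values` must be a numeric matrix")
  if (length(origin) != 2 || !is.numeric(origin))
    stopf("`origin` must be numeric (x, y)")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stopf("`cell_size` must be a single positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size)),
    class = "grid_raster")
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @rdname grid_raster
#' @param x,g a `grid_raster`.
#' @export
grid_values <- function(g) g$values

#' @rdname grid_raster
#' @export
grid_cell_size <- function(g) g$cell_size

#' @rdname grid_raster
#' @export
grid_origin <- function(g) g$origin

#' Extent of a grid
#' @param g a `grid_raster`.
#' @return named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$origin[1], xmax = g$origin[1] + d[2] * g$cell_size,
    ymin = g$origin[2] - d[1] * g$cell_size, ymax = g$origin[2])
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  e <- grid_extent(x)
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster: %d rows x %d cols @ %g m\n", d[1], d[2], x$cell_size))
  cat(sprintf("  extent   : x [%g, %g], y [%g, %g] m\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
  if (length(v))
    cat(sprintf("  values   : [%g, %g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  else cat("  values   : all NA\n")
  invisible(x)
}

## shared-frame predicate used by stack validation and raster algebra
same_frame <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

## build a grid that shares a template's frame
grid_like <- function(template, values) {
  grid_raster(values, origin = template$origin, cell_size = template$cell_size)
}

#' Cell-centre coordinates
#'
#' @param g a `grid_raster`.
#' @return list with vectors `x` (per column) and `y` (per row) of cell-centre
#'   coordinates, northernmost row first.
#' @export
cell_centers <- function(g) {
  d <- dim(g$values)
  list(x = g$origin[1] + (seq_len(d[2]) - 0.5) * g$cell_size,
       y = g$origin[2] - (seq_len(d[1]) - 0.5) * g$cell_size)
}

#' Locate points on a grid
#'
#' Cell membership uses half-open intervals `[low, high)` in x and the
#' mirrored convention in y (a point on a cell's northern edge belongs to
#' that cell). Points outside the extent get `NA`.
#'
#' @param g a `grid_raster`.
#' @param x,y point coordinates in metres.
#' @return data.frame with integer columns `row`, `col`.
#' @export
cell_index <- function(g, x, y) {
  d <- dim(g$values)
  cs <- g$cell_size
  col <- floor((x - g$origin[1]) / cs) + 1
  row <- ceiling((g$origin[2] - y) / cs)
  row[y == g$origin[2]] <- 1   # points exactly on the northern grid edge
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @inheritParams cell_index
#' @return numeric vector, `NA` outside the extent.
#' @export
extract_values <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Named stack of co-registered covariate grids
#'
#' Holds the covariate layers used by the habitat-selection model (elevation,
#' slope, ruggedness, south deviation, NDVI, livestock presence, distance
#' surfaces, ...). All layers must share origin, shape and cell size.
#'
#' @param ... named `grid_raster` layers, or a single named list of them.
#' @return an object of class `covariate_stack` (a named list of grids).
#' @export
covariate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && !inherits(layers[[1]], "grid_raster"))
    layers <- layers[[1]]
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stopf("all layers must be named")
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid_raster"))
      stopf("layer '%s' is not a grid_raster", nm)
    if (!same_frame(layers[[1]], layers[[nm]]))
      stopf("layer '%s' does not share the stack frame", nm)
  }
  structure(layers, class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- dim(x[[1]]$values)
  cat(sprintf("covariate_stack: %d layers, %d x %d @ %g m\n  %s\n",
              length(x), d[1], d[2], x[[1]]$cell_size,
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Extract all stack layers at point locations
#'
#' @param stack a `covariate_stack`.
#' @param x,y point coordinates in metres.
#' @return data.frame, one column per layer.
#' @export
extract_covariates <- function(stack, x, y) {
  out <- lapply(stack, extract_values, x = x, y = y)
  as.data.frame(out)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' north to south), round-tripping origin, cell size and nodata cells.
#'
#' @param g a `grid_raster`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @return `read_ascii_grid` returns a `grid_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  d <- dim(g$values)
  e <- grid_extent(g)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", e["xmin"]),
           sprintf("yllcorner %.10g", e["ymin"]),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- g$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, digits = 10, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  cs <- val[["cellsize"]]; nodata <- val[["nodata_value"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrows * ncols) stopf("malformed ASCII grid '%s'", path)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_raster(m, origin = c(val[["xllcorner"]], val[["yllcorner"]] + nrows * cs),
              cell_size = cs)
}
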