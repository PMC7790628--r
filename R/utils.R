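#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.05 -> 0.1), the
#' convention used when reporting densities and transect lengths, unlike
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Bresenham rasterisation of the segment between two cells, inclusive of both
## endpoints. Returns a two-column matrix (row, col). Used by line-of-sight so
## that the standalone predicate and the viewshed sweep share one rasterisation.
bresenham_cells <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, 1L] <- r; out[i, 2L] <- c
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

## Draw a derived RNG seed below 2^31 from a base seed and a stage label, so
## that pipeline stages are independently reproducible from one master seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + h %% 100003L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
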