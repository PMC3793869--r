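# Plain-polygon helpers used across modules. Polygons are n x 2 matrices of
# (x, y) vertices, implicitly closed, counter-clockwise when oriented.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param v Two-column matrix of vertices, implicitly closed.
#' @return \code{polygonArea}: absolute area; \code{polygonSignedArea}:
#'   signed area (positive for counter-clockwise vertex order).
#' @export
polygonArea <- function(v) abs(polygonSignedArea(v))

#' @rdname polygonArea
#' @export
polygonSignedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon perimeter
#' @param v Two-column vertex matrix, implicitly closed.
#' @return Total polyline length.
#' @export
polygonPerimeter <- function(v) {
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(sqrt(rowSums((v[j, , drop = FALSE] - v)^2)))
}

ensureCCW <- function(v) {
  if (polygonSignedArea(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

#' Test points against a closed polygon (even-odd rule)
#'
#' @param pts Two-column matrix of query points.
#' @param poly Two-column vertex matrix, implicitly closed.
#' @return Logical vector: point strictly inside the polygon.
#' @export
pointInPolygon <- function(pts, poly) {
  pts <- rbind(pts)
  cpp_point_in_polygon(pts[, 1L], pts[, 2L], poly[, 1L], poly[, 2L])
}

#' Minimum distance from points to a closed polygon boundary
#'
#' @param pts Two-column matrix of query points.
#' @param poly Two-column vertex matrix, implicitly closed.
#' @return Numeric vector of Euclidean distances to the nearest boundary
#'   point (sub-pixel; not a rasterised distance).
#' @export
distToPolygon <- function(pts, poly) {
  pts <- rbind(pts)
  cpp_dist_to_polyline(pts[, 1L], pts[, 2L], poly[, 1L], poly[, 2L])
}

# Resample a closed polyline to (approximately) equal spacing. Returns the
# same orientation; n is chosen from the target spacing unless given.
resampleClosed <- function(v, spacing = NULL, n = NULL) {
  j <- c(seq_len(nrow(v))[-1L], 1L)
  seg <- sqrt(rowSums((v[j, , drop = FALSE] - v)^2))
  per <- sum(seg)
  if (is.null(n)) n <- max(16L, as.integer(round(per / spacing)))
  s <- c(0, cumsum(seg))
  target <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > nrow(v)] <- nrow(v)
  frac <- (target - s[idx]) / pmax(seg[idx], .Machine$double.eps)
  v[idx, , drop = FALSE] +
    (v[j[idx], , drop = FALSE] - v[idx, , drop = FALSE]) * frac
}

# Evaluate an expression under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NA runs in the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Grids of pixel-center coordinates for an nrow x ncol canvas (0-based).
pixelGrid <- function(nrow, ncol) {
  list(x = matrix(rep(0:(ncol - 1L), each = nrow), nrow, ncol),
       y = matrix(rep(0:(nrow - 1L), times = ncol), nrow, ncol))
}
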