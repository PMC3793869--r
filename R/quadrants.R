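# Four-domain partition of a cell by the diagonals of its axis-oriented
# bounding rectangle. Domains: NSB (toward the notochord-somite boundary,
# i.e. along +axisAngle), ANTI (opposite), ANT / POST (the two flanks; ANT
# is 90 degrees counter-clockwise from the NSB direction in the
# mathematical x/y sense). Tie-break for points exactly on a diagonal: the
# diagonal belongs to the sector counter-clockwise of it; the center is NSB.

# normalised rectangle coordinates: s along the axis, t across, both in
# units of the respective half side; diagonals are |s| == |t|
.rectCoords <- function(pts, center, axisAngle, halfExtent) {
  u <- c(cos(axisAngle), sin(axisAngle))
  dx <- pts[, 1L] - center[1L]; dy <- pts[, 2L] - center[2L]
  list(s = (dx * u[1L] + dy * u[2L]) / halfExtent[1L],
       t = (-dx * u[2L] + dy * u[1L]) / halfExtent[2L])
}

# integer domain codes from normalised coordinates; 1=NSB 2=ANTI 3=ANT 4=POST
.domainCode <- function(s, t) {
  code <- integer(length(s))
  as <- abs(s); at <- abs(t)
  code[as > at & s > 0] <- 1L
  code[as > at & s < 0] <- 2L
  code[at > as & t > 0] <- 3L
  code[at > as & t < 0] <- 4L
  tie <- as == at
  if (any(tie)) {
    code[tie & s > 0 & t > 0] <- 3L   # 45 deg ray -> ANT
    code[tie & s < 0 & t > 0] <- 2L   # 135 deg ray -> ANTI
    code[tie & s < 0 & t < 0] <- 4L   # 225 deg ray -> POST
    code[tie & s >= 0 & t <= 0] <- 1L # 315 deg ray and center -> NSB
  }
  code
}

#' Axis-oriented bounding rectangle of a contour
#'
#' The minimal rectangle containing all contour vertices whose sides are
#' parallel and perpendicular to \code{axisAngle}.
#'
#' @param contour A \code{CellContour} or two-column vertex matrix.
#' @param axisAngle Orientation of the rectangle sides, radians.
#' @return 4 x 2 matrix of corners in order (-u,-v), (+u,-v), (+u,+v),
#'   (-u,+v), with attributes \code{center}, \code{halfExtent} and
#'   \code{axisAngle}.
#' @export
orientedBoundingRectangle <- function(contour, axisAngle) {
  v <- if (is(contour, "CellContour")) contour@vertices else contour
  u <- c(cos(axisAngle), sin(axisAngle))
  a <- v[, 1L] * u[1L] + v[, 2L] * u[2L]
  b <- -v[, 1L] * u[2L] + v[, 2L] * u[1L]
  ar <- range(a); br <- range(b)
  corn_ab <- cbind(c(ar[1L], ar[2L], ar[2L], ar[1L]),
                   c(br[1L], br[1L], br[2L], br[2L]))
  corners <- cbind(corn_ab[, 1L] * u[1L] - corn_ab[, 2L] * u[2L],
                   corn_ab[, 1L] * u[2L] + corn_ab[, 2L] * u[1L])
  ctr_ab <- c(mean(ar), mean(br))
  structure(corners,
            center = c(ctr_ab[1L] * u[1L] - ctr_ab[2L] * u[2L],
                       ctr_ab[1L] * u[2L] + ctr_ab[2L] * u[1L]),
            halfExtent = c(diff(ar) / 2, diff(br) / 2),
            axisAngle = axisAngle)
}

#' Partition a cell into four quadrant domains
#'
#' Every pixel of the cell mask is assigned to the sector formed by the two
#' diagonals of the axis-oriented bounding rectangle that contains it, and
#' the contour is split at its intersections with the diagonals to obtain
#' per-domain arc lengths.
#'
#' @param contour A \code{CellContour} (vertices in pixel coordinates).
#' @param mask Logical matrix: the rasterised cell.
#' @param axisAngle Radians toward the NSB; defaults to the contour's.
#' @param pixelSize Micrometres per pixel (arc lengths are reported in um).
#' @return A \code{QuadrantPartition}.
#' @export
partitionQuadrants <- function(contour, mask, axisAngle = NULL,
                               pixelSize = 1) {
  stopifnot(is(contour, "CellContour"))
  if (is.null(axisAngle)) axisAngle <- contour@axisAngle
  rect <- orientedBoundingRectangle(contour, axisAngle)
  he <- attr(rect, "halfExtent")
  if (any(he <= .Machine$double.eps))
    stop("degenerate bounding rectangle (zero width)")
  ctr <- attr(rect, "center")
  idx <- which(mask)
  labelMap <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx)) {
    # 0-based pixel-center coordinates of masked pixels
    py <- (idx - 1L) %% nrow(mask)
    px <- (idx - 1L) %/% nrow(mask)
    st <- .rectCoords(cbind(px, py), ctr, axisAngle, he)
    labelMap[idx] <- .domainCode(st$s, st$t)
  }
  part <- new("QuadrantPartition", rectangle = rect, center = ctr,
              axisAngle = axisAngle, labelMap = labelMap,
              arcLength = setNames(numeric(4L), domainLabels()),
              pixelSize = pixelSize, halfExtent = he)
  part@arcLength <- domainArcLengths(contour, part, pixelSize)
  part
}

#' Contour arc length per domain
#'
#' The contour polyline is split at its intersections with the two rectangle
#' diagonals; each piece accrues to the domain containing its midpoint.
#' Lengths sum exactly to the polygon perimeter.
#'
#' @param contour A \code{CellContour}.
#' @param partition A \code{QuadrantPartition} computed for this contour.
#' @param pixelSize Micrometres per pixel.
#' @return Named numeric vector (um) over \code{domainLabels()}.
#' @export
domainArcLengths <- function(contour, partition, pixelSize = 1) {
  v <- contour@vertices
  n <- nrow(v)
  ctr <- partition@center; ang <- partition@axisAngle
  he <- partition@halfExtent
  st <- .rectCoords(v, ctr, ang, he)
  # diagonal line functions at each vertex
  f1 <- st$s - st$t; f2 <- st$s + st$t
  jn <- c(2:n, 1L)
  seglen <- sqrt(rowSums((v[jn, , drop = FALSE] - v)^2))
  out <- setNames(numeric(4L), domainLabels())
  # segments not crossing either diagonal: classify midpoints vectorised
  cross1 <- (f1 > 0) != (f1[jn] > 0)
  cross2 <- (f2 > 0) != (f2[jn] > 0)
  plain <- !(cross1 | cross2)
  if (any(plain)) {
    mid <- (v[plain, , drop = FALSE] + v[jn[plain], , drop = FALSE]) / 2
    stm <- .rectCoords(mid, ctr, ang, he)
    code <- .domainCode(stm$s, stm$t)
    for (d in 1:4) out[d] <- out[d] + sum(seglen[plain][code == d])
  }
  for (i in which(!plain)) {
    j <- jn[i]
    ts <- numeric()
    if (cross1[i]) ts <- c(ts, f1[i] / (f1[i] - f1[j]))
    if (cross2[i]) ts <- c(ts, f2[i] / (f2[i] - f2[j]))
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    bounds <- c(0, ts, 1)
    p <- v[i, ]; q <- v[j, ]
    for (k in seq_len(length(bounds) - 1L)) {
      tm <- (bounds[k] + bounds[k + 1L]) / 2
      mid <- rbind(p + tm * (q - p))
      stm <- .rectCoords(mid, ctr, ang, he)
      code <- .domainCode(stm$s, stm$t)
      out[code] <- out[code] + (bounds[k + 1L] - bounds[k]) * seglen[i]
    }
  }
  if (any(out == 0))
    warning("zero arc length in domain(s): ",
            paste(domainLabels()[out == 0], collapse = ", "))
  out * pixelSize
}

#' Assign points to quadrant domains
#'
#' @param points Two-column matrix (x, y) in pixel coordinates (a single
#'   point may be given as a length-2 vector).
#' @param partition A \code{QuadrantPartition}.
#' @return Character vector of domain labels. Points outside the bounding
#'   rectangle are still classified by sector (the nearest domain) and
#'   flagged in the \code{"outside"} attribute.
#' @export
assignPointToDomain <- function(points, partition) {
  if (is.null(dim(points))) points <- rbind(points)
  st <- .rectCoords(points, partition@center, partition@axisAngle,
                    partition@halfExtent)
  lab <- domainLabels()[.domainCode(st$s, st$t)]
  structure(lab, outside = abs(st$s) > 1 | abs(st$t) > 1)
}
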