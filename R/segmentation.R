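# Parametric active-contour (snake) outlining of single cells, plus
# rasterisation. The snake carries the classical internal energies
# (elasticity, stiffness) integrated by explicit Euler steps, an edge
# attraction force (gradient of the squared gradient magnitude of the
# Gaussian-smoothed image, whose stable zero sits on the intensity edge)
# and an optional inflation (balloon) force along the outward normal that
# carries the contour from its initialisation to within capture range of
# the edge. Dark intracellular holes (yolk platelets) are filled by
# grayscale morphological closing before force computation so the snake
# settles on the outer cell boundary.

#' Snake evolution parameters
#'
#' @param elasticity Weight of the first-order (membrane) internal force.
#' @param stiffness Weight of the second-order (thin-plate) internal force.
#' @param imageWeight Weight of the edge-attraction force.
#' @param balloon Inflation force along the outward normal (0 disables;
#'   positive inflates an initialisation placed inside the cell).
#' @param step Explicit-Euler step size, px.
#' @param maxIterations Iteration cap.
#' @param tolerance Convergence threshold on mean vertex displacement per
#'   iteration, px.
#' @param resampleSpacing Target vertex spacing after resampling, px.
#' @param resampleEvery Resample period, iterations.
#' @param smoothSigma Gaussian sigma for image smoothing, px.
#' @param closingRadius Radius (px) of the grayscale closing brush used to
#'   fill dark intracellular holes before force computation (0 disables).
#' @return Named list of snake parameters.
#' @export
snakeParams <- function(elasticity = 0.15, stiffness = 0.05,
                        imageWeight = 3, balloon = 0.6, step = 0.3,
                        maxIterations = 1500L, tolerance = 0.02,
                        resampleSpacing = 2, resampleEvery = 10L,
                        smoothSigma = 2, closingRadius = 9L) {
  stopifnot(elasticity >= 0, stiffness >= 0, imageWeight >= 0,
            tolerance > 0, step > 0)
  list(elasticity = elasticity, stiffness = stiffness,
       imageWeight = imageWeight, balloon = balloon, step = step,
       maxIterations = as.integer(maxIterations), tolerance = tolerance,
       resampleSpacing = resampleSpacing,
       resampleEvery = as.integer(resampleEvery),
       smoothSigma = smoothSigma, closingRadius = as.integer(closingRadius))
}

#' Initialise a circular snake contour
#'
#' @param seedPoint Numeric (x, y): a point inside the target cell.
#' @param radius Circle radius, px.
#' @param nVertices Number of vertices.
#' @param cellId,axisAngle Carried into the contour.
#' @return A \code{CellContour}: regular polygon centred on the seed,
#'   counter-clockwise.
#' @export
initialiseContour <- function(seedPoint, radius, nVertices = 64L,
                              cellId = "cell", axisAngle = 0) {
  stopifnot(radius > 0, nVertices >= 3L)
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  new("CellContour",
      vertices = cbind(seedPoint[1L] + radius * cos(th),
                       seedPoint[2L] + radius * sin(th)),
      cellId = cellId, axisAngle = axisAngle)
}

# does the closed polyline self-intersect? O(n^2) segment test
.selfIntersects <- function(v) {
  n <- nrow(v)
  jn <- c(2:n, 1L)
  p <- v; q <- v[jn, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    d1 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], p[js, 1L], p[js, 2L])
    d2 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], q[js, 1L], q[js, 2L])
    d3 <- cross(p[js, 1L], p[js, 2L], q[js, 1L], q[js, 2L], p[i, 1L], p[i, 2L])
    d4 <- cross(p[js, 1L], p[js, 2L], q[js, 1L], q[js, 2L], q[i, 1L], q[i, 2L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Evolve an active contour on a single-channel image
#'
#' Deterministic explicit-Euler evolution until the mean vertex displacement
#' per iteration falls below \code{tolerance} or \code{maxIterations} is
#' reached (in which case the best contour is returned with
#' \code{converged = FALSE}).
#'
#' @param image Numeric matrix (row = y), background-zeroed.
#' @param contour Initial \code{CellContour}.
#' @param params See \code{\link{snakeParams}}.
#' @return The evolved, resampled \code{CellContour}.
#' @export
evolveSnake <- function(image, contour, params = snakeParams()) {
  img <- image
  if (params$closingRadius > 0) {
    kern <- EBImage::makeBrush(2L * params$closingRadius + 1L, "disc")
    img <- as.matrix(EBImage::closing(img / max(img, 1), kern)) * max(img, 1)
  }
  S <- .gauss2d(img, params$smoothSigma)
  g <- .gradients(S)
  M <- g$gx^2 + g$gy^2
  mx <- max(M)
  if (mx > 0) M <- M / mx
  gm <- .gradients(M)
  # normalise the edge force so imageWeight is in px-per-step units
  fscale <- max(sqrt(gm$gx^2 + gm$gy^2))
  if (fscale > 0) { Fx <- gm$gx / fscale; Fy <- gm$gy / fscale }
  else { Fx <- gm$gx; Fy <- gm$gy }

  v <- ensureCCW(contour@vertices)
  v <- resampleClosed(v, spacing = params$resampleSpacing)
  converged <- FALSE
  for (it in seq_len(params$maxIterations)) {
    n <- nrow(v)
    ip <- c(n, 1:(n - 1L)); jn <- c(2:n, 1L)
    d2 <- v[ip, , drop = FALSE] - 2 * v + v[jn, , drop = FALSE]
    d4 <- d2[ip, , drop = FALSE] - 2 * d2 + d2[jn, , drop = FALSE]
    force <- params$elasticity * d2 - params$stiffness * d4
    if (params$imageWeight > 0) {
      force[, 1L] <- force[, 1L] +
        params$imageWeight * .bilinear(Fx, v[, 1L], v[, 2L])
      force[, 2L] <- force[, 2L] +
        params$imageWeight * .bilinear(Fy, v[, 1L], v[, 2L])
    }
    if (params$balloon != 0) {
      tg <- v[jn, , drop = FALSE] - v[ip, , drop = FALSE]
      len <- sqrt(rowSums(tg^2)); len[len == 0] <- 1
      # outward normal of a CCW contour (x/y orientation): (ty, -tx)
      force[, 1L] <- force[, 1L] + params$balloon * tg[, 2L] / len
      force[, 2L] <- force[, 2L] - params$balloon * tg[, 1L] / len
    }
    stepv <- params$step * force
    # cap per-vertex displacement at 1 px/iteration to prevent overshoot
    mag <- sqrt(rowSums(stepv^2))
    big <- mag > 1
    if (any(big)) stepv[big, ] <- stepv[big, ] / mag[big]
    vNew <- v + stepv
    nr <- nrow(S); nc <- ncol(S)
    vNew[, 1L] <- pmin(pmax(vNew[, 1L], 0), nc - 1L)
    vNew[, 2L] <- pmin(pmax(vNew[, 2L], 0), nr - 1L)
    disp <- mean(sqrt(rowSums((vNew - v)^2)))
    v <- vNew
    if (it %% params$resampleEvery == 0L)
      v <- resampleClosed(ensureCCW(v), spacing = params$resampleSpacing)
    if (disp < params$tolerance) { converged <- TRUE; break }
  }
  v <- resampleClosed(ensureCCW(v), spacing = params$resampleSpacing)
  if (.selfIntersects(v)) {
    v <- resampleClosed(v, spacing = 2 * params$resampleSpacing)
    if (.selfIntersects(v))
      stop("snake produced a self-intersecting contour for cell '",
           contour@cellId, "'")
  }
  if (!converged)
    warning("snake did not converge within ", params$maxIterations,
            " iterations for cell '", contour@cellId, "'")
  new("CellContour", vertices = v, cellId = contour@cellId,
      axisAngle = contour@axisAngle, converged = converged)
}

#' Rasterise a contour to a pixel mask
#'
#' A pixel belongs to the mask iff its center (at integer 0-based
#' coordinates) lies inside the polygon under the even-odd rule.
#'
#' @param contour A \code{CellContour} or two-column vertex matrix.
#' @param dim c(nrow, ncol) of the target canvas.
#' @return Logical matrix.
#' @export
contourToMask <- function(contour, dim) {
  v <- if (is(contour, "CellContour")) contour@vertices else contour
  if (any(v[, 1L] < -0.5 | v[, 1L] > dim[2L] - 0.5 |
          v[, 2L] < -0.5 | v[, 2L] > dim[1L] - 0.5))
    stop("contour vertices out of canvas bounds")
  cpp_rasterize_polygon(v[, 1L], v[, 2L], dim[1L], dim[2L])
}

#' Ground-truth bypass for segmentation
#'
#' Builds the \code{CellContour} directly from the planted truth so that
#' downstream quantification can be validated independently of snake
#' quality.
#'
#' @param truth A \code{GroundTruth}.
#' @param cellId Identifier for the contour.
#' @return A \code{CellContour}.
#' @export
segmentFromTruth <- function(truth, cellId = "cell") {
  new("CellContour", vertices = ensureCCW(truth@contour), cellId = cellId,
      axisAngle = truth@axisAngle)
}

#' Segment one cell with the snake
#'
#' Convenience wrapper: initialises a circle at \code{seedPoint} (inside
#' the cell) and evolves it with an inflating snake on the given channel.
#'
#' @param image Numeric matrix, background-zeroed.
#' @param seedPoint (x, y) inside the cell.
#' @param radius Initial circle radius, px.
#' @param params Snake parameters.
#' @param cellId,axisAngle Carried into the contour.
#' @return A \code{CellContour}.
#' @export
segmentCell <- function(image, seedPoint, radius, params = snakeParams(),
                        cellId = "cell", axisAngle = 0) {
  init <- initialiseContour(seedPoint, radius, cellId = cellId,
                            axisAngle = axisAngle)
  evolveSnake(image, init, params)
}
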