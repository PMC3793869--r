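#' @useDynLib CortexQuant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' The four within-cell domain labels
#'
#' Domains are defined by the diagonals of the cell's axis-oriented bounding
#' rectangle: \code{NSB} (pointing toward the notochord-somite boundary),
#' \code{ANTI} (opposite), and the two flanking domains \code{ANT} and
#' \code{POST}.
#'
#' @return Character vector of the four labels, in canonical order.
#' @export
domainLabels <- function() c("NSB", "ANTI", "ANT", "POST")

.POLARITY_CLASSES <- c("bipolar", "monopolar_toward", "monopolar_away",
                       "captured", "unpolarised")
.TISSUES <- c("notochord", "somite")

#' ImageField: a 2D multi-channel fluorescence image
#'
#' Container for one optical section. Channels are stored as a named list of
#' numeric matrices (row = image y, column = image x; pixel centers at 0-based
#' integer coordinates), with the physical pixel size and a channel-role map.
#'
#' @slot channels Named list of equal-dimension numeric matrices.
#' @slot pixelSize Pixel size in micrometres per pixel.
#' @slot channelRoles Named character vector mapping role (\code{"signal"},
#'   \code{"reference"}, ...) to channel name.
#' @slot metadata List of free-form metadata (seed, provenance).
#' @export
setClass("ImageField",
  representation(channels = "list", pixelSize = "numeric",
                 channelRoles = "character", metadata = "list"),
  prototype(metadata = list()))

setValidity("ImageField", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) < 1L) msg <- c(msg, "at least one channel required")
  if (is.null(names(ch)) || anyDuplicated(names(ch)))
    msg <- c(msg, "channels must be uniquely named")
  dims <- vapply(ch, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) > 1L) msg <- c(msg, "channel dimensions differ")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@channelRoles) &&
      !all(object@channelRoles %in% names(ch)))
    msg <- c(msg, "channelRoles must name existing channels")
  if (anyDuplicated(object@channelRoles))
    msg <- c(msg, "channel roles must map to distinct channels")
  if (length(msg)) msg else TRUE
})

#' CellGeometry: ground-truth geometry of one synthetic cell
#'
#' All coordinates are in micrometres in the cell's own frame (centroid near
#' the origin) unless placed on a field. The outline is a simple closed
#' polygon; the nucleus polygon lies strictly inside it; yolk platelets are
#' disks inside the outline and disjoint from the nucleus.
#'
#' @slot outline Two-column matrix (x, y) of outline vertices, micrometres.
#' @slot nucleus Two-column matrix of nucleus vertices.
#' @slot yolk Data frame with columns \code{x}, \code{y}, \code{r} (disks).
#' @slot axisAngle Radians; direction pointing toward the NSB.
#' @slot polarityClass One of bipolar, monopolar_toward, monopolar_away,
#'   captured, unpolarised.
#' @slot tissue \code{"notochord"} or \code{"somite"}.
#' @slot distanceToNSB Non-negative, in mean-cell-diameter units.
#' @slot meanDiameter Mean cell diameter (length + width)/2, micrometres.
#' @export
setClass("CellGeometry",
  representation(outline = "matrix", nucleus = "matrix", yolk = "data.frame",
                 axisAngle = "numeric", polarityClass = "character",
                 tissue = "character", distanceToNSB = "numeric",
                 meanDiameter = "numeric"))

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (ncol(object@outline) != 2L || nrow(object@outline) < 3L)
    msg <- c(msg, "outline must be an n x 2 matrix, n >= 3")
  if (!object@polarityClass %in% .POLARITY_CLASSES)
    msg <- c(msg, paste("polarityClass must be one of:",
                        paste(.POLARITY_CLASSES, collapse = ", ")))
  if (!object@tissue %in% .TISSUES)
    msg <- c(msg, "tissue must be 'notochord' or 'somite'")
  if (object@distanceToNSB < 0) msg <- c(msg, "distanceToNSB must be >= 0")
  if (nrow(object@yolk) && !all(c("x", "y", "r") %in% names(object@yolk)))
    msg <- c(msg, "yolk must have columns x, y, r")
  if (length(msg)) msg else TRUE
})

#' RenderSpec: how a synthetic cell is drawn
#'
#' Per-channel base intensities are expected photon counts per pixel on
#' yolk-free cytoplasm. The signal channel is multiplied by the per-domain
#' \code{corticalEnrichment} inside the cortical band and modulated by an
#' optional spatially correlated texture field (log-normal, mimicking
#' protein-pool inhomogeneity independent of the volume marker). Noise is
#' Poisson shot noise followed by additive Gaussian read noise and a constant
#' camera offset.
#'
#' @slot pixelSize Micrometres per pixel.
#' @slot baseIntensity Named numeric, photons per cytoplasm pixel per channel.
#' @slot nucleusFactor Named numeric multiplier per channel on the nucleus.
#' @slot yolkFactor Single multiplier applied to both channels on yolk disks.
#' @slot corticalEnrichment Named numeric over \code{domainLabels()}; signal
#'   channel multiplier within the cortical band.
#' @slot bandWidth Cortical band width in micrometres.
#' @slot punctaRate Named numeric over domains: expected cortical puncta count.
#' @slot punctaPerUm Expected cortical puncta per micrometre of contour,
#'   added on top of \code{punctaRate} with per-domain means proportional to
#'   arc length (a cortex-uniform spatial null).
#' @slot punctaAmplitude,punctaSigma Spot peak amplitude (photons) and
#'   Gaussian sigma (micrometres).
#' @slot noise List: \code{shot} (logical), \code{readSigma}, \code{offset},
#'   \code{textureCV}, \code{textureScale} (micrometres).
#' @slot seed Integer RNG seed (NA for no reseeding).
#' @export
setClass("RenderSpec",
  representation(pixelSize = "numeric", baseIntensity = "numeric",
                 nucleusFactor = "numeric", yolkFactor = "numeric",
                 corticalEnrichment = "numeric", bandWidth = "numeric",
                 punctaRate = "numeric", punctaPerUm = "numeric",
                 punctaAmplitude = "numeric",
                 punctaSigma = "numeric", noise = "list", seed = "numeric"))

setValidity("RenderSpec", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (any(object@baseIntensity < 0)) msg <- c(msg, "baseIntensity must be >= 0")
  if (any(object@nucleusFactor <= 0)) msg <- c(msg, "nucleusFactor must be > 0")
  if (object@yolkFactor < 0) msg <- c(msg, "yolkFactor must be >= 0")
  if (any(object@corticalEnrichment <= 0))
    msg <- c(msg, "corticalEnrichment multipliers must be > 0")
  if (!all(domainLabels() %in% names(object@corticalEnrichment)))
    msg <- c(msg, "corticalEnrichment must cover all four domains")
  if (object@bandWidth <= 0) msg <- c(msg, "bandWidth must be > 0")
  if (any(object@punctaRate < 0)) msg <- c(msg, "punctaRate must be >= 0")
  if (object@punctaPerUm < 0) msg <- c(msg, "punctaPerUm must be >= 0")
  need <- c("shot", "readSigma", "offset", "textureCV", "textureScale")
  if (!all(need %in% names(object@noise)))
    msg <- c(msg, paste("noise must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted truth accompanying a rendered cell
#'
#' @slot cellMask,nucleusMask,yolkMask,bandMask Logical matrices on the
#'   rendered canvas.
#' @slot domainLabelMap Integer matrix; 0 outside the cell, 1..4 indexing
#'   \code{domainLabels()} inside.
#' @slot truePuncta Data frame \code{x}, \code{y} (pixel coords),
#'   \code{domain}.
#' @slot plantedEnrichment The cortical enrichment mapping actually used.
#' @slot contour Two-column matrix: true outline in pixel coordinates.
#' @slot nucleusContour Two-column matrix: nucleus outline in pixel coords.
#' @slot axisAngle Radians toward the NSB (image frame).
#' @export
setClass("GroundTruth",
  representation(cellMask = "matrix", nucleusMask = "matrix",
                 yolkMask = "matrix", bandMask = "matrix",
                 domainLabelMap = "matrix", truePuncta = "data.frame",
                 plantedEnrichment = "numeric", contour = "matrix",
                 nucleusContour = "matrix", axisAngle = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(object@nucleusMask & !object@cellMask))
    msg <- c(msg, "nucleus mask must lie inside the cell mask")
  if (any(object@bandMask & !object@cellMask))
    msg <- c(msg, "band mask must lie inside the cell mask")
  if (any((object@domainLabelMap > 0) != object@cellMask))
    msg <- c(msg, "domain label map support must equal the cell mask")
  if (length(msg)) msg else TRUE
})

#' CellContour: closed polygon outlining one cell
#'
#' Vertices are stored counter-clockwise in pixel coordinates (x right,
#' y down in matrix row order; orientation is counter-clockwise in the x/y
#' sense used throughout, i.e. positive signed area).
#'
#' @slot vertices Two-column matrix (x, y), pixel coordinates, implicitly
#'   closed.
#' @slot cellId Character identifier.
#' @slot axisAngle Radians toward the NSB.
#' @slot converged Logical; FALSE if snake evolution hit maxIterations.
#' @export
setClass("CellContour",
  representation(vertices = "matrix", cellId = "character",
                 axisAngle = "numeric", converged = "logical"),
  prototype(cellId = "cell", axisAngle = 0, converged = TRUE))

setValidity("CellContour", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2L) msg <- c(msg, "vertices must be n x 2")
  if (nrow(object@vertices) < 3L) msg <- c(msg, "need >= 3 vertices")
  if (length(msg)) msg else TRUE
})

#' QuadrantPartition: the four-domain division of one cell
#'
#' @slot rectangle 4 x 2 matrix: corners of the axis-oriented bounding
#'   rectangle (pixel coordinates), in order (-u,-v), (+u,-v), (+u,+v),
#'   (-u,+v) where u is the NSB axis direction.
#' @slot center Rectangle center (x, y).
#' @slot axisAngle Radians toward the NSB.
#' @slot labelMap Integer matrix over the canvas: 0 outside the cell mask,
#'   1..4 indexing \code{domainLabels()}.
#' @slot arcLength Named numeric: contour length per domain, micrometres.
#' @slot pixelSize Micrometres per pixel.
#' @slot halfExtent Half side lengths (along axis, across axis) in pixels.
#' @export
setClass("QuadrantPartition",
  representation(rectangle = "matrix", center = "numeric",
                 axisAngle = "numeric", labelMap = "matrix",
                 arcLength = "numeric", pixelSize = "numeric",
                 halfExtent = "numeric"))

#' StatsResult: repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' @slot F F statistic of the within-cell domain effect.
#' @slot df1,df2 Uncorrected degrees of freedom (3 and 3(n-1) for 4 domains).
#' @slot epsilon Greenhouse-Geisser epsilon, in [1/3, 1] for 4 domains.
#' @slot pGG p-value at the corrected degrees of freedom.
#' @slot pUncorrected p-value at the uncorrected degrees of freedom.
#' @slot pairwise Data frame of the 6 Bonferroni-adjusted paired comparisons.
#' @slot n Number of cells.
#' @slot label Group label.
#' @export
setClass("StatsResult",
  representation(F = "numeric", df1 = "numeric", df2 = "numeric",
                 epsilon = "numeric", pGG = "numeric",
                 pUncorrected = "numeric", pairwise = "data.frame",
                 n = "integer", label = "character"))

setMethod("show", "ImageField", function(object) {
  d <- dim(object@channels[[1L]])
  cat("ImageField:", d[1L], "x", d[2L], "px,", length(object@channels),
      "channel(s) [", paste(names(object@channels), collapse = ", "),
      "], pixel size", object@pixelSize, "um\n")
  if (length(object@channelRoles))
    cat("  roles:", paste(names(object@channelRoles), "=",
                          object@channelRoles, collapse = ", "), "\n")
})

setMethod("show", "CellGeometry", function(object) {
  cat("CellGeometry:", object@polarityClass, "cell in", object@tissue,
      sprintf("(%.3g diameters from NSB)\n", object@distanceToNSB))
  cat(" ", nrow(object@outline), "outline vertices,", nrow(object@yolk),
      "yolk platelets, axis", sprintf("%.2f rad\n", object@axisAngle))
})

setMethod("show", "CellContour", function(object) {
  cat("CellContour", object@cellId, ":", nrow(object@vertices),
      "vertices, area", sprintf("%.1f px^2", polygonArea(object@vertices)),
      if (!object@converged) "(snake not converged)" else "", "\n")
})

setMethod("show", "QuadrantPartition", function(object) {
  cat("QuadrantPartition: center (",
      paste(sprintf("%.1f", object@center), collapse = ", "),
      "), axis", sprintf("%.2f rad\n", object@axisAngle))
  print(round(object@arcLength, 2))
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf(
    "RM-ANOVA (%s, n=%d): F(%.0f,%.0f)=%.3f, GG eps=%.3f, p_GG=%.4g\n",
    object@label, object@n, object@df1, object@df2, object@F,
    object@epsilon, object@pGG))
  print(object@pairwise, digits = 4)
})

#' @describeIn ImageField-class Extract a channel matrix by name or role.
#' @param x An \code{ImageField}.
#' @param which Channel name, or role name present in \code{channelRoles}.
#' @export
getChannel <- function(x, which) {
  stopifnot(is(x, "ImageField"))
  if (which %in% names(x@channelRoles)) which <- x@channelRoles[[which]]
  if (!which %in% names(x@channels))
    stop("no channel or role named '", which, "'")
  x@channels[[which]]
}

#' Pixel size accessor
#' @param x An \code{ImageField}.
#' @return Pixel size in micrometres per pixel.
#' @export
pixelSize <- function(x) x@pixelSize

#' Contour vertex accessor
#' @param x A \code{CellContour}.
#' @return Two-column matrix of (x, y) vertices.
#' @export
contourVertices <- function(x) x@vertices

#' Domain arc-length accessor
#' @param x A \code{QuadrantPartition}.
#' @return Named numeric vector, micrometres per domain.
#' @export
arcLengths <- function(x) x@arcLength
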