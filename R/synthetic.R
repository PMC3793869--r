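# Synthetic two-channel cell images with full ground truth, emulating
# mosaic-labelled gastrula chordamesoderm cells in a single optical section:
# an elongated cell with protrusive ends, signal-excluding yolk platelets, a
# dextran-marked nucleus, an optional planted cortical enrichment of the
# signal channel per domain, optional cortical puncta, and confocal noise
# (Poisson shot noise + Gaussian read noise + constant offset).

#' Default shape parameters for synthetic cells
#'
#' Dimensions follow mid-gastrula chordamesoderm cells: roughly 40 x 20 um,
#' mediolaterally elongated, with large smooth protrusions at one or both
#' ends depending on polarity class, a ~10 x 8 um nucleus and a dozen yolk
#' platelets of 1-2 um radius.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of shape parameters.
#' @export
shapeParams <- function(...) {
  p <- list(
    length = 40, width = 20,          # um
    protrusionAmp = 0.35,             # fractional radial bump at cell ends
    protrusionWidth = 0.7,            # angular half-width of a bump, rad
    irregularity = 0.05,              # low-order radial roughness
    nVertices = 160L,
    nucleusSemiAxes = c(5, 4),        # um
    yolkCount = 12L,
    yolkRadius = c(1.0, 2.2),         # um
    margin = 0.8)                     # clearance of yolk from boundary, um
  p[names(list(...))] <- list(...)
  p
}

# radial bump centred at angle th0
.bump <- function(theta, th0, width, amp) {
  d <- atan2(sin(theta - th0), cos(theta - th0))
  ifelse(abs(d) < width, amp * cos(pi * d / (2 * width))^2, 0)
}

#' Generate the geometry of one synthetic cell
#'
#' The outline is a radial (star-shaped, hence simple) polygon: an ellipse
#' of the requested length and width carrying smooth cosine protrusion bumps
#' at the end(s) dictated by the polarity class, plus low-order random
#' roughness. The nucleus is an inner ellipse; yolk platelets are disks
#' packed by rejection sampling inside the outline and away from the
#' nucleus.
#'
#' @param class Polarity class: \code{"bipolar"}, \code{"monopolar_toward"},
#'   \code{"monopolar_away"}, \code{"captured"} or \code{"unpolarised"}.
#' @param tissue \code{"notochord"} or \code{"somite"}.
#' @param distance Distance to the NSB in mean-cell-diameter units.
#' @param params Shape parameters, see \code{\link{shapeParams}}.
#' @param axisAngle Direction toward the NSB, radians (cell frame is
#'   rotated so that protrusions point along this axis).
#' @param seed Integer seed; the caller's RNG stream is untouched. \code{NA}
#'   draws from the current stream.
#' @return A \code{CellGeometry} (coordinates in micrometres, centred).
#' @export
generateCellGeometry <- function(class = "bipolar", tissue = "notochord",
                                 distance = 1, params = shapeParams(),
                                 axisAngle = 0, seed = NA) {
  withSeed(seed, {
    a <- params$length / 2; b <- params$width / 2
    nv <- as.integer(params$nVertices)
    theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    rEll <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    amp <- params$protrusionAmp; w <- params$protrusionWidth
    bump <- switch(class,
      bipolar = .bump(theta, 0, w, amp) + .bump(theta, pi, w, amp),
      monopolar_toward = .bump(theta, 0, w, amp),
      monopolar_away = .bump(theta, pi, w, amp),
      captured = , unpolarised = rep(0, nv))
    rough <- rep(0, nv)
    if (params$irregularity > 0) {
      for (k in 2:6) {
        rough <- rough + stats::rnorm(1L, 0, params$irregularity / k) *
          cos(k * theta + stats::runif(1L, 0, 2 * pi))
      }
    }
    r <- rEll * pmax(1 + bump + rough, 0.2)
    outline <- cbind(r * cos(theta + axisAngle), r * sin(theta + axisAngle))

    # nucleus: inner ellipse, small random offset and tilt, strictly inside
    nuc <- NULL
    na_ <- params$nucleusSemiAxes[1L]; nb <- params$nucleusSemiAxes[2L]
    phiN <- stats::runif(1L, 0, pi)
    off <- c(stats::runif(1L, -0.12, 0.12) * a,
             stats::runif(1L, -0.2, 0.2) * b)
    tn <- seq(0, 2 * pi, length.out = 49L)[-49L]
    for (shrink in c(1, 0.9, 0.8, 0.7)) {
      cand <- cbind(shrink * na_ * cos(tn), shrink * nb * sin(tn))
      cand <- cbind(cand[, 1L] * cos(phiN) - cand[, 2L] * sin(phiN),
                    cand[, 1L] * sin(phiN) + cand[, 2L] * cos(phiN))
      cand <- sweep(cand, 2L, off * shrink, "+")
      if (all(pointInPolygon(cand, outline)) &&
          min(distToPolygon(cand, outline)) > 0.5) { nuc <- cand; break }
    }
    if (is.null(nuc))
      stop("could not place nucleus inside the outline")

    # yolk platelets: disks inside the outline, clear of the nucleus
    ny <- as.integer(params$yolkCount)
    yolk <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    if (ny > 0L) {
      placed <- 0L; tries <- 0L; maxTries <- 400L * ny
      xs <- ys <- rs <- numeric(ny)
      while (placed < ny) {
        tries <- tries + 1L
        if (tries > maxTries)
          stop("infeasible yolk packing: placed ", placed, " of ", ny,
               " disks after ", maxTries, " attempts")
        rr <- stats::runif(1L, params$yolkRadius[1L], params$yolkRadius[2L])
        cx <- stats::runif(1L, -a, a); cy <- stats::runif(1L, -b, b)
        p <- cbind(cx * cos(axisAngle) - cy * sin(axisAngle),
                   cx * sin(axisAngle) + cy * cos(axisAngle))
        if (!pointInPolygon(p, outline)) next
        if (distToPolygon(p, outline) < rr + params$margin) next
        if (pointInPolygon(p, nuc) || distToPolygon(p, nuc) < rr + 0.3) next
        placed <- placed + 1L
        xs[placed] <- p[1L]; ys[placed] <- p[2L]; rs[placed] <- rr
      }
      yolk <- data.frame(x = xs, y = ys, r = rs)
    }
    new("CellGeometry", outline = outline, nucleus = nuc, yolk = yolk,
        axisAngle = axisAngle, polarityClass = class, tissue = tissue,
        distanceToNSB = distance,
        meanDiameter = (params$length + params$width) / 2)
  })
}

#' Construct a render specification
#'
#' Defaults emulate the acquisition regime of the emulated experiments:
#' photon-limited confocal imaging with no saturated pixels and background
#' that can be zeroed exactly (constant camera offset), plus a spatially
#' correlated log-normal texture on the signal channel representing
#' protein-pool inhomogeneity that the volume marker does not share.
#'
#' @param pixelSize um/px (default 0.25, a typical 63x confocal sampling).
#' @param baseIntensity Named photons/px on cytoplasm for \code{signal} and
#'   \code{reference}.
#' @param nucleusFactor Per-channel nuclear multiplier. The reference
#'   (dextran) default is > 1 so the nucleus is dextran-marked; the level is
#'   a free parameter of the model.
#' @param yolkFactor Intensity multiplier on yolk platelets (0 = hard
#'   exclusion of both channels).
#' @param corticalEnrichment Named per-domain multiplier applied to the
#'   signal channel inside the cortical band (all 1 = no planted polarity).
#' @param bandWidth Cortical band width used when planting enrichment and
#'   puncta, um.
#' @param punctaRate Named per-domain expected cortical puncta count.
#' @param punctaPerUm Expected cortical puncta per micrometre of contour;
#'   per-domain means are proportional to domain arc length, the
#'   cortex-uniform null of the puncta analysis (0 disables).
#' @param punctaAmplitude,punctaSigma Spot peak (photons) and sigma (um).
#' @param shot,readSigma,offset Shot-noise switch, Gaussian read-noise sigma
#'   and constant background offset.
#' @param textureCV,textureScale Coefficient of variation and correlation
#'   scale (um) of the signal-channel texture field (0 disables).
#' @param seed Integer seed for rendering randomness (NA = current stream).
#' @return A \code{RenderSpec}.
#' @export
renderSpec <- function(pixelSize = 0.25,
                       baseIntensity = c(signal = 60, reference = 80),
                       nucleusFactor = c(signal = 0.7, reference = 1.3),
                       yolkFactor = 0,
                       corticalEnrichment = c(NSB = 1, ANTI = 1,
                                              ANT = 1, POST = 1),
                       bandWidth = 5,
                       punctaRate = c(NSB = 0, ANTI = 0, ANT = 0, POST = 0),
                       punctaPerUm = 0,
                       punctaAmplitude = 150, punctaSigma = 0.5,
                       shot = TRUE, readSigma = 2, offset = 4,
                       textureCV = 0.15, textureScale = 3,
                       seed = NA) {
  new("RenderSpec", pixelSize = pixelSize, baseIntensity = baseIntensity,
      nucleusFactor = nucleusFactor, yolkFactor = yolkFactor,
      corticalEnrichment = corticalEnrichment[domainLabels()],
      bandWidth = bandWidth, punctaRate = punctaRate[domainLabels()],
      punctaPerUm = punctaPerUm,
      punctaAmplitude = punctaAmplitude, punctaSigma = punctaSigma,
      noise = list(shot = shot, readSigma = readSigma, offset = offset,
                   textureCV = textureCV, textureScale = textureScale),
      seed = as.numeric(seed))
}

# log-normal multiplicative texture with unit mean, sd ~ cv, correlation
# scale given in pixels; the smooth field is synthesised on a coarse grid
# and bilinearly upsampled (indistinguishable for scales >> 1 px)
.textureField <- function(nrow, ncol, scalePx, cv) {
  f <- max(1L, floor(scalePx / 1.5))
  nrc <- ceiling(nrow / f) + 2L; ncc <- ceiling(ncol / f) + 2L
  g <- matrix(stats::rnorm(nrc * ncc), nrc, ncc)
  g <- .gauss2d(g, scalePx / f)
  if (f > 1L) {
    gx <- (seq_len(ncol) - 1) / f; gy <- (seq_len(nrow) - 1) / f
    g <- matrix(.bilinear(g, rep(gx, each = nrow), rep(gy, times = ncol)),
                nrow, ncol)
  }
  s <- stats::sd(g)
  if (s < .Machine$double.eps) return(matrix(1, nrow, ncol))
  g <- g / s
  exp(cv * g - cv^2 / 2)
}

.rasterDisks <- function(nrow, ncol, disks, pixelSize, origin) {
  m <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(nrow(disks))) {
    cx <- (disks$x[i] - origin[1L]) / pixelSize
    cy <- (disks$y[i] - origin[2L]) / pixelSize
    r <- disks$r[i] / pixelSize
    x0 <- max(0L, floor(cx - r)); x1 <- min(ncol - 1L, ceiling(cx + r))
    y0 <- max(0L, floor(cy - r)); y1 <- min(nrow - 1L, ceiling(cy + r))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    m[ys + 1L, xs + 1L] <- m[ys + 1L, xs + 1L] | dd
  }
  m
}

#' Render a synthetic cell into a two-channel image with ground truth
#'
#' Both channels share the same yolk-excluded cytoplasmic support (the null
#' structure of a volume marker); polarised signal is introduced only via
#' \code{corticalEnrichment} and puncta in the render spec. Expectations are
#' built per pixel, then shot noise, read noise and the constant offset are
#' applied (in that order) and negative values clipped at zero.
#'
#' @param geometry A \code{CellGeometry}.
#' @param spec A \code{RenderSpec}.
#' @param marginUm Canvas margin around the outline, um.
#' @param canvasDim Optional c(nrow, ncol) canvas override; an error is
#'   raised if the geometry does not fit.
#' @return List with elements \code{image} (an \code{ImageField}) and
#'   \code{truth} (a \code{GroundTruth}).
#' @export
renderCell <- function(geometry, spec, marginUm = 4, canvasDim = NULL) {
  validObject(spec)
  ps <- spec@pixelSize
  bb <- apply(geometry@outline, 2L, range)
  origin <- bb[1L, ] - marginUm
  need <- ceiling((bb[2L, ] - origin + marginUm) / ps) + 1L
  ncol_ <- need[1L]; nrow_ <- need[2L]
  if (!is.null(canvasDim)) {
    if (canvasDim[1L] < nrow_ || canvasDim[2L] < ncol_)
      stop(sprintf("canvas too small: need at least %d x %d", nrow_, ncol_))
    nrow_ <- canvasDim[1L]; ncol_ <- canvasDim[2L]
  }
  outPx <- sweep(geometry@outline, 2L, origin) / ps
  nucPx <- sweep(geometry@nucleus, 2L, origin) / ps

  cellMask <- cpp_rasterize_polygon(outPx[, 1L], outPx[, 2L], nrow_, ncol_)
  nucMask <- cpp_rasterize_polygon(nucPx[, 1L], nucPx[, 2L], nrow_, ncol_)
  nucMask <- nucMask & cellMask
  yolkMask <- .rasterDisks(nrow_, ncol_, geometry@yolk, ps, origin) & cellMask

  contour <- new("CellContour", vertices = ensureCCW(outPx),
                 cellId = "truth", axisAngle = geometry@axisAngle)
  part <- partitionQuadrants(contour, cellMask, pixelSize = ps)

  bandMask <- cpp_band_mask(outPx[, 1L], outPx[, 2L], nrow_, ncol_,
                            spec@bandWidth / ps) & cellMask

  withSeed(spec@seed, {
    chans <- list()
    truePuncta <- data.frame(x = numeric(0), y = numeric(0),
                             domain = character(0))
    noise <- spec@noise
    for (ch in names(spec@baseIntensity)) {
      fac <- matrix(0, nrow_, ncol_)
      fac[cellMask] <- 1
      fac[yolkMask] <- spec@yolkFactor
      fac[nucMask] <- spec@nucleusFactor[[ch]]
      E <- spec@baseIntensity[[ch]] * fac
      if (ch == "signal") {
        enr <- spec@corticalEnrichment
        if (any(enr != 1)) {
          sel <- bandMask & !nucMask & !yolkMask
          E[sel] <- E[sel] * enr[part@labelMap[sel]]
        }
        if (noise$textureCV > 0) {
          tex <- .textureField(nrow_, ncol_, noise$textureScale / ps,
                               noise$textureCV)
          E[cellMask] <- E[cellMask] * tex[cellMask]
        }
        rates <- spec@punctaRate + spec@punctaPerUm * part@arcLength
        if (any(rates > 0)) {
          # plant only where the full 3x3 neighbourhood stays in the band,
          # so a punctum's centroid pixel is cortical even after sub-pixel
          # jitter
          inner <- bandMask
          inner[] <- FALSE
          inner[2:(nrow_ - 1L), 2:(ncol_ - 1L)] <-
            bandMask[2:(nrow_ - 1L), 2:(ncol_ - 1L)] &
            bandMask[1:(nrow_ - 2L), 2:(ncol_ - 1L)] &
            bandMask[3:nrow_, 2:(ncol_ - 1L)] &
            bandMask[2:(nrow_ - 1L), 1:(ncol_ - 2L)] &
            bandMask[2:(nrow_ - 1L), 3:ncol_] &
            bandMask[1:(nrow_ - 2L), 1:(ncol_ - 2L)] &
            bandMask[1:(nrow_ - 2L), 3:ncol_] &
            bandMask[3:nrow_, 1:(ncol_ - 2L)] &
            bandMask[3:nrow_, 3:ncol_]
          for (d in 1:4) {
            lam <- rates[[d]]
            if (lam <= 0) next
            cand <- which(inner & part@labelMap == d)
            if (!length(cand)) cand <- which(bandMask & part@labelMap == d)
            if (!length(cand)) next
            np <- stats::rpois(1L, lam)
            if (np == 0L) next
            pick <- cand[sample.int(length(cand), np, replace = TRUE)]
            sx <- (pick - 1L) %/% nrow_ + stats::runif(np, -0.5, 0.5)
            sy <- (pick - 1L) %% nrow_ + stats::runif(np, -0.5, 0.5)
            E <- cpp_add_gaussian_spots(E, sx, sy,
                   rep(spec@punctaAmplitude, np),
                   rep(spec@punctaSigma / ps, np))
            truePuncta <- rbind(truePuncta,
              data.frame(x = sx, y = sy, domain = domainLabels()[d]))
          }
        }
      }
      img <- if (isTRUE(noise$shot)) {
        matrix(stats::rpois(length(E), E), nrow_, ncol_)
      } else E
      if (noise$readSigma > 0)
        img <- img + matrix(stats::rnorm(length(E), 0, noise$readSigma),
                            nrow_, ncol_)
      img <- img + noise$offset
      chans[[ch]] <- pmax(img, 0)
    }
    image <- new("ImageField", channels = chans, pixelSize = ps,
                 channelRoles = c(signal = "signal", reference = "reference"),
                 metadata = list(origin_um = origin, seed = spec@seed))
    truth <- new("GroundTruth", cellMask = cellMask, nucleusMask = nucMask,
                 yolkMask = yolkMask, bandMask = bandMask,
                 domainLabelMap = part@labelMap, truePuncta = truePuncta,
                 plantedEnrichment = spec@corticalEnrichment,
                 contour = contour@vertices, nucleusContour = ensureCCW(nucPx),
                 axisAngle = geometry@axisAngle)
    list(image = image, truth = truth)
  })
}

#' SyntheticField: a simulated mosaic of labelled cells
#'
#' Cells are isolated (non-abutting) as in mosaic expression, each rendered
#' on its own tile; the annotation table records class, tissue, axis angle
#' and the distance from the cell centroid to the NSB line in mean-diameter
#' units.
#'
#' @slot cells List of per-cell lists (\code{image}, \code{truth},
#'   \code{geometry}).
#' @slot annotations Data frame, one row per cell.
#' @slot nsbX Field x-coordinate (um) of the vertical NSB line.
#' @slot seed Seed used for generation.
#' @export
setClass("SyntheticField",
  representation(cells = "list", annotations = "data.frame",
                 nsbX = "numeric", seed = "numeric"))

setMethod("show", "SyntheticField", function(object) {
  cat("SyntheticField:", length(object@cells), "cells, NSB line at x =",
      object@nsbX, "um\n")
  print(table(object@annotations$class))
})

#' Annotation table of a synthetic field
#' @param x A \code{SyntheticField}.
#' @return Data frame with one row per cell.
#' @export
annotations <- function(x) x@annotations

#' Access one cell of a synthetic field
#' @param x A \code{SyntheticField}.
#' @param i Cell index.
#' @return \code{fieldCell}: list with \code{image}, \code{truth},
#'   \code{geometry}.
#' @export
fieldCell <- function(x, i) x@cells[[i]]

#' Generate a field of synthetic cells at controlled NSB distances
#'
#' The NSB is modelled as a vertical line at field coordinate
#' \code{nsbX = 0}; cells are stacked at non-overlapping vertical positions
#' with centroids placed exactly \code{distance * meanDiameter} um from the
#' line, axes pointing toward it (plus a small jitter).
#'
#' @param nCells Number of cells (>= 1).
#' @param mix Named proportions over polarity classes (must sum to 1).
#' @param spec A \code{RenderSpec}; its \code{seed} slot is ignored in
#'   favour of \code{seed}.
#' @param distances Distances (diameters) to draw from, or a length-
#'   \code{nCells} vector used as-is.
#' @param tissue Tissue label for all cells, or per-cell vector.
#' @param params Shape parameters.
#' @param axisJitter Half-range of uniform jitter on the axis angle, rad.
#' @param enrichmentByClass Optional named list: per-class cortical
#'   enrichment override (e.g. plant enrichment only in "toward" classes).
#' @param enrichmentByDistanceBin Optional list with \code{edges} (c(2, 5))
#'   and \code{enrichment} (list of per-domain mappings per bin).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A \code{SyntheticField}.
#' @export
generateField <- function(nCells, mix = c(bipolar = 1), spec = renderSpec(),
                          distances = c(1, 2, 3, 4, 5, 6),
                          tissue = "notochord", params = shapeParams(),
                          axisJitter = 0.15, enrichmentByClass = NULL,
                          enrichmentByDistanceBin = NULL, seed = NA) {
  stopifnot(nCells >= 1)
  if (abs(sum(mix) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (!all(names(mix) %in% .POLARITY_CLASSES))
    stop("unknown polarity class in mix")
  withSeed(seed, {
    classes <- sample(names(mix), nCells, replace = TRUE, prob = mix)
    dist <- if (length(distances) == nCells) distances else
      sample(distances, nCells, replace = TRUE)
    tiss <- rep_len(tissue, nCells)
    D <- (params$length + params$width) / 2
    ySpacing <- params$width + 8
    cells <- vector("list", nCells)
    ann <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      ang <- pi + stats::runif(1L, -axisJitter, axisJitter)
      geom <- generateCellGeometry(classes[i], tiss[i], dist[i], params,
                                   axisAngle = ang, seed = NA)
      specI <- spec
      specI@seed <- NA_real_
      if (!is.null(enrichmentByClass) &&
          classes[i] %in% names(enrichmentByClass))
        specI@corticalEnrichment <-
          enrichmentByClass[[classes[i]]][domainLabels()]
      if (!is.null(enrichmentByDistanceBin)) {
        bin <- findInterval(dist[i], enrichmentByDistanceBin$edges,
                            left.open = TRUE) + 1L
        specI@corticalEnrichment <-
          enrichmentByDistanceBin$enrichment[[bin]][domainLabels()]
      }
      cells[[i]] <- c(renderCell(geom, specI), list(geometry = geom))
      cx <- dist[i] * D
      cy <- (i - 1) * ySpacing
      ann[[i]] <- data.frame(
        cell_id = sprintf("cell_%03d", i), class = classes[i],
        tissue = tiss[i], distance = dist[i], axis_angle = ang,
        centroid_x = cx, centroid_y = cy, stringsAsFactors = FALSE)
    }
    new("SyntheticField", cells = cells, annotations = do.call(rbind, ann),
        nsbX = 0, seed = as.numeric(seed))
  })
}
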