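# Punctum detection and per-domain cortical density. Bright spots are found
# by multiscale scale-normalised Laplacian-of-Gaussian filtering with an
# adaptive (intensity-rescaling-invariant) threshold, greedy non-maximum
# suppression, and sub-pixel peak refinement. Puncta whose centroid lies in
# the cortical band are counted per domain and normalised to the domain's
# contour arc length.

#' Puncta detection parameters
#'
#' @param sigmas Blob scales to probe, px.
#' @param nmad Detection threshold in robust (MAD) units of the LoG
#'   response inside the mask; relative, so detection is invariant to
#'   intensity rescaling.
#' @param minSeparation Non-maximum suppression radius as a multiple of the
#'   detected scale.
#' @return Named list.
#' @export
punctaParams <- function(sigmas = c(1.4, 2, 2.8), nmad = 10,
                         minSeparation = 2) {
  list(sigmas = sigmas, nmad = nmad, minSeparation = minSeparation)
}

.logKernel <- function(sigma) {
  r <- max(3L, ceiling(4 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g, g)
  X2 <- outer(x^2, x^2, "+")
  K <- ((X2 - 2 * sigma^2) / sigma^4) * G
  K - mean(K)   # zero-sum: flat regions give zero response
}

# sub-pixel 1D parabolic peak refinement
.parabolic <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (lo - hi) / den))
}

#' Detect bright puncta in a single channel
#'
#' @param image Numeric matrix (background-zeroed).
#' @param mask Logical matrix restricting the search (e.g. the cell mask).
#' @param params See \code{\link{punctaParams}}.
#' @param cellId Identifier copied to the output.
#' @return Data frame, one row per punctum: \code{cell_id}, \code{x},
#'   \code{y} (pixel coordinates, sub-pixel), \code{scale} (sigma, px),
#'   \code{peak} (image intensity at the peak), \code{response}
#'   (scale-normalised LoG response).
#' @export
detectPuncta <- function(image, mask, params = punctaParams(),
                         cellId = "cell") {
  empty <- data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
                      scale = numeric(0), peak = numeric(0),
                      response = numeric(0), stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  sig <- params$sigmas
  resp <- lapply(sig, function(s) -s^2 * .filter2d(image, .logKernel(s)))
  nr <- nrow(image); nc <- ncol(image)
  inner <- matrix(FALSE, nr, nc)
  inner[2:(nr - 1L), 2:(nc - 1L)] <- TRUE
  cand <- list()
  allResp <- unlist(lapply(resp, function(r) r[mask]))
  scaleMad <- stats::mad(allResp)
  thr <- params$nmad * scaleMad
  for (k in seq_along(sig)) {
    r <- resp[[k]]
    ok <- mask & inner & r > thr & r > 0
    idx <- which(ok)
    if (!length(idx)) next
    y <- (idx - 1L) %% nr + 1L; x <- (idx - 1L) %/% nr + 1L
    val <- r[idx]
    isMax <- val >= r[cbind(y - 1L, x)] & val >= r[cbind(y + 1L, x)] &
      val >= r[cbind(y, x - 1L)] & val >= r[cbind(y, x + 1L)] &
      val >= r[cbind(y - 1L, x - 1L)] & val >= r[cbind(y - 1L, x + 1L)] &
      val >= r[cbind(y + 1L, x - 1L)] & val >= r[cbind(y + 1L, x + 1L)]
    if (k > 1L) isMax <- isMax & val >= resp[[k - 1L]][idx]
    if (k < length(sig)) isMax <- isMax & val >= resp[[k + 1L]][idx]
    if (!any(isMax)) next
    cand[[length(cand) + 1L]] <- data.frame(
      x = x[isMax] - 1L, y = y[isMax] - 1L, scale = sig[k],
      response = val[isMax])
  }
  if (!length(cand)) return(empty)
  det <- do.call(rbind, cand)
  det <- det[order(-det$response), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- det[keep, , drop = FALSE]
    dd <- sqrt((prev$x - det$x[i])^2 + (prev$y - det$y[i])^2)
    lim <- params$minSeparation * pmax(prev$scale, det$scale[i])
    keep[i] <- all(dd >= lim)
  }
  det <- det[keep, , drop = FALSE]
  # sub-pixel refinement on the response surface at the detected scale
  for (i in seq_len(nrow(det))) {
    r <- resp[[match(det$scale[i], sig)]]
    xi <- det$x[i] + 1L; yi <- det$y[i] + 1L
    if (xi > 1L && xi < nc)
      det$x[i] <- det$x[i] + .parabolic(r[yi, xi - 1L], r[yi, xi], r[yi, xi + 1L])
    if (yi > 1L && yi < nr)
      det$y[i] <- det$y[i] + .parabolic(r[yi - 1L, xi], r[yi, xi], r[yi + 1L, xi])
  }
  det$peak <- .bilinear(image, det$x, det$y)
  data.frame(cell_id = cellId, det[, c("x", "y", "scale", "peak", "response")],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify puncta as cortical
#'
#' A punctum is cortical iff the pixel containing its centroid lies inside
#' the cortical band.
#'
#' @param puncta Data frame from \code{\link{detectPuncta}}.
#' @param band Logical cortical-band mask.
#' @return The puncta table with an \code{is_cortical} column added.
#' @export
classifyCortical <- function(puncta, band) {
  if (!nrow(puncta)) {
    puncta$is_cortical <- logical(0)
    return(puncta)
  }
  xi <- pmin(pmax(round(puncta$x), 0), ncol(band) - 1L)
  yi <- pmin(pmax(round(puncta$y), 0), nrow(band) - 1L)
  puncta$is_cortical <- band[cbind(yi + 1L, xi + 1L)]
  puncta
}

#' Per-domain cortical puncta density
#'
#' Cortical puncta are assigned to quadrant domains by
#' \code{\link{assignPointToDomain}} and counts are normalised to the
#' domain's contour arc length.
#'
#' @param puncta Puncta table with \code{is_cortical} set.
#' @param partition A \code{QuadrantPartition} (provides arc lengths, um).
#' @param cellId Identifier for the output rows.
#' @return Data frame, one row per domain: \code{cell_id}, \code{domain},
#'   \code{count}, \code{arc_length_um}, \code{density} (counts per um;
#'   \code{NA} with a warning where the arc length is zero).
#' @export
punctaDensity <- function(puncta, partition, cellId = "cell") {
  cort <- puncta[isTRUE_v(puncta$is_cortical), , drop = FALSE]
  counts <- setNames(integer(4L), domainLabels())
  if (nrow(cort)) {
    dom <- assignPointToDomain(cbind(cort$x, cort$y), partition)
    tab <- table(factor(dom, levels = domainLabels()))
    counts[] <- as.integer(tab)
  }
  arc <- partition@arcLength[domainLabels()]
  dens <- ifelse(arc > 0, counts / arc, NA_real_)
  if (any(arc <= 0)) warning("zero arc length; density undefined there")
  data.frame(cell_id = cellId, domain = domainLabels(),
             count = as.integer(counts), arc_length_um = as.numeric(arc),
             density = as.numeric(dens), stringsAsFactors = FALSE,
             row.names = NULL)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Group summary of puncta densities
#'
#' @param densities Rows from \code{\link{punctaDensity}} over several
#'   cells.
#' @return Per-domain data frame with n, mean density, SEM and
#'   \code{two_sem} = 2 x SEM (the error bars used for puncta panels).
#' @export
punctaSummary <- function(densities) {
  out <- do.call(rbind, lapply(domainLabels(), function(d) {
    x <- densities$density[densities$domain == d]
    x <- x[is.finite(x)]
    sem <- stats::sd(x) / sqrt(length(x))
    data.frame(domain = d, n = length(x), mean = mean(x), sem = sem,
               two_sem = 2 * sem, stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
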