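# Ratiometric fractional-fluorescence quantification. The primary statistic
# is, per domain, the ratio of the signal channel's fractional fluorescence
# to the reference channel's fractional fluorescence (domain sum divided by
# the nucleus-excluded cell total) -- invariant to the overall expression
# level of either marker. Measurements can be taken over the whole cell or
# restricted to the cortical band.

#' Zero the image background
#'
#' Subtracts, per channel, the mean intensity of a background region (or a
#' supplied scalar offset) and clips at zero, mirroring acquisition in which
#' all background is zeroed.
#'
#' @param image An \code{ImageField}.
#' @param background Logical matrix marking background pixels (disjoint from
#'   labelled cells), or a single numeric offset, or a named numeric offset
#'   per channel.
#' @return The background-zeroed \code{ImageField}.
#' @export
zeroBackground <- function(image, background) {
  stopifnot(is(image, "ImageField"))
  ch <- image@channels
  if (is.matrix(background)) {
    if (!any(background)) stop("empty background region")
    off <- vapply(ch, function(m) mean(m[background]), numeric(1L))
  } else {
    off <- if (length(background) == 1L)
      setNames(rep(background, length(ch)), names(ch))
    else background[names(ch)]
  }
  image@channels <- lapply(names(ch), function(nm) pmax(ch[[nm]] - off[[nm]], 0))
  names(image@channels) <- names(ch)
  image@metadata$background_offset <- off
  image
}

#' Cortical band mask
#'
#' The band is the set of cell pixels whose Euclidean distance to the
#' contour polygon (sub-pixel, not to the rasterised mask edge) is at most
#' \code{widthUm}.
#'
#' @param mask Logical cell mask.
#' @param contour A \code{CellContour} in pixel coordinates.
#' @param widthUm Band width, micrometres (default 5).
#' @param pixelSize Micrometres per pixel.
#' @return Logical matrix, a subset of \code{mask}. If the width reaches the
#'   inradius the band equals the whole mask and a warning is raised.
#' @export
corticalBand <- function(mask, contour, widthUm = 5, pixelSize = 1) {
  stopifnot(widthUm > 0)
  v <- if (is(contour, "CellContour")) contour@vertices else contour
  if (!any(mask)) return(mask & FALSE)
  band <- cpp_band_mask(v[, 1L], v[, 2L], nrow(mask), ncol(mask),
                        widthUm / pixelSize) & mask
  if (all(band == mask))
    warning("band width >= cell inradius: band equals the whole cell")
  band
}

#' Per-domain fluorescence measurement of one cell
#'
#' For each domain and channel, sums intensity over (region intersect
#' domain) minus the nucleus, converts to fractional fluorescence (domain
#' sum / sum over the four domains) and forms the per-domain ratio of
#' signal fraction to reference fraction. Ratios are formed at domain level
#' (sums first), never pixelwise.
#'
#' @param image An \code{ImageField} (background-zeroed).
#' @param partition A \code{QuadrantPartition} for this cell.
#' @param mask Logical cell mask.
#' @param nucleusMask Logical nucleus mask (excluded from all sums).
#' @param region \code{"whole_cell"} or \code{"cortex"}.
#' @param band Cortical band mask (required when \code{region = "cortex"}).
#' @param cellId Cell identifier for the output rows.
#' @return Data frame with one row per domain x channel: \code{cell_id},
#'   \code{region}, \code{domain}, \code{channel}, \code{sum},
#'   \code{fraction}, \code{ratio} (signal fraction / reference fraction,
#'   repeated on both channel rows of a domain; \code{NA} where undefined).
#' @export
domainFluorescence <- function(image, partition, mask, nucleusMask = NULL,
                               region = c("whole_cell", "cortex"),
                               band = NULL, cellId = "cell") {
  region <- match.arg(region)
  if (region == "cortex") {
    if (is.null(band)) stop("cortex region requires a band mask")
    reg <- mask & band
  } else reg <- mask
  if (!is.null(nucleusMask)) reg <- reg & !nucleusMask
  lab <- partition@labelMap
  chn <- names(image@channels)
  sums <- sapply(chn, function(nm) {
    m <- image@channels[[nm]]
    vapply(1:4, function(d) sum(m[reg & lab == d]), numeric(1L))
  })                                     # 4 x nchannel
  fractions <- apply(sums, 2L, function(s) {
    tot <- sum(s)
    if (tot <= 0) rep(NA_real_, 4L) else s / tot
  })
  sig <- image@channelRoles[["signal"]]; ref <- image@channelRoles[["reference"]]
  ratio <- ifelse(is.na(fractions[, ref]) | fractions[, ref] <= 0,
                  NA_real_, fractions[, sig] / fractions[, ref])
  out <- data.frame(
    cell_id = cellId, region = region,
    domain = rep(domainLabels(), times = length(chn)),
    channel = rep(chn, each = 4L),
    sum = as.vector(sums), fraction = as.vector(fractions),
    ratio = rep(ratio, times = length(chn)),
    stringsAsFactors = FALSE)
  if (any(colSums(sums) <= 0))
    attr(out, "flagged") <- chn[colSums(sums) <= 0]
  out
}

#' Per-cell ratio table and group summary
#'
#' @param measurements Data frame as returned by
#'   \code{\link{domainFluorescence}} (rows from several cells combined).
#' @return List with \code{cells} (one row per cell x domain: ratio) and
#'   \code{summary} (per domain: n, mean ratio, sd, \code{two_sd} = 2 x SD
#'   as plotted for ratio/fraction panels). Cells with any missing domain
#'   ratio are dropped with a message.
#' @export
ratioProfile <- function(measurements) {
  wide <- ratioMatrix(measurements)
  bad <- apply(wide, 1L, function(r) any(!is.finite(r)))
  if (any(bad)) {
    message("dropping ", sum(bad), " cell(s) with missing domain ratios: ",
            paste(rownames(wide)[bad], collapse = ", "))
    wide <- wide[!bad, , drop = FALSE]
  }
  cells <- data.frame(cell_id = rep(rownames(wide), times = 4L),
                      domain = rep(domainLabels(), each = nrow(wide)),
                      ratio = as.vector(wide), stringsAsFactors = FALSE)
  sds <- if (nrow(wide) == 1L) setNames(numeric(4L), colnames(wide)) else
    apply(wide, 2L, stats::sd)
  summary <- data.frame(domain = domainLabels(), n = nrow(wide),
                        mean = colMeans(wide), sd = sds, two_sd = 2 * sds,
                        stringsAsFactors = FALSE, row.names = NULL)
  list(cells = cells, summary = summary)
}

#' Per-cell by domain ratio matrix
#'
#' @param measurements Tidy measurement rows (\code{domainFluorescence}).
#' @return Numeric matrix, one row per cell (rownames = cell_id), columns
#'   in \code{domainLabels()} order, entries = signal/reference fractional
#'   ratio.
#' @export
ratioMatrix <- function(measurements) {
  m <- unique(measurements[, c("cell_id", "domain", "ratio")])
  ids <- unique(m$cell_id)
  out <- matrix(NA_real_, length(ids), 4L,
                dimnames = list(ids, domainLabels()))
  out[cbind(match(m$cell_id, ids), match(m$domain, domainLabels()))] <- m$ratio
  out
}
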