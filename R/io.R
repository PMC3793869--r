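# File formats: multi-page TIFF for images and masks (one page per channel,
# float samples scaled to [0,1] with per-channel scale factors recorded in a
# JSON sidecar), CSV for contours / annotations / measurements, JSON for
# ground truth summaries and run reports.

#' Write / read an ImageField as multi-page TIFF + JSON sidecar
#'
#' @param image An \code{ImageField}.
#' @param path Output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{writeImageField}: the path, invisibly.
#' @export
writeImageField <- function(image, path) {
  stopifnot(is(image, "ImageField"))
  scales <- vapply(image@channels, function(m) max(m, 1), numeric(1L))
  pages <- mapply(function(m, s) m / s, image@channels, scales,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(pixel_size_um = image@pixelSize,
                  channels = names(image@channels),
                  channel_roles = as.list(image@channelRoles),
                  scales = as.list(scales),
                  metadata = image@metadata[setdiff(names(image@metadata),
                                                    "origin_um")])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageField
#' @return \code{readImageField}: the \code{ImageField}.
#' @export
readImageField <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chans <- mapply(function(p, s) p * s, pages, as.numeric(side$scales),
                  SIMPLIFY = FALSE)
  names(chans) <- side$channels
  roles <- unlist(side$channel_roles)
  new("ImageField", channels = chans, pixelSize = side$pixel_size_um,
      channelRoles = roles,
      metadata = if (is.null(side$metadata)) list() else as.list(side$metadata))
}

#' Write / read cell contours as CSV polygon files
#'
#' Long format: one row per vertex with columns \code{cell_id},
#' \code{vertex_index}, \code{x}, \code{y}, \code{axis_angle}.
#'
#' @param contours A \code{CellContour} or list of them.
#' @param path CSV path.
#' @return \code{writeContours}: the path invisibly; \code{readContours}: a
#'   named list of \code{CellContour}.
#' @export
writeContours <- function(contours, path) {
  if (is(contours, "CellContour")) contours <- list(contours)
  rows <- do.call(rbind, lapply(contours, function(cc) {
    data.frame(cell_id = cc@cellId,
               vertex_index = seq_len(nrow(cc@vertices)) - 1L,
               x = cc@vertices[, 1L], y = cc@vertices[, 2L],
               axis_angle = cc@axisAngle, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(rows, rows$cell_id), function(d) {
    d <- d[order(d$vertex_index), ]
    new("CellContour", vertices = cbind(d$x, d$y), cellId = d$cell_id[1L],
        axisAngle = d$axis_angle[1L])
  })
  out[unique(rows$cell_id)]
}

#' Write a logical mask (or small-integer label map) as single-page TIFF
#'
#' @param mask Logical or small-integer matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- if (is.logical(mask)) mask * 1 else mask
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 8L)
  invisible(path)
}
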