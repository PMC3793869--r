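# Orchestration: simulate -> (segment | truth bypass) -> quantify ->
# puncta -> stats, with a single config, deterministic under a fixed seed.

# background frame of a per-cell tile: pixels within `width` px of the edge
.borderFrame <- function(dim, width = 6L) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[c(seq_len(width), dim[1L] - seq_len(width) + 1L), ] <- TRUE
  m[, c(seq_len(width), dim[2L] - seq_len(width) + 1L)] <- TRUE
  m
}

#' Quantify every cell of a synthetic field
#'
#' For each cell: zero the background (estimated from the tile border),
#' obtain the outline (ground-truth bypass, or the snake seeded at the
#' reference-channel intensity centroid), partition into quadrants, extract
#' the cortical band if needed, and measure per-domain fluorescence.
#'
#' @param field A \code{SyntheticField}.
#' @param region \code{"whole_cell"} or \code{"cortex"}.
#' @param bandWidth Cortical band width, um.
#' @param segmentation \code{"truth"} or \code{"snake"}.
#' @param snake Snake parameters (used when \code{segmentation="snake"}).
#' @param seedRadiusUm Initial snake circle radius, um.
#' @return Tidy measurement data frame (see
#'   \code{\link{domainFluorescence}}).
#' @export
measureCells <- function(field, region = c("whole_cell", "cortex"),
                         bandWidth = 5, segmentation = c("truth", "snake"),
                         snake = snakeParams(), seedRadiusUm = 5) {
  region <- match.arg(region)
  segmentation <- match.arg(segmentation)
  ann <- field@annotations
  out <- vector("list", length(field@cells))
  for (i in seq_along(field@cells)) {
    cell <- field@cells[[i]]
    img <- cell$image; truth <- cell$truth
    ps <- img@pixelSize
    dimIm <- dim(img@channels[[1L]])
    img <- zeroBackground(img, .borderFrame(dimIm))
    if (segmentation == "truth") {
      contour <- segmentFromTruth(truth, cellId = ann$cell_id[i])
      mask <- truth@cellMask
    } else {
      ref <- getChannel(img, "reference")
      sm <- .gauss2d(ref, 2)
      w <- sm / sum(sm)
      gx <- sum(w * col(sm)) - 1; gy <- sum(w * row(sm)) - 1
      contour <- segmentCell(ref, c(gx, gy), seedRadiusUm / ps,
                             params = snake, cellId = ann$cell_id[i],
                             axisAngle = ann$axis_angle[i])
      mask <- contourToMask(contour, dimIm)
    }
    part <- partitionQuadrants(contour, mask, pixelSize = ps)
    band <- if (region == "cortex")
      corticalBand(mask, contour, bandWidth, ps) else NULL
    out[[i]] <- domainFluorescence(img, part, mask,
                                   nucleusMask = truth@nucleusMask,
                                   region = region, band = band,
                                   cellId = ann$cell_id[i])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect and summarise puncta over a synthetic field
#'
#' @param field A \code{SyntheticField}.
#' @param bandWidth Cortical band width, um.
#' @param params Detection parameters (\code{\link{punctaParams}}).
#' @return List with \code{puncta} (all detections, cortical flag and
#'   domain set) and \code{densities} (per cell x domain).
#' @export
measurePuncta <- function(field, bandWidth = 5, params = punctaParams()) {
  ann <- field@annotations
  allP <- list(); allD <- list()
  for (i in seq_along(field@cells)) {
    cell <- field@cells[[i]]
    img <- zeroBackground(cell$image,
                          .borderFrame(dim(cell$image@channels[[1L]])))
    sig <- getChannel(img, "signal")
    truth <- cell$truth
    contour <- segmentFromTruth(truth, cellId = ann$cell_id[i])
    mask <- truth@cellMask
    ps <- img@pixelSize
    band <- corticalBand(mask, contour, bandWidth, ps)
    part <- partitionQuadrants(contour, mask, pixelSize = ps)
    det <- detectPuncta(sig, mask, params, cellId = ann$cell_id[i])
    det <- classifyCortical(det, band)
    if (nrow(det))
      det$domain <- ifelse(det$is_cortical,
                           assignPointToDomain(cbind(det$x, det$y), part),
                           NA_character_)
    else det$domain <- character(0)
    allP[[i]] <- det
    allD[[i]] <- punctaDensity(det, part, cellId = ann$cell_id[i])
  }
  list(puncta = do.call(rbind, c(allP, list(make.row.names = FALSE))),
       densities = do.call(rbind, c(allD, list(make.row.names = FALSE))))
}

#' Default run configuration
#'
#' @param ... Named overrides merged over the defaults.
#' @return Config list for \code{\link{runPipeline}}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    pixel_size = 0.25,
    band_width = 5,
    region = "cortex",
    segmentation = "truth",
    simulate = list(n_cells = 10L, mix = c(bipolar = 1),
                    distances = c(1, 2, 3, 4, 5), tissue = "notochord"),
    noise = list(shot = TRUE, read_sigma = 2, offset = 4,
                 texture_cv = 0.15, texture_scale = 3),
    enrichment = c(NSB = 1, ANTI = 1, ANT = 1, POST = 1),
    puncta = list(enabled = FALSE, rate = c(NSB = 0, ANTI = 0, ANT = 0,
                                            POST = 0)),
    stats = list(scheme = "class", value = "ratio",
                 distance_edges = c(2, 5)))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Validate a run configuration
#'
#' @param config Config list (see \code{\link{runConfig}}) or a YAML path.
#' @return Character vector of error messages; empty when the config is
#'   valid. All problems are reported, never a partial list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(!is.null(config$pixel_size) && config$pixel_size > 0,
       "pixel_size must be a positive number")
  need(!is.null(config$band_width) && config$band_width > 0,
       "band_width must be a positive number")
  need(isTRUE(config$region %in% c("whole_cell", "cortex")),
       "region must be 'whole_cell' or 'cortex'")
  need(isTRUE(config$segmentation %in% c("truth", "snake")),
       "segmentation must be 'truth' or 'snake'")
  need(!is.null(config$seed), "seed is required")
  sim <- config$simulate
  need(!is.null(sim$n_cells) && sim$n_cells >= 1,
       "simulate$n_cells must be >= 1")
  if (!is.null(sim$mix))
    need(abs(sum(unlist(sim$mix)) - 1) < 1e-8,
         "simulate$mix proportions must sum to 1")
  enr <- unlist(config$enrichment)
  if (!is.null(enr)) {
    need(all(names(enr) %in% domainLabels()),
         "enrichment names must be domain labels (NSB, ANTI, ANT, POST)")
    need(all(enr > 0), "enrichment multipliers must be > 0")
  }
  sc <- config$stats$scheme
  if (!is.null(sc))
    need(all(sc %in% c("class", "tissue", "distance_bin")),
         "stats$scheme must be among class, tissue, distance_bin")
  errs
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a configuration
#'
#' Simulates a field, quantifies every cell, optionally detects puncta,
#' runs the stratified statistics, and writes all artifacts (images,
#' annotations, contours, measurements, puncta, stats, JSON report) to the
#' output directory. Deterministic for a fixed seed; every CSV carries the
#' config hash in a comment-free sidecar (the report).
#'
#' @param config Config list or YAML path (see \code{\link{runConfig}}).
#' @param outDir Output directory (created if missing); NULL skips writing.
#' @return The run report, invisibly: a list with counts, group tests, the
#'   seed and the config hash.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  hash <- .configHash(config)
  noise <- config$noise
  sim <- config$simulate
  spec <- renderSpec(pixelSize = config$pixel_size,
                     corticalEnrichment = unlist(config$enrichment),
                     bandWidth = config$band_width,
                     punctaRate = if (isTRUE(config$puncta$enabled))
                       unlist(config$puncta$rate) else
                       c(NSB = 0, ANTI = 0, ANT = 0, POST = 0),
                     shot = isTRUE(noise$shot),
                     readSigma = noise$read_sigma, offset = noise$offset,
                     textureCV = noise$texture_cv,
                     textureScale = noise$texture_scale)
  field <- generateField(sim$n_cells, mix = unlist(sim$mix), spec = spec,
                         distances = unlist(sim$distances),
                         tissue = sim$tissue, seed = config$seed)
  meas <- measureCells(field, region = config$region,
                       bandWidth = config$band_width,
                       segmentation = config$segmentation)
  punc <- if (isTRUE(config$puncta$enabled))
    measurePuncta(field, bandWidth = config$band_width) else NULL
  groups <- stratify(meas, annotations(field),
                     scheme = config$stats$scheme,
                     value = config$stats$value,
                     distanceEdges = unlist(config$stats$distance_edges))
  figs <- summariseFigures(groups)
  report <- list(
    package = as.character(utils::packageVersion("CortexQuant")),
    seed = config$seed, config_hash = hash,
    n_cells = sim$n_cells,
    n_measured = length(unique(meas$cell_id)),
    groups = lapply(figs$tests, function(t) if (is.null(t)) NULL else
      list(n = t@n, F = t@F, epsilon = t@epsilon, p_gg = t@pGG)),
    significant_groups = names(Filter(function(t) !is.null(t) &&
                                        t@pGG < 0.05, figs$tests)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(field@cells))
      writeImageField(field@cells[[i]]$image,
                      file.path(outDir, sprintf("cell_%03d.tif", i)))
    utils::write.csv(annotations(field),
                     file.path(outDir, "annotations.csv"), row.names = FALSE)
    writeContours(lapply(seq_along(field@cells), function(i)
      segmentFromTruth(field@cells[[i]]$truth,
                       annotations(field)$cell_id[i])),
      file.path(outDir, "contours.csv"))
    utils::write.csv(meas, file.path(outDir, "measurements.csv"),
                     row.names = FALSE)
    if (!is.null(punc)) {
      utils::write.csv(punc$puncta, file.path(outDir, "puncta.csv"),
                       row.names = FALSE)
      utils::write.csv(punc$densities, file.path(outDir, "puncta_density.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(figs$summary, file.path(outDir, "group_summary.csv"),
                     row.names = FALSE)
    if (!is.null(figs$pairwise))
      utils::write.csv(figs$pairwise, file.path(outDir, "pairwise.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(report, list(measurements = meas, figures = figs,
                           puncta = punc)))
}
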