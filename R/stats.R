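# Repeated-measures one-way ANOVA over the four within-cell domains with
# Greenhouse-Geisser sphericity correction, Bonferroni-adjusted paired
# post hoc comparisons, and the stratification schemes (polarity class,
# tissue, distance-to-NSB bin) used for group-level testing.

#' Greenhouse-Geisser epsilon (Box's formula)
#'
#' Computed from the double-centred sample covariance matrix C of the k
#' repeated measures: epsilon = tr(C)^2 / ((k-1) * sum(C^2)), clipped to
#' [1/(k-1), 1]. Constant (singular) data yield epsilon = 1 by convention,
#' flagged in the \code{"degenerate"} attribute.
#'
#' @param values n x k numeric matrix, one row per subject (cell).
#' @return Epsilon in [1/(k-1), 1].
#' @export
ggEpsilon <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2L, k >= 2L, !anyNA(values))
  S <- stats::cov(values)
  H <- diag(k) - matrix(1 / k, k, k)
  C <- H %*% S %*% H
  den <- (k - 1) * sum(C^2)
  if (den < .Machine$double.eps * max(1, sum(diag(C))^2))
    return(structure(1, degenerate = TRUE))
  eps <- sum(diag(C))^2 / den
  min(max(eps, 1 / (k - 1)), 1)
}

.stars <- function(p) ifelse(p < 0.001, "***",
                      ifelse(p < 0.01, "**",
                      ifelse(p < 0.05, "*", "ns")))

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way within-subject ANOVA over the four domains. The F statistic uses
#' the usual subject-by-domain decomposition; its p-value is evaluated at
#' the epsilon-corrected degrees of freedom (df1 * eps, df2 * eps). All six
#' domain pairs are compared with paired t-tests and Bonferroni factor 6.
#'
#' @param values n x 4 matrix (rows = cells, columns in
#'   \code{domainLabels()} order), or a \code{CellGroup}-like data frame
#'   with columns \code{cell_id}, \code{domain}, \code{value}. Rows with
#'   missing values are dropped listwise with a message.
#' @param label Group label carried into the result.
#' @return A \code{StatsResult}.
#' @export
rmAnovaGG <- function(values, label = "group") {
  if (is.data.frame(values)) {
    ids <- unique(values$cell_id)
    m <- matrix(NA_real_, length(ids), 4L,
                dimnames = list(ids, domainLabels()))
    m[cbind(match(values$cell_id, ids),
            match(values$domain, domainLabels()))] <- values$value
    values <- m
  }
  values <- as.matrix(values)
  drop <- apply(values, 1L, function(r) any(!is.finite(r)))
  if (any(drop)) {
    message("listwise deletion of ", sum(drop), " cell(s) with missing values")
    values <- values[!drop, , drop = FALSE]
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("need at least 3 complete cells for the RM-ANOVA")
  grand <- mean(values)
  colM <- colMeans(values); rowM <- rowMeans(values)
  ssDomain <- n * sum((colM - grand)^2)
  ssErr <- sum((values - outer(rowM, colM, "+") + grand)^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fstat <- if (ssErr <= 0) {
    if (ssDomain <= 0) 0 else Inf
  } else (ssDomain / df1) / (ssErr / df2)
  eps <- ggEpsilon(values)
  if (ssDomain <= 0) Fstat <- 0
  pUn <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  pGG <- stats::pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  pairs <- utils::combn(k, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- values[, a] - values[, b]
    p <- if (stats::sd(d) == 0) as.numeric(all(d == 0) * 1) else
      stats::t.test(d)$p.value
    data.frame(domain_a = colnames(values)[a], domain_b = colnames(values)[b],
               mean_diff = mean(d), p_raw = p,
               p_bonferroni = min(1, 6 * p), stringsAsFactors = FALSE)
  }))
  pw$stars <- .stars(pw$p_bonferroni)
  new("StatsResult", F = Fstat, df1 = df1, df2 = df2,
      epsilon = as.numeric(eps), pGG = pGG, pUncorrected = pUn,
      pairwise = pw, n = n, label = label)
}

#' Stratify measured cells into groups
#'
#' Groups cells by polarity class, tissue and/or distance-to-NSB bin, the
#' strata used in the emulated experiments. Default distance bins are
#' up-to-2, 3-to-4 and 5-or-more cell diameters.
#'
#' @param measurements Tidy measurement table carrying one value per cell x
#'   domain: columns \code{cell_id}, \code{domain}, and a value column.
#' @param annotations Annotation table: \code{cell_id}, \code{class},
#'   \code{tissue}, \code{distance}.
#' @param scheme Character vector from \code{c("class", "tissue",
#'   "distance_bin")}; groups are keyed by their combination.
#' @param value Name of the value column (default \code{"ratio"}).
#' @param distanceEdges Bin edges: distances <= edges[1] fall in the first
#'   bin, distances >= edges[2] in the last.
#' @return Named list of groups; each group is a list with \code{label},
#'   \code{values} (n x 4 matrix) and \code{n}. Empty groups are dropped.
#' @export
stratify <- function(measurements, annotations,
                     scheme = c("class"), value = "ratio",
                     distanceEdges = c(2, 5)) {
  stopifnot(all(scheme %in% c("class", "tissue", "distance_bin")))
  orphan <- setdiff(unique(measurements$cell_id), annotations$cell_id)
  if (length(orphan))
    stop("cells without annotation: ", paste(orphan, collapse = ", "))
  ann <- annotations
  labs <- c(sprintf("<=%g", distanceEdges[1L]),
            sprintf("%g-%g", distanceEdges[1L] + 1, distanceEdges[2L] - 1),
            sprintf(">=%g", distanceEdges[2L]))
  ann$distance_bin <- factor(
    ifelse(ann$distance <= distanceEdges[1L], labs[1L],
    ifelse(ann$distance < distanceEdges[2L], labs[2L], labs[3L])),
    levels = labs)
  key <- interaction(ann[, scheme, drop = FALSE], drop = TRUE, sep = "/")
  groups <- list()
  for (lev in levels(key)) {
    ids <- ann$cell_id[key == lev]
    rows <- measurements[measurements$cell_id %in% ids, , drop = FALSE]
    if (!nrow(rows)) next
    m <- unique(rows[, c("cell_id", "domain", value)])
    uid <- unique(m$cell_id)
    mat <- matrix(NA_real_, length(uid), 4L,
                  dimnames = list(uid, domainLabels()))
    mat[cbind(match(m$cell_id, uid), match(m$domain, domainLabels()))] <-
      m[[value]]
    groups[[lev]] <- list(label = lev, values = mat, n = nrow(mat))
  }
  groups
}

#' Test and summarise all groups
#'
#' Runs \code{\link{rmAnovaGG}} on every group (groups with fewer than 3
#' cells are summarised but not tested) and assembles the figure-style
#' summary: per-domain means with +/- 2 x SD error bars (ratio/fraction
#' statistics) or +/- 2 x SEM (puncta densities), plus the star-annotated
#' pairwise table.
#'
#' @param groups List from \code{\link{stratify}}.
#' @param errorBar \code{"2sd"} or \code{"2sem"}.
#' @return List with \code{tests} (named list of \code{StatsResult} or
#'   NULL), \code{summary} (per group x domain means and error bars) and
#'   \code{pairwise} (all pairwise rows with group labels).
#' @export
summariseFigures <- function(groups, errorBar = c("2sd", "2sem")) {
  errorBar <- match.arg(errorBar)
  tests <- list(); summ <- list(); pw <- list()
  for (g in groups) {
    mat <- g$values
    sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
    err <- if (errorBar == "2sd") 2 * sds else
      2 * sds / sqrt(colSums(is.finite(mat)))
    summ[[g$label]] <- data.frame(
      group = g$label, domain = domainLabels(), n = g$n,
      mean = colMeans(mat, na.rm = TRUE), error = err,
      stringsAsFactors = FALSE, row.names = NULL)
    if (g$n >= 3L) {
      res <- rmAnovaGG(mat, label = g$label)
      tests[[g$label]] <- res
      pw[[g$label]] <- cbind(group = g$label, res@pairwise)
    } else {
      message("group '", g$label, "' has n < 3; test skipped")
      tests[g$label] <- list(NULL)
    }
  }
  list(tests = tests,
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       pairwise = if (length(pw))
         do.call(rbind, c(pw, list(make.row.names = FALSE))) else NULL)
}
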