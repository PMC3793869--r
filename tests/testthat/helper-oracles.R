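# Independent brute-force oracles, deliberately implemented apart from the
# package's own (compiled) routines.

# even-odd ray-casting point-in-polygon, plain R
pipOracleR <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# minimum point-to-segment distance, plain R
distOracleR <- function(px, py, poly) {
  n <- nrow(poly)
  best <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    dx <- poly[i, 1] - ax; dy <- poly[i, 2] - ay
    l2 <- dx^2 + dy^2
    t <- if (l2 > 0) pmin(pmax(((px - ax) * dx + (py - ay) * dy) / l2, 0), 1)
         else 0
    d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    best <- pmin(best, d)
    j <- i
  }
  best
}

# Greenhouse-Geisser epsilon via the eigenvalues of the double-centred
# covariance (equivalent route to Box's trace formula)
ggEpsOracle <- function(X) {
  k <- ncol(X)
  H <- diag(k) - matrix(1 / k, k, k)
  C <- H %*% stats::cov(X) %*% H
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  sum(ev)^2 / ((k - 1) * sum(ev^2))
}

# construct an n x k data matrix whose sample covariance equals S exactly:
# centered iid columns are orthonormalised and scaled so cov(Z) = I
.dataWithCov <- function(n, S, seed = 1) {
  k <- ncol(S)
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z)) * sqrt(n - 1)
  Z %*% chol(S)
}

# random star-shaped simple polygon around a center
randomStarPolygon <- function(n = 24, rMin = 5, rMax = 20,
                              center = c(0, 0)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rMin, rMax)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# noise-free render spec used by segmentation/measurement fixtures
quietSpec <- function(...) {
  renderSpec(shot = FALSE, readSigma = 0, offset = 0, textureCV = 0, ...)
}

# match detections to planted truth within tol px; returns recall/precision
matchPuncta <- function(det, truth, tol = 2) {
  if (!nrow(det) || !nrow(truth))
    return(list(recall = as.numeric(nrow(truth) == 0),
                precision = as.numeric(nrow(det) == 0)))
  d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2
  list(recall = mean(apply(d2, 2, min) <= tol^2),
       precision = mean(apply(d2, 1, min) <= tol^2))
}
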