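# Thin wrappers around EBImage filtering, keeping the package's plain-matrix
# (row = y) convention at the interfaces.

.gauss2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  cpp_gauss_blur(m, sigma)
}

.filter2d <- function(m, kernel) {
  as.matrix(EBImage::filter2(m, kernel, boundary = "replicate"))
}

# central-difference gradients; gx along columns (image x), gy along rows
.gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1L, 1:(nc - 1L))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1L, 1:(nr - 1L)), ]) / 2
  list(gx = gx, gy = gy)
}

# bilinear interpolation of matrix m at 0-based (x, y) positions, clamped
.bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1L); y <- pmin(pmax(y, 0), nr - 1L)
  x0 <- pmin(floor(x), nc - 2L); y0 <- pmin(floor(y), nr - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  v00 <- m[i00]; v01 <- m[cbind(y0 + 1L, x0 + 2L)]
  v10 <- m[cbind(y0 + 2L, x0 + 1L)]; v11 <- m[cbind(y0 + 2L, x0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}
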