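#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Geometry kernels shared by rasterisation, cortical-band extraction and the
// synthetic renderer. Conventions: pixel centers sit at integer (x, y) with
// x = column - 1, y = row - 1 of the R matrix; polygons are closed implicitly
// (last vertex connects back to the first); even-odd interior rule throughout.

// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    bool in = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((vy[j] > y) != (vy[k] > y)) &&
          (x < (vx[k] - vx[j]) * (y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        in = !in;
    }
    inside[i] = in;
  }
  return inside;
}

// Scanline even-odd fill: a pixel is set iff its center lies inside the
// polygon. Crossings are collected per row (y = 0 .. nrow-1), paired, and
// the spans between pairs are filled.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(NumericVector vx, NumericVector vy,
                                    int nrow, int ncol) {
  LogicalMatrix mask(nrow, ncol);
  const int m = vx.size();
  if (m < 3) return mask;
  std::vector<double> xs;
  for (int y = 0; y < nrow; ++y) {
    xs.clear();
    const double yc = (double)y;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      const double y1 = vy[k], y2 = vy[j];
      if ((y1 > yc) != (y2 > yc)) {
        xs.push_back(vx[k] + (vx[j] - vx[k]) * (yc - y1) / (y2 - y1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int x0 = (int)std::ceil(xs[p]);
      int x1 = (int)std::floor(xs[p + 1]);
      // pixel center strictly inside the span; centers exactly on an edge
      // crossing follow the half-open rule of the ceil/floor pair
      if (std::floor(xs[p]) == xs[p]) x0 = (int)xs[p] + 1;
      if (x0 < 0) x0 = 0;
      if (x1 > ncol - 1) x1 = ncol - 1;
      for (int x = x0; x <= x1; ++x) mask(y, x) = true;
    }
  }
  return mask;
}

// Minimum Euclidean distance from each query point to a closed polyline.
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    double best = R_PosInf;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      const double ax = vx[k], ay = vy[k];
      const double dx = vx[j] - ax, dy = vy[j] - ay;
      const double len2 = dx * dx + dy * dy;
      double t = 0.0;
      if (len2 > 0) {
        t = ((x - ax) * dx + (y - ay) * dy) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      const double ex = x - (ax + t * dx), ey = y - (ay + t * dy);
      const double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Accumulate Gaussian spots (amplitude * exp(-r^2 / 2 sigma^2)) into an
// image, each truncated at 4 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_add_gaussian_spots(NumericMatrix img, NumericVector cx,
                                     NumericVector cy, NumericVector amp,
                                     NumericVector sigma) {
  const int nrow = img.nrow(), ncol = img.ncol(), n = cx.size();
  for (int i = 0; i < n; ++i) {
    const double s = sigma[i], a = amp[i];
    const double r = 4.0 * s;
    const int x0 = std::max(0, (int)std::floor(cx[i] - r));
    const int x1 = std::min(ncol - 1, (int)std::ceil(cx[i] + r));
    const int y0 = std::max(0, (int)std::floor(cy[i] - r));
    const int y1 = std::min(nrow - 1, (int)std::ceil(cy[i] + r));
    const double inv = 1.0 / (2.0 * s * s);
    for (int y = y0; y <= y1; ++y) {
      const double dy = y - cy[i];
      for (int x = x0; x <= x1; ++x) {
        const double dx = x - cx[i];
        img(y, x) += a * std::exp(-(dx * dx + dy * dy) * inv);
      }
    }
  }
  return img;
}

// Separable Gaussian blur with replicate boundary (truncated at 3 sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix m, double sigma) {
  const int nr = m.nrow(), nc = m.ncol();
  if (sigma <= 0) return m;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int x = 0; x < nc; ++x) {        // vertical pass
    for (int y = 0; y < nr; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = 0; else if (yy >= nr) yy = nr - 1;
        acc += k[i + r] * m(yy, x);
      }
      tmp(y, x) = acc;
    }
  }
  for (int y = 0; y < nr; ++y) {        // horizontal pass
    for (int x = 0; x < nc; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0; else if (xx >= nc) xx = nc - 1;
        acc += k[i + r] * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Pixels whose center lies within `width` of the closed polyline: each
// segment stamps its width-inflated bounding box, testing point-segment
// distance locally. Exact (same predicate as cpp_dist_to_polyline <= width)
// but near-linear in perimeter * width.
// [[Rcpp::export]]
LogicalMatrix cpp_band_mask(NumericVector vx, NumericVector vy,
                            int nrow, int ncol, double width) {
  LogicalMatrix out(nrow, ncol);
  const int m = vx.size();
  const double w2 = width * width;
  for (int j = 0, k = m - 1; j < m; k = j++) {
    const double ax = vx[k], ay = vy[k];
    const double bx = vx[j], by = vy[j];
    const double dx = bx - ax, dy = by - ay;
    const double len2 = dx * dx + dy * dy;
    const int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - width));
    const int x1 = std::min(ncol - 1, (int)std::ceil(std::max(ax, bx) + width));
    const int y0 = std::max(0, (int)std::floor(std::min(ay, by) - width));
    const int y1 = std::min(nrow - 1, (int)std::ceil(std::max(ay, by) + width));
    for (int y = y0; y <= y1; ++y) {
      for (int x = x0; x <= x1; ++x) {
        if (out(y, x)) continue;
        double t = 0.0;
        if (len2 > 0) {
          t = ((x - ax) * dx + (y - ay) * dy) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        const double ex = x - (ax + t * dx), ey = y - (ay + t * dy);
        if (ex * ex + ey * ey <= w2) out(y, x) = true;
      }
    }
  }
  return out;
}
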