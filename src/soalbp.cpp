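#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fold an out-of-range index back into [0, n) by symmetric reflection
// (edge pixel duplicated: ... b a | a b c | c b ...), iterated so that
// kernels wider than the image remain well defined.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// Separable convolution with a symmetric odd-length kernel and reflective
// boundary handling. Kernel is applied along rows, then columns.
// [[Rcpp::export(name = ".sep_convolve")]]
NumericMatrix sep_convolve(const NumericMatrix& img, const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int h = klen / 2;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns of each row (x direction)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        acc += kernel[t + h] * img(r, reflect_index(c + t, nc));
      }
      tmp(r, c) = acc;
    }
  }
  // along rows of each column (y direction)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        acc += kernel[t + h] * tmp(reflect_index(r + t, nr), c);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// 5-point finite-difference Laplacian with reflective boundaries.
// [[Rcpp::export(name = ".laplacian5")]]
NumericMatrix laplacian5(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const int cl = reflect_index(c - 1, nc), cr = reflect_index(c + 1, nc);
    for (int r = 0; r < nr; ++r) {
      const int ru = reflect_index(r - 1, nr), rd = reflect_index(r + 1, nr);
      out(r, c) = img(ru, c) + img(rd, c) + img(r, cl) + img(r, cr) - 4.0 * img(r, c);
    }
  }
  return out;
}

static inline double bilinear(const NumericMatrix& img, double row, double col) {
  const int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
  const double fr = row - r0, fc = col - c0;
  const double v00 = img(r0, c0), v01 = img(r0, c0 + 1);
  const double v10 = img(r0 + 1, c0), v11 = img(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Accumulated LBP histogram. Neighbor k of the center (x, y) at angular
// offset o sits at (x + r*cos(o + 2*pi*k/n), y - r*sin(o + 2*pi*k/n)) with
// x = column, y = row and the y axis of the angle convention pointing up.
// Patterns are accumulated over all offsets; pixels closer than `margin`
// to the border are skipped. Bit k is set when neighbor - center >= thresh.
// [[Rcpp::export(name = ".lbp_hist")]]
NumericVector lbp_hist(const NumericMatrix& img, double radius, int n,
                       double thresh, const NumericVector& offsets, int margin) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nbins = 1 << n;
  NumericVector hist(nbins);
  if (nr - 2 * margin <= 0 || nc - 2 * margin <= 0)
    stop("image too small for radius");
  const int noff = offsets.size();
  std::vector<double> dx(n * noff), dy(n * noff);
  for (int o = 0; o < noff; ++o) {
    for (int k = 0; k < n; ++k) {
      const double a = offsets[o] + 2.0 * M_PI * k / n;
      dx[o * n + k] = radius * std::cos(a);
      dy[o * n + k] = -radius * std::sin(a);  // image rows grow downward
    }
  }
  for (int o = 0; o < noff; ++o) {
    const double* ddx = &dx[o * n];
    const double* ddy = &dy[o * n];
    for (int r = margin; r < nr - margin; ++r) {
      for (int c = margin; c < nc - margin; ++c) {
        const double center = img(r, c);
        int pattern = 0;
        for (int k = 0; k < n; ++k) {
          const double v = bilinear(img, r + ddy[k], c + ddx[k]);
          if (v - center >= thresh) pattern |= (1 << k);
        }
        hist[pattern] += 1.0;
      }
    }
  }
  return hist;
}

// Bilinear sampling of an image on an arbitrary grid of (row, col)
// coordinates (0-based, fractional); out-of-range coordinates reflect.
// [[Rcpp::export(name = ".bilinear_grid")]]
NumericVector bilinear_grid(const NumericMatrix& img, const NumericVector& rows,
                            const NumericVector& cols) {
  const int nr = img.nrow(), nc = img.ncol();
  const int m = rows.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double row = rows[i], col = cols[i];
    int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
    const double fr = row - r0, fc = col - c0;
    const int r1 = reflect_index(r0 + 1, nr), c1 = reflect_index(c0 + 1, nc);
    r0 = reflect_index(r0, nr);
    c0 = reflect_index(c0, nc);
    out[i] = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
             fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
  }
  return out;
}
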