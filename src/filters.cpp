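#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// reflect-101 border index: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
static inline int reflect101(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// k x k median filter of one channel (doubles, any range).
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  int m = x.nrow(), n = x.ncol(), h = k / 2;
  NumericMatrix out(m, n);
  std::vector<double> buf(k * k);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      int c = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = reflect101(j + dj, n);
        for (int di = -h; di <= h; ++di)
          buf[c++] = x(reflect101(i + di, m), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + c / 2, buf.begin() + c);
      double med = buf[c / 2];
      if (c % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + c / 2);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable convolution with a symmetric 1-D kernel, reflect-101 borders.
// [[Rcpp::export]]
NumericMatrix sep_conv_cpp(NumericMatrix x, NumericVector kernel) {
  int m = x.nrow(), n = x.ncol(), k = kernel.size(), h = k / 2;
  NumericMatrix tmp(m, n), out(m, n);
  for (int j = 0; j < n; ++j)       // vertical pass
    for (int i = 0; i < m; ++i) {
      double s = 0;
      for (int d = -h; d <= h; ++d) s += kernel[d + h] * x(reflect101(i + d, m), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < n; ++j)       // horizontal pass
    for (int i = 0; i < m; ++i) {
      double s = 0;
      for (int d = -h; d <= h; ++d) s += kernel[d + h] * tmp(i, reflect101(j + d, n));
      out(i, j) = s;
    }
  return out;
}

// Bilateral filter of one channel: product of a spatial Gaussian
// (sigma_space, over pixel distance) and a range Gaussian (sigma_range,
// over intensity difference in 8-bit counts), normalized per pixel.
// d is the neighborhood diameter (odd).
// [[Rcpp::export]]
NumericMatrix bilateral_filter_cpp(NumericMatrix x, int d,
                                   double sigma_space, double sigma_range) {
  int m = x.nrow(), n = x.ncol(), h = d / 2;
  NumericMatrix out(m, n);
  double gs = -0.5 / (sigma_space * sigma_space);
  double gr = -0.5 / (sigma_range * sigma_range);
  std::vector<double> spatial((2 * h + 1) * (2 * h + 1));
  for (int dj = -h, c = 0; dj <= h; ++dj)
    for (int di = -h; di <= h; ++di, ++c)
      spatial[c] = std::exp(gs * (di * di + dj * dj));
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double center = x(i, j), num = 0, den = 0;
      int c = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = reflect101(j + dj, n);
        for (int di = -h; di <= h; ++di, ++c) {
          double v = x(reflect101(i + di, m), jj);
          double diff = v - center;
          double w = spatial[c] * std::exp(gr * diff * diff);
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
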