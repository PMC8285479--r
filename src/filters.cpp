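#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disk-footprint median filter. `off` is a K x 2 matrix of (dy, dx)
// offsets; at image borders the median is taken over the in-bounds part
// of the footprint.
// [[Rcpp::export(name = ".cpp_disk_median")]]
NumericMatrix cpp_disk_median(NumericMatrix img, IntegerMatrix off) {
  int ny = img.nrow(), nx = img.ncol(), K = off.nrow();
  NumericMatrix out(ny, nx);
  std::vector<double> buf;
  buf.reserve(K);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      buf.clear();
      for (int k = 0; k < K; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        if (ii >= 0 && ii < ny && jj >= 0 && jj < nx)
          buf.push_back(img(ii, jj));
      }
      size_t n = buf.size(), h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double m = buf[h];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        m = 0.5 * (m + lo);
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Disk-footprint local mean (in-bounds normalised).
// [[Rcpp::export(name = ".cpp_disk_mean")]]
NumericMatrix cpp_disk_mean(NumericMatrix img, IntegerMatrix off) {
  int ny = img.nrow(), nx = img.ncol(), K = off.nrow();
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double s = 0.0; int n = 0;
      for (int k = 0; k < K; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        if (ii >= 0 && ii < ny && jj >= 0 && jj < nx) {
          s += img(ii, jj);
          ++n;
        }
      }
      out(i, j) = s / n;
    }
  }
  return out;
}

// Grayscale erosion with a non-flat (ball) structuring element:
// e(p) = min over in-bounds q of img(p+q) - h(q).
// [[Rcpp::export(name = ".cpp_ball_erode")]]
NumericMatrix cpp_ball_erode(NumericMatrix img, IntegerMatrix off,
                             NumericVector h) {
  int ny = img.nrow(), nx = img.ncol(), K = off.nrow();
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        if (ii >= 0 && ii < ny && jj >= 0 && jj < nx) {
          double v = img(ii, jj) - h[k];
          if (v < m) m = v;
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Grayscale dilation with a non-flat (ball) structuring element:
// d(p) = max over in-bounds q of img(p+q) + h(q).
// [[Rcpp::export(name = ".cpp_ball_dilate")]]
NumericMatrix cpp_ball_dilate(NumericMatrix img, IntegerMatrix off,
                              NumericVector h) {
  int ny = img.nrow(), nx = img.ncol(), K = off.nrow();
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        if (ii >= 0 && ii < ny && jj >= 0 && jj < nx) {
          double v = img(ii, jj) + h[k];
          if (v > m) m = v;
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}
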