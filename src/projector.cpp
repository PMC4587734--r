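#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Pixel-driven parallel-beam projector.  Every pixel is divided into
// 2x2 equal sub-pixels; each sub-pixel's value/4 is split linearly
// between the two detector bins that bracket its projected coordinate
//   t = x*cos(theta) + y*sin(theta)
// with x = col - center (rightwards) and y = center - row (upwards),
// both in pixel units relative to the rotation center.  The detector
// axis has unit spacing and is symmetric about t = 0 (odd bin count).
//
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img,
                                  const NumericVector& anglesRad,
                                  int nbins, double center) {
  const int n = img.nrow(), K = anglesRad.size();
  const double half = (nbins - 1) / 2.0;
  static const double sub[2] = {-0.25, 0.25};
  NumericMatrix out(K, nbins);

  for (int k = 0; k < K; ++k) {
    const double c = std::cos(anglesRad[k]), s = std::sin(anglesRad[k]);
    double* row = &out(k, 0);
    for (int i = 0; i < n; ++i) {      // image row
      const double y = center - i;
      for (int j = 0; j < n; ++j) {    // image column
        const double v = img(i, j);
        if (v == 0.0) continue;
        const double x = j - center;
        const double q = v * 0.25;
        for (int a = 0; a < 2; ++a) {
          for (int b = 0; b < 2; ++b) {
            const double t = (x + sub[a]) * c + (y + sub[b]) * s + half;
            const int lo = (int)std::floor(t);
            const double f = t - lo;
            if (lo >= 0 && lo < nbins) row[(size_t)lo * K] += q * (1.0 - f);
            if (lo + 1 >= 0 && lo + 1 < nbins) row[(size_t)(lo + 1) * K] += q * f;
          }
        }
      }
    }
  }
  return out;
}

// Back-projection of filtered rows: each pixel accumulates the
// interpolated value of every row at t = x*cos + y*sin, scaled by pi/K.
// Samples falling outside the detector axis contribute zero.
//
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& q,
                              const NumericVector& anglesRad,
                              int n, double center, bool linear) {
  const int K = q.nrow(), nbins = q.ncol();
  const double half = (nbins - 1) / 2.0;
  const double scale = M_PI / K;
  NumericMatrix out(n, n);

  for (int k = 0; k < K; ++k) {
    const double c = std::cos(anglesRad[k]), s = std::sin(anglesRad[k]);
    for (int i = 0; i < n; ++i) {
      const double y = center - i;
      const double base = y * s + half;
      for (int j = 0; j < n; ++j) {
        const double t = (j - center) * c + base;
        double val = 0.0;
        if (linear) {
          const int lo = (int)std::floor(t);
          const double f = t - lo;
          if (lo >= 0 && lo < nbins) val += q(k, lo) * (1.0 - f);
          if (lo + 1 >= 0 && lo + 1 < nbins) val += q(k, lo + 1) * f;
        } else {
          const int nn = (int)std::lround(t);
          if (nn >= 0 && nn < nbins) val = q(k, nn);
        }
        out(i, j) += scale * val;
      }
    }
  }
  return out;
}

// Exact adjoint (matrix transpose) of cpp_forward_project, used by the
// algebraic reconstructors.  No pi/K scaling.
//
// [[Rcpp::export]]
NumericMatrix cpp_project_adjoint(const NumericMatrix& sino,
                                  const NumericVector& anglesRad,
                                  int n, double center) {
  const int K = sino.nrow(), nbins = sino.ncol();
  const double half = (nbins - 1) / 2.0;
  static const double sub[2] = {-0.25, 0.25};
  NumericMatrix out(n, n);

  for (int k = 0; k < K; ++k) {
    const double c = std::cos(anglesRad[k]), s = std::sin(anglesRad[k]);
    for (int i = 0; i < n; ++i) {
      const double y = center - i;
      for (int j = 0; j < n; ++j) {
        const double x = j - center;
        double acc = 0.0;
        for (int a = 0; a < 2; ++a) {
          for (int b = 0; b < 2; ++b) {
            const double t = (x + sub[a]) * c + (y + sub[b]) * s + half;
            const int lo = (int)std::floor(t);
            const double f = t - lo;
            if (lo >= 0 && lo < nbins) acc += 0.25 * (1.0 - f) * sino(k, lo);
            if (lo + 1 >= 0 && lo + 1 < nbins) acc += 0.25 * f * sino(k, lo + 1);
          }
        }
        out(i, j) += acc;
      }
    }
  }
  return out;
}
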