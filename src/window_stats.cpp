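#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sliding circular-window statistics with border clipping: windows are
// truncated at the image edge and statistics use the in-bounds pixels only.
// Offsets (dx, dy) are the integer displacements of the circular footprint.

// [[Rcpp::export]]
List cpp_window_mean_sd(NumericMatrix img, IntegerVector dx, IntegerVector dy) {
  const int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix mean(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      int n = 0;
      for (int k = 0; k < K; ++k) {
        const int ii = i + dx[k], jj = j + dy[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj);
        s += v; s2 += v * v; ++n;
      }
      const double m = s / n;
      mean(i, j) = m;
      const double var = s2 / n - m * m;   // population variance
      sd(i, j) = var > 0.0 ? std::sqrt(var) : 0.0;
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// [[Rcpp::export]]
NumericMatrix cpp_window_median(NumericMatrix img, IntegerVector dx,
                                IntegerVector dy) {
  const int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(K);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int k = 0; k < K; ++k) {
        const int ii = i + dx[k], jj = j + dy[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        buf.push_back(img(ii, jj));
      }
      const int n = (int)buf.size();
      const int h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (n % 2 == 0) {
        // even count: mean of the central pair
        const double lo = *std::max_element(buf.begin(), buf.begin() + h);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Masked (background-restricted) window mean and SD.  If the base circular
// window holds no masked pixel, the window radius grows in +1 steps
// (diameter +2) until at least one masked pixel is reached.
// [[Rcpp::export]]
List cpp_window_masked_mean_sd(NumericMatrix img, LogicalMatrix mask,
                               IntegerVector dx, IntegerVector dy,
                               double radius) {
  const int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix mean(nr, nc), sd(nr, nc);
  IntegerMatrix used_radius(nr, nc);
  const int max_r = nr + nc;  // a nonempty mask is always reached before this
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      int n = 0;
      for (int k = 0; k < K; ++k) {
        const int ii = i + dx[k], jj = j + dy[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (!mask(ii, jj)) continue;
        const double v = img(ii, jj);
        s += v; s2 += v * v; ++n;
      }
      double r_prev = radius, r_cur = radius;
      while (n == 0 && r_cur < max_r) {
        r_cur = r_prev + 1.0;  // grow diameter by 2 px
        const double r2_lo = r_prev * r_prev, r2_hi = r_cur * r_cur;
        const int b = (int)std::floor(r_cur);
        for (int ddx = -b; ddx <= b; ++ddx) {
          for (int ddy = -b; ddy <= b; ++ddy) {
            const double d2 = (double)ddx * ddx + (double)ddy * ddy;
            if (d2 <= r2_lo || d2 > r2_hi) continue;  // new ring only
            const int ii = i + ddx, jj = j + ddy;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (!mask(ii, jj)) continue;
            const double v = img(ii, jj);
            s += v; s2 += v * v; ++n;
          }
        }
        r_prev = r_cur;
      }
      used_radius(i, j) = (int)std::ceil(r_cur);
      const double m = n > 0 ? s / n : NA_REAL;
      mean(i, j) = m;
      if (n > 0) {
        const double var = s2 / n - m * m;
        sd(i, j) = var > 0.0 ? std::sqrt(var) : 0.0;
      } else {
        sd(i, j) = NA_REAL;
      }
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd,
                      _["radius"] = used_radius);
}
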