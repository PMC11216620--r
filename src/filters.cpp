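#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// replicate-padded index
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// 3x3x3 spatial median with replicate edge padding.
// vol is a numeric vector in column-major (x fastest) order.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, int nx, int ny, int nz) {
  NumericVector out(vol.size());
  std::vector<double> nb(27);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = clampi(z + dz, nz);
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = clampi(y + dy, ny);
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = clampi(x + dx, nx);
              nb[k++] = vol[xx + nx * (yy + (R_xlen_t)ny * zz)];
            }
          }
        }
        std::nth_element(nb.begin(), nb.begin() + 13, nb.end());
        out[x + nx * (y + (R_xlen_t)ny * z)] = nb[13];
      }
    }
  }
  return out;
}

// Per-row temporal median filter, odd window, replicate padding.
// mat: nvox x nt.
// [[Rcpp::export]]
NumericMatrix cpp_row_median(NumericMatrix mat, int window) {
  int n = mat.nrow(), nt = mat.ncol(), h = window / 2;
  NumericMatrix out(n, nt);
  std::vector<double> buf(window);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < nt; ++t) {
      for (int w = -h; w <= h; ++w) buf[w + h] = mat(i, clampi(t + w, nt));
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      out(i, t) = buf[h];
    }
  }
  return out;
}

// Per-row grayscale running max (dilate=true) or min, odd window,
// replicate padding; building block for 1-D morphological closing.
// [[Rcpp::export]]
NumericMatrix cpp_row_extremum(NumericMatrix mat, int window, bool dilate) {
  int n = mat.nrow(), nt = mat.ncol(), h = window / 2;
  NumericMatrix out(n, nt);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < nt; ++t) {
      double v = mat(i, clampi(t - h, nt));
      for (int w = -h + 1; w <= h; ++w) {
        double u = mat(i, clampi(t + w, nt));
        if (dilate ? (u > v) : (u < v)) v = u;
      }
      out(i, t) = v;
    }
  }
  return out;
}
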