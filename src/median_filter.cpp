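#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter over a 4D array (nx, ny, nz, nt): 3x3x3 spatial window plus
// the adjacent cardiac phases, truncated at array edges. Used as the local
// reference for 2*VENC phase-unwrapping jumps.
// [[Rcpp::export]]
NumericVector median_filter4(NumericVector arr, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2],
            nt = dim.size() > 3 ? dim[3] : 1;
  NumericVector out(arr.size());
  std::vector<double> buf;
  buf.reserve(81);
  const double *a = arr.begin();
  double *o = out.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny,
                 st = (R_xlen_t)nx * ny * nz;
  for (int t = 0; t < nt; ++t) {
    const int t0 = std::max(0, t - 1), t1 = std::min(nt - 1, t + 1);
    for (int k = 0; k < nz; ++k) {
      const int k0 = std::max(0, k - 1), k1 = std::min(nz - 1, k + 1);
      for (int j = 0; j < ny; ++j) {
        const int j0 = std::max(0, j - 1), j1 = std::min(ny - 1, j + 1);
        for (int i = 0; i < nx; ++i) {
          const int i0 = std::max(0, i - 1), i1 = std::min(nx - 1, i + 1);
          buf.clear();
          for (int tt = t0; tt <= t1; ++tt)
            for (int kk = k0; kk <= k1; ++kk)
              for (int jj = j0; jj <= j1; ++jj)
                for (int ii = i0; ii <= i1; ++ii)
                  buf.push_back(a[ii * sx + jj * sy + kk * sz + tt * st]);
          const size_t m = buf.size() / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.end());
          double med = buf[m];
          if (buf.size() % 2 == 0) {
            std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
            med = 0.5 * (med + buf[m - 1]);
          }
          o[i * sx + j * sy + k * sz + t * st] = med;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
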