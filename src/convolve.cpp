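#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D convolution of a 3D array along one axis with an odd-length kernel,
// replicate (nearest) boundary padding. Used for the in-plane PSF and
// motion box blur on the supersampled phantom grid; replicate padding
// keeps a uniform background exactly uniform. Each scan line is copied
// into a padded buffer so the inner loop is branch-free.

static inline void convLine(const double* buf, double* out, int len,
                            const double* kp, int kl) {
  for (int i = 0; i < len; ++i) {
    double acc = 0.0;
    const double* b = buf + i;
    for (int k = 0; k < kl; ++k) acc += kp[k] * b[k];
    out[i] = acc;
  }
}

// [[Rcpp::export(name = ".convolveAxis")]]
NumericVector convolveAxis(NumericVector x, IntegerVector dims,
                           NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size();
  const int kr = kl / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* src = REAL(x);
  double* dst = REAL(out);
  const double* kp = REAL(kernel);

  const int len = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  std::vector<double> buf(len + 2 * kr), res(len);
  double* bm = buf.data() + kr;          // buf main section

  const R_xlen_t stride = (axis == 1) ? 1
                        : (axis == 2) ? (R_xlen_t)nx
                        : (R_xlen_t)nx * ny;
  // enumerate scan lines: vary the two non-axis dimensions
  int d1, d2; R_xlen_t s1, s2;
  if (axis == 1)      { d1 = ny; s1 = nx;               d2 = nz; s2 = (R_xlen_t)nx * ny; }
  else if (axis == 2) { d1 = nx; s1 = 1;                d2 = nz; s2 = (R_xlen_t)nx * ny; }
  else                { d1 = nx; s1 = 1;                d2 = ny; s2 = (R_xlen_t)nx; }

  for (int j2 = 0; j2 < d2; ++j2)
    for (int j1 = 0; j1 < d1; ++j1) {
      const double* s = src + j1 * s1 + j2 * s2;
      double* o = dst + j1 * s1 + j2 * s2;
      if (stride == 1)
        std::copy(s, s + len, bm);
      else
        for (int i = 0; i < len; ++i) bm[i] = s[(R_xlen_t)i * stride];
      for (int k = 0; k < kr; ++k) { buf[k] = bm[0]; bm[len + k] = bm[len - 1]; }
      convLine(buf.data(), res.data(), len, kp, kl);
      if (stride == 1)
        std::copy(res.begin(), res.end(), o);
      else
        for (int i = 0; i < len; ++i) o[(R_xlen_t)i * stride] = res[i];
    }
  return out;
}
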