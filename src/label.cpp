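#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D logical array by iterative flood
// fill. Labels are assigned in scan order; relabeling by component size is
// done on the R side.

// [[Rcpp::export(name = ".label26")]]
IntegerVector label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);            // zero-initialised
  int* lab = INTEGER(out);
  std::vector<R_xlen_t> stack;
  int cur = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int zi = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p - (R_xlen_t)zi * nx * ny);
      int yi = rem / nx, xi = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = zi + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y2 = yi + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x2 = xi + dx;
            if (x2 < 0 || x2 >= nx) continue;
            if (!dx && !dy && !dz) continue;
            R_xlen_t q = (R_xlen_t)z2 * nx * ny + (R_xlen_t)y2 * nx + x2;
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return out;
}
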