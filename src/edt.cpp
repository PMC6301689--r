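#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// lower-envelope-of-parabolas), generalised to a uniform per-axis sample
// spacing so that voxel anisotropy is handled exactly. Distances are measured
// voxel-center to voxel-center in physical units (mm).

static const double INF = std::numeric_limits<double>::infinity();

// 1D transform: d[q] = min_p ( (s*(q - p))^2 + f[p] ), positions on a uniform
// grid of spacing s. Parabolas with f[p] == INF can never be minimal and are
// skipped (valid as long as at least one finite entry exists).
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double pq = s * q, fq = f[q];
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sN;
    for (;;) {
      double pv = s * v[k];
      sN = ((fq + pq * pq) - (f[v[k]] + pv * pv)) / (2.0 * (pq - pv));
      if (sN > z[k]) break;
      --k;
      if (k < 0) break;
    }
    ++k; v[k] = q; z[k] = sN; z[k + 1] = INF;
  }
  if (k < 0) {                 // no finite entry on this scan line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double pq = s * q;
    while (z[j + 1] < pq) ++j;
    double dp = pq - s * v[j];
    d[q] = dp * dp + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double* g = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass (fastest-varying index)
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      double* row = g + (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx;
      dt1d(row, d.data(), nx, spacing[0], v, z);
      for (int xi = 0; xi < nx; ++xi) row[xi] = d[xi];
    }
  // y pass
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      double* base = g + (R_xlen_t)zi * nx * ny + xi;
      for (int yi = 0; yi < ny; ++yi) f[yi] = base[(R_xlen_t)yi * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int yi = 0; yi < ny; ++yi) base[(R_xlen_t)yi * nx] = d[yi];
    }
  // z pass
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int yi = 0; yi < ny; ++yi)
    for (int xi = 0; xi < nx; ++xi) {
      double* base = g + (R_xlen_t)yi * nx + xi;
      for (int zi = 0; zi < nz; ++zi) f[zi] = base[(R_xlen_t)zi * sz];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int zi = 0; zi < nz; ++zi) base[(R_xlen_t)zi * sz] = d[zi];
    }

  for (R_xlen_t i = 0; i < n; ++i) g[i] = std::sqrt(g[i]);
  return out;
}
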