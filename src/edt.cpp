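#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing h. f holds squared distances on input.
static void dt1d(const double* f, double* d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    for (;;) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// centre of a feature voxel, on an anisotropic lattice. Axes with
// non-finite spacing are skipped, which restricts the transform to the
// remaining axes (used for radial / longitudinal margins).
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel instead of infinity so the parabola-intersection
  // arithmetic stays NaN-free on all-background lines
  const double INF = 1e35;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  std::vector<double> buf, res;
  // pass along x
  if (R_finite(spacing[0]) && nx > 1) {
    buf.resize(nx); res.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
        dt1d(buf.data(), res.data(), nx, spacing[0]);
        for (int x = 0; x < nx; ++x) out[base + x] = res[x];
      }
  }
  // pass along y
  if (R_finite(spacing[1]) && ny > 1) {
    buf.resize(ny); res.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
        dt1d(buf.data(), res.data(), ny, spacing[1]);
        for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = res[y];
      }
  }
  // pass along z
  if (R_finite(spacing[2]) && nz > 1) {
    buf.resize(nz); res.resize(nz);
    const R_xlen_t sl = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) buf[z] = out[base + sl * z];
        dt1d(buf.data(), res.data(), nz, spacing[2]);
        for (int z = 0; z < nz; ++z) out[base + sl * z] = res[z];
      }
  }
  return out;
}
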