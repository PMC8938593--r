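#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 3-D convolution with one odd-length tap vector per axis and
// zero padding outside the lattice. A length-1 tap of {1} skips the axis.
// Kernels that sum to one conserve the volume total up to boundary
// truncation, which is the behaviour blur/smearing operators rely on.
// [[Rcpp::export]]
NumericVector sep_conv3(NumericVector vol, IntegerVector dim,
                        NumericVector kx, NumericVector ky,
                        NumericVector kz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sl = (R_xlen_t)nx * ny;
  NumericVector cur(clone(vol));
  NumericVector tmp(n);

  // x axis
  if (kx.size() > 1) {
    const int h = (kx.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = sl * z + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          int t0 = std::max(0, x - h), t1 = std::min(nx - 1, x + h);
          for (int t = t0; t <= t1; ++t) s += cur[base + t] * kx[h + x - t];
          tmp[base + x] = s;
        }
      }
    std::swap(cur, tmp);
  }
  // y axis
  if (ky.size() > 1) {
    const int h = (ky.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = sl * z + x;
        for (int y = 0; y < ny; ++y) {
          double s = 0.0;
          int t0 = std::max(0, y - h), t1 = std::min(ny - 1, y + h);
          for (int t = t0; t <= t1; ++t) s += cur[base + (R_xlen_t)t * nx] * ky[h + y - t];
          tmp[base + (R_xlen_t)y * nx] = s;
        }
      }
    std::swap(cur, tmp);
  }
  // z axis
  if (kz.size() > 1) {
    const int h = (kz.size() - 1) / 2;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) {
          double s = 0.0;
          int t0 = std::max(0, z - h), t1 = std::min(nz - 1, z + h);
          for (int t = t0; t <= t1; ++t) s += cur[base + sl * t] * kz[h + z - t];
          tmp[base + sl * z] = s;
        }
      }
    std::swap(cur, tmp);
  }
  return cur;
}
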