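#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double ME = 0.510999;   // electron rest mass, MeV
static const double X0 = 360.8;      // radiation length of water, mm

// linear interpolation on a strictly increasing grid, linear through the
// origin below the first point (sub-grid electrons are sub-micron range)
static double interp_inc(const std::vector<double>& x,
                         const std::vector<double>& y, double xi) {
  const int n = (int)x.size();
  if (xi <= x[0]) return y[0] * (xi / x[0]);
  if (xi >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; if (x[m] <= xi) lo = m; else hi = m; }
  double t = (xi - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + t * (y[hi] - y[lo]);
}

struct Particle { double px, py, pz, ux, uy, uz, E; };

// Moller factor g(eps) with eps = W / E (delta kinetic over primary kinetic)
static double moller_g(double eps, double tau) {
  double t1 = tau / (tau + 1.0);
  double t2 = (2.0 * tau + 1.0) / ((tau + 1.0) * (tau + 1.0));
  return 1.0 / (eps * eps) + 1.0 / ((1.0 - eps) * (1.0 - eps)) + t1 * t1 -
         t2 / (eps * (1.0 - eps));
}

// Condensed-history beta transport in a voxelized water sphere: source
// uniform in the origin voxel, restricted continuous energy loss from a
// range-energy table, explicit Moller delta-ray production above `w_min`
// (secondaries transported like primaries), optional Highland multiple
// scattering per step, energy scored at segment midpoints. Deposits with
// the carrier beyond `rmax` of the origin are dropped (water sphere
// surrounded by air). Returns energy in MeV per voxel plus per-batch
// central-voxel energies for uncertainty estimation.
// [[Rcpp::export]]
List dvk_transport(IntegerVector dim, NumericVector spacing,
                   int histories, int nbatch,
                   NumericVector e_tab, NumericVector r_tab,
                   NumericVector sigma_tab, NumericVector cdf_energy,
                   bool scatter, bool deltas, double w_min,
                   double rmax, double step_max_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const int cx = (nx - 1) / 2, cy = (ny - 1) / 2, cz = (nz - 1) / 2;
  const R_xlen_t sl = (R_xlen_t)nx * ny;
  const R_xlen_t cidx = (R_xlen_t)cz * sl + (R_xlen_t)cy * nx + cx;
  NumericVector energy((R_xlen_t)nx * ny * nz);
  NumericVector central_batch(nbatch);

  std::vector<double> et(e_tab.begin(), e_tab.end());
  std::vector<double> rt(r_tab.begin(), r_tab.end());
  std::vector<double> st(sigma_tab.begin(), sigma_tab.end());
  std::vector<double> cdf(cdf_energy.begin(), cdf_energy.end());
  const int ncdf = (int)cdf.size();

  const double step_max =
      std::min(std::min(0.5 * std::min(dx, std::min(dy, dz)), 1.0), step_max_mm);
  const double rmax2 = rmax * rmax;
  const double e_floor = 1e-3;  // 1 keV transport cut-off

  double cacc = 0.0;
  // deposit `ed` at point (x,y,z), track central-voxel share
  auto deposit = [&](double x, double y, double z, double ed) {
    if (x * x + y * y + z * z > rmax2) return;
    int ix = (int)std::floor(x / dx + 0.5) + cx;
    int iy = (int)std::floor(y / dy + 0.5) + cy;
    int iz = (int)std::floor(z / dz + 0.5) + cz;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) return;
    R_xlen_t idx = (R_xlen_t)iz * sl + (R_xlen_t)iy * nx + ix;
    energy[idx] += ed;
    if (idx == cidx) cacc += ed;
  };

  RNGScope scope;
  int per_batch = histories / nbatch;
  if (per_batch < 1) { per_batch = histories; nbatch = 1; }
  std::vector<Particle> stack;
  stack.reserve(64);

  for (int b = 0; b < nbatch; ++b) {
    cacc = 0.0;
    for (int h = 0; h < per_batch; ++h) {
      // primary: energy from the inverse-CDF table, position uniform in
      // the origin voxel, isotropic emission
      double u = unif_rand() * (ncdf - 1);
      int iu = (int)u; if (iu >= ncdf - 1) iu = ncdf - 2;
      Particle prim;
      prim.E = cdf[iu] + (u - iu) * (cdf[iu + 1] - cdf[iu]);
      prim.px = (unif_rand() - 0.5) * dx;
      prim.py = (unif_rand() - 0.5) * dy;
      prim.pz = (unif_rand() - 0.5) * dz;
      double cz0 = 2.0 * unif_rand() - 1.0;
      double sz0 = std::sqrt(std::max(0.0, 1.0 - cz0 * cz0));
      double ph0 = 2.0 * M_PI * unif_rand();
      prim.ux = sz0 * std::cos(ph0); prim.uy = sz0 * std::sin(ph0);
      prim.uz = cz0;
      stack.push_back(prim);

      while (!stack.empty()) {
        Particle p = stack.back();
        stack.pop_back();
        while (p.E > e_floor) {
          double range = interp_inc(et, rt, p.E);
          double ds = std::min(step_max, range);
          double e1 = (ds >= range) ? 0.0 : interp_inc(rt, et, range - ds);
          double edep = p.E - e1;
          deposit(p.px + p.ux * ds * 0.5, p.py + p.uy * ds * 0.5,
                  p.pz + p.uz * ds * 0.5, edep);
          p.px += p.ux * ds; p.py += p.uy * ds; p.pz += p.uz * ds;
          p.E = e1;
          if (p.E <= e_floor) break;
          // Moller delta production above w_min
          if (deltas && p.E > 2.0 * w_min) {
            double sig = interp_inc(et, st, p.E);  // interactions per mm
            int n_int = (int)R::rpois(sig * ds);
            for (int d = 0; d < n_int && p.E > 2.0 * w_min; ++d) {
              double e_pre = p.E;
              double tau = e_pre / ME;
              double ec = w_min / e_pre;
              double W, eps;
              for (;;) {  // sample eps from 1/eps^2 majorant, reject to g
                double u1 = unif_rand();
                eps = ec / (1.0 - u1 * (1.0 - 2.0 * ec));
                if (eps >= 0.5) eps = 0.5 - 1e-12;
                double ratio = moller_g(eps, tau) * eps * eps / 2.5;
                if (unif_rand() < ratio) break;
              }
              W = eps * e_pre;
              // delta emission angle from free-electron kinematics
              double cth2 = W * (e_pre + 2.0 * ME) / (e_pre * (W + 2.0 * ME));
              double cth = std::sqrt(std::min(cth2, 1.0));
              double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
              double dphi = 2.0 * M_PI * unif_rand();
              Particle sec;
              sec.px = p.px; sec.py = p.py; sec.pz = p.pz; sec.E = W;
              double cp = std::cos(dphi), sp = std::sin(dphi);
              if (std::fabs(p.uz) > 0.99999) {
                sec.ux = sth * cp; sec.uy = sth * sp;
                sec.uz = (p.uz > 0 ? cth : -cth);
              } else {
                double den = std::sqrt(1.0 - p.uz * p.uz);
                sec.ux = p.ux * cth + sth * (p.ux * p.uz * cp - p.uy * sp) / den;
                sec.uy = p.uy * cth + sth * (p.uy * p.uz * cp + p.ux * sp) / den;
                sec.uz = p.uz * cth - den * sth * cp;
              }
              stack.push_back(sec);
              p.E -= W;  // discrete loss; primary deflection neglected
            }
          }
          // Highland multiple scattering over the step
          if (scatter) {
            double E2 = std::max(p.E, 1e-4);
            double pc = std::sqrt(E2 * (E2 + 2.0 * ME));
            double beta = pc / (E2 + ME);
            double corr = 1.0 + 0.038 * std::log(ds / X0);
            if (corr < 0.25) corr = 0.25;
            double th0 = 13.6 / (beta * pc) * std::sqrt(ds / X0) * corr;
            double gx = norm_rand() * th0, gy = norm_rand() * th0;
            double theta = std::sqrt(gx * gx + gy * gy);
            double phi = 2.0 * M_PI * unif_rand();
            double ct = std::cos(theta), stn = std::sin(theta);
            double cp = std::cos(phi), sp = std::sin(phi);
            if (std::fabs(p.uz) > 0.99999) {
              p.ux = stn * cp; p.uy = stn * sp;
              p.uz = (p.uz > 0 ? ct : -ct);
            } else {
              double den = std::sqrt(1.0 - p.uz * p.uz);
              double nux = p.ux * ct + stn * (p.ux * p.uz * cp - p.uy * sp) / den;
              double nuy = p.uy * ct + stn * (p.uy * p.uz * cp + p.ux * sp) / den;
              double nuz = p.uz * ct - den * stn * cp;
              p.ux = nux; p.uy = nuy; p.uz = nuz;
            }
            double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
            p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
          }
        }
        if (p.E > 0) deposit(p.px, p.py, p.pz, p.E);
      }
    }
    central_batch[b] = cacc;
  }
  return List::create(_["energy"] = energy,
                      _["central_batch"] = central_batch,
                      _["histories"] = per_batch * nbatch);
}
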