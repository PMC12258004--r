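// Backward (pull) trilinear warping of volumes with displacement vector
// fields, fixed-point DVF inversion, and DVF composition.
//
// DVFs are stored as (nx, ny, nz, 3) arrays in mm, components ordered
// (x, y, z), defined on the target state's grid: out(r) = vol(r + u(r)).
// Out-of-range samples are edge-clamped (replicate), which avoids
// introducing a zero rim into single-angle reconstructions before they
// are summed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// edge-clamped trilinear sample in voxel index space
static inline double tri_clamp(const double* v, int nx, int ny, int nz,
                               double fx, double fy, double fz) {
  fx = clampd(fx, 0.0, nx - 1.0);
  fy = clampd(fy, 0.0, ny - 1.0);
  fz = clampd(fz, 0.0, nz - 1.0);
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  if (ix >= nx - 1) ix = nx > 1 ? nx - 2 : 0;
  if (iy >= ny - 1) iy = ny > 1 ? ny - 2 : 0;
  if (iz >= nz - 1) iz = nz > 1 ? nz - 2 : 0;
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  int x1 = nx > 1 ? ix + 1 : ix, y1 = ny > 1 ? iy + 1 : iy, z1 = nz > 1 ? iz + 1 : iz;
  size_t sxy = (size_t)nx * ny;
  double c000 = v[(size_t)iz * sxy + (size_t)iy * nx + ix];
  double c100 = v[(size_t)iz * sxy + (size_t)iy * nx + x1];
  double c010 = v[(size_t)iz * sxy + (size_t)y1 * nx + ix];
  double c110 = v[(size_t)iz * sxy + (size_t)y1 * nx + x1];
  double c001 = v[(size_t)z1 * sxy + (size_t)iy * nx + ix];
  double c101 = v[(size_t)z1 * sxy + (size_t)iy * nx + x1];
  double c011 = v[(size_t)z1 * sxy + (size_t)y1 * nx + ix];
  double c111 = v[(size_t)z1 * sxy + (size_t)y1 * nx + x1];
  double c00 = c000 * (1 - wx) + c100 * wx;
  double c10 = c010 * (1 - wx) + c110 * wx;
  double c01 = c001 * (1 - wx) + c101 * wx;
  double c11 = c011 * (1 - wx) + c111 * wx;
  return (c00 * (1 - wy) + c10 * wy) * (1 - wz) + (c01 * (1 - wy) + c11 * wy) * wz;
}

// [[Rcpp::export(name = ".cpp_warp")]]
NumericVector cpp_warp(NumericVector vol, NumericVector dvf, double voxel_size) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(Dimension(nx, ny, nz));
  const double* v = REAL(vol);
  const double* u = REAL(dvf);
  double* o = REAL(out);
  size_t idx = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double fx = kx + u[idx] / voxel_size;
        double fy = ky + u[idx + nvox] / voxel_size;
        double fz = kz + u[idx + 2 * nvox] / voxel_size;
        o[idx] = tri_clamp(v, nx, ny, nz, fx, fy, fz);
      }
  return out;
}

// sample a DVF (edge-clamped) at displaced positions: out_c(r) = u_c(r + d(r))
static void sample_dvf(const double* u, int nx, int ny, int nz, double vs,
                       const double* d, double* out) {
  size_t nvox = (size_t)nx * ny * nz;
  size_t idx = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double fx = kx + d[idx] / vs;
        double fy = ky + d[idx + nvox] / vs;
        double fz = kz + d[idx + 2 * nvox] / vs;
        for (int c = 0; c < 3; ++c)
          out[idx + c * nvox] = tri_clamp(u + c * nvox, nx, ny, nz, fx, fy, fz);
      }
}

// fixed-point inversion: u_hat(r) = -u(r + u_hat(r))
// [[Rcpp::export(name = ".cpp_invert_dvf")]]
List cpp_invert_dvf(NumericVector dvf, double voxel_size, double tol, int max_iter) {
  IntegerVector dim = dvf.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> uh(3 * nvox, 0.0), samp(3 * nvox);
  const double* u = REAL(dvf);
  double max_upd = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    sample_dvf(u, nx, ny, nz, voxel_size, uh.data(), samp.data());
    max_upd = 0.0;
    for (size_t i = 0; i < 3 * nvox; ++i) {
      double nu_ = -samp[i];
      double d = std::fabs(nu_ - uh[i]);
      if (d > max_upd) max_upd = d;
      uh[i] = nu_;
    }
    if (max_upd < tol) { ++it; break; }
  }
  NumericVector out((size_t)nx * ny * nz * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  std::copy(uh.begin(), uh.end(), REAL(out));
  return List::create(_["dvf"] = out, _["iterations"] = it,
                      _["residual"] = max_upd, _["converged"] = max_upd < tol);
}

// composition residual u(r + u_hat(r)) + u_hat(r) (for inversion QC)
// [[Rcpp::export(name = ".cpp_compose_dvf")]]
NumericVector cpp_compose_dvf(NumericVector u_outer, NumericVector u_inner,
                              double voxel_size) {
  IntegerVector dim = u_outer.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out((size_t)nx * ny * nz * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  std::vector<double> samp(3 * nvox);
  sample_dvf(REAL(u_outer), nx, ny, nz, voxel_size, REAL(u_inner), samp.data());
  double* o = REAL(out);
  const double* ui = REAL(u_inner);
  for (size_t i = 0; i < 3 * nvox; ++i) o[i] = samp[i] + ui[i];
  return out;
}
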