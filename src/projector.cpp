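// Cone-beam forward projector (ray-driven, trilinear gather) and
// backprojectors: the exact scatter adjoint of the projector (used by the
// SART-type modified-SAR update) and the voxel-driven distance-weighted
// FDK backprojector (used for filtered single-angle reconstructions).
//
// Conventions:
//   - world coordinates in mm, isocenter at (0,0,0), z = rotation axis
//   - view angle = source azimuth, counter-clockwise from +x
//   - e_w = (cos b, sin b, 0), e_u = (-sin b, cos b, 0), e_v = (0,0,1)
//   - source at sid * e_w; detector plane at distance sdd from the source,
//     physical detector coordinate u measured from the principal ray,
//     u(iu) = (iu - (nu-1)/2) * du + offset_u
//   - volumes are R arrays dim (nx, ny, nz), x fastest; frames are
//     (nu, nv) matrices stacked into (nu, nv, nviews)
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Grid {
  int nx, ny, nz;
  double vs;          // isotropic voxel size, mm
  double ox, oy, oz;  // world coordinate of voxel (0,0,0) center
};

static Grid as_grid(const List& g) {
  Grid gr;
  gr.nx = as<int>(g["nx"]); gr.ny = as<int>(g["ny"]); gr.nz = as<int>(g["nz"]);
  gr.vs = as<double>(g["voxel_size"]);
  NumericVector o = g["origin"];
  gr.ox = o[0]; gr.oy = o[1]; gr.oz = o[2];
  return gr;
}

// trilinear gather with zero outside the volume
static inline double tri_sample(const double* v, const Grid& g,
                                double x, double y, double z) {
  double fx = (x - g.ox) / g.vs, fy = (y - g.oy) / g.vs, fz = (z - g.oz) / g.vs;
  if (fx < -1.0 || fx > g.nx || fy < -1.0 || fy > g.ny || fz < -1.0 || fz > g.nz)
    return 0.0;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int kz = iz + dz;
    if (kz < 0 || kz >= g.nz) continue;
    double wwz = dz ? wz : 1.0 - wz;
    for (int dy = 0; dy < 2; ++dy) {
      int ky = iy + dy;
      if (ky < 0 || ky >= g.ny) continue;
      double wwy = dy ? wy : 1.0 - wy;
      for (int dx = 0; dx < 2; ++dx) {
        int kx = ix + dx;
        if (kx < 0 || kx >= g.nx) continue;
        double wwx = dx ? wx : 1.0 - wx;
        acc += wwx * wwy * wwz * v[(size_t)kz * g.nx * g.ny + (size_t)ky * g.nx + kx];
      }
    }
  }
  return acc;
}

// trilinear scatter (adjoint of tri_sample)
static inline void tri_scatter(double* v, const Grid& g,
                               double x, double y, double z, double val) {
  double fx = (x - g.ox) / g.vs, fy = (y - g.oy) / g.vs, fz = (z - g.oz) / g.vs;
  if (fx < -1.0 || fx > g.nx || fy < -1.0 || fy > g.ny || fz < -1.0 || fz > g.nz)
    return;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  for (int dz = 0; dz < 2; ++dz) {
    int kz = iz + dz;
    if (kz < 0 || kz >= g.nz) continue;
    double wwz = dz ? wz : 1.0 - wz;
    for (int dy = 0; dy < 2; ++dy) {
      int ky = iy + dy;
      if (ky < 0 || ky >= g.ny) continue;
      double wwy = dy ? wy : 1.0 - wy;
      for (int dx = 0; dx < 2; ++dx) {
        int kx = ix + dx;
        if (kx < 0 || kx >= g.nx) continue;
        double wwx = dx ? wx : 1.0 - wx;
        v[(size_t)kz * g.nx * g.ny + (size_t)ky * g.nx + kx] += wwx * wwy * wwz * val;
      }
    }
  }
}

// intersection of ray p = s + t*d with the volume bounding box (voxel centers
// padded by one voxel so boundary interpolation is included)
static inline bool bbox_clip(const Grid& g, const double s[3], const double d[3],
                             double& t0, double& t1) {
  double lo[3] = { g.ox - g.vs, g.oy - g.vs, g.oz - g.vs };
  double hi[3] = { g.ox + g.nx * g.vs, g.oy + g.ny * g.vs, g.oz + g.nz * g.vs };
  t0 = 0.0; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (s[a] < lo[a] || s[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - s[a]) / d[a], tb = (hi[a] - s[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericVector cpp_forward_project(NumericVector vol, List grid, List geom,
                                  IntegerVector view_idx, double step) {
  Grid g = as_grid(grid);
  double sid = as<double>(geom["sid"]), sdd = as<double>(geom["sdd"]);
  int nu = as<int>(geom["n_u"]), nv = as<int>(geom["n_v"]);
  double du = as<double>(geom["pixel_u"]), dv = as<double>(geom["pixel_v"]);
  double off = as<double>(geom["detector_offset_u"]);
  NumericVector angles = geom["angles"];
  int nviews = view_idx.size();
  NumericVector out(Dimension(nu, nv, nviews));
  const double* v = REAL(vol);
  double* po = REAL(out);

  for (int k = 0; k < nviews; ++k) {
    int iv = view_idx[k];
    double b = angles[iv];
    double cb = std::cos(b), sb = std::sin(b);
    double s[3] = { sid * cb, sid * sb, 0.0 };
    // detector center of principal ray: source + sdd * (-e_w)
    for (int jv = 0; jv < nv; ++jv) {
      double vmm = (jv - (nv - 1) / 2.0) * dv;
      for (int ju = 0; ju < nu; ++ju) {
        double umm = (ju - (nu - 1) / 2.0) * du + off;
        // pixel world position
        double px = s[0] - sdd * cb - umm * sb;
        double py = s[1] - sdd * sb + umm * cb;
        double pz = vmm;
        double d[3] = { px - s[0], py - s[1], pz - s[2] };
        double len = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= len; d[1] /= len; d[2] /= len;
        double t0, t1, acc = 0.0;
        if (bbox_clip(g, s, d, t0, t1)) {
          int ns = (int)std::ceil((t1 - t0) / step);
          if (ns < 1) ns = 1;
          double dt = (t1 - t0) / ns;
          for (int m = 0; m < ns; ++m) {
            double t = t0 + (m + 0.5) * dt;
            acc += tri_sample(v, g, s[0] + t * d[0], s[1] + t * d[1], s[2] + t * d[2]);
          }
          acc *= dt;
        }
        po[(size_t)k * nu * nv + (size_t)jv * nu + ju] = acc;
      }
    }
  }
  return out;
}

// exact adjoint of cpp_forward_project (same ray marching, scatter)
// [[Rcpp::export(name = ".cpp_backproject_adjoint")]]
NumericVector cpp_backproject_adjoint(NumericVector frames, List grid, List geom,
                                      IntegerVector view_idx, double step) {
  Grid g = as_grid(grid);
  double sid = as<double>(geom["sid"]), sdd = as<double>(geom["sdd"]);
  int nu = as<int>(geom["n_u"]), nv = as<int>(geom["n_v"]);
  double du = as<double>(geom["pixel_u"]), dv = as<double>(geom["pixel_v"]);
  double off = as<double>(geom["detector_offset_u"]);
  NumericVector angles = geom["angles"];
  int nviews = view_idx.size();
  NumericVector out(Dimension(g.nx, g.ny, g.nz));
  double* v = REAL(out);
  const double* pf = REAL(frames);

  for (int k = 0; k < nviews; ++k) {
    int ivw = view_idx[k];
    double b = angles[ivw];
    double cb = std::cos(b), sb = std::sin(b);
    double s[3] = { sid * cb, sid * sb, 0.0 };
    for (int jv = 0; jv < nv; ++jv) {
      double vmm = (jv - (nv - 1) / 2.0) * dv;
      for (int ju = 0; ju < nu; ++ju) {
        double val = pf[(size_t)k * nu * nv + (size_t)jv * nu + ju];
        if (val == 0.0) continue;
        double umm = (ju - (nu - 1) / 2.0) * du + off;
        double px = s[0] - sdd * cb - umm * sb;
        double py = s[1] - sdd * sb + umm * cb;
        double pz = vmm;
        double d[3] = { px - s[0], py - s[1], pz - s[2] };
        double len = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= len; d[1] /= len; d[2] /= len;
        double t0, t1;
        if (!bbox_clip(g, s, d, t0, t1)) continue;
        int ns = (int)std::ceil((t1 - t0) / step);
        if (ns < 1) ns = 1;
        double dt = (t1 - t0) / ns;
        double w = val * dt;
        for (int m = 0; m < ns; ++m) {
          double t = t0 + (m + 0.5) * dt;
          tri_scatter(v, g, s[0] + t * d[0], s[1] + t * d[1], s[2] + t * d[2], w);
        }
      }
    }
  }
  return out;
}

// Voxel-driven distance-weighted FDK backprojection of (already filtered and
// weighted) frames. view_weight holds the per-view angular weight (rad).
// Frame pixels are addressed in isocenter-scaled detector coordinates.
// [[Rcpp::export(name = ".cpp_backproject_fdk")]]
NumericVector cpp_backproject_fdk(NumericVector frames, List grid, List geom,
                                  IntegerVector view_idx, NumericVector view_weight) {
  Grid g = as_grid(grid);
  double sid = as<double>(geom["sid"]), sdd = as<double>(geom["sdd"]);
  int nu = as<int>(geom["n_u"]), nv = as<int>(geom["n_v"]);
  double du = as<double>(geom["pixel_u"]), dv = as<double>(geom["pixel_v"]);
  double off = as<double>(geom["detector_offset_u"]);
  NumericVector angles = geom["angles"];
  double mag = sdd / sid;
  double tau_u = du / mag, tau_v = dv / mag, off_iso = off / mag;
  int nviews = view_idx.size();
  NumericVector out(Dimension(g.nx, g.ny, g.nz));
  double* v = REAL(out);
  const double* pf = REAL(frames);

  for (int k = 0; k < nviews; ++k) {
    int ivw = view_idx[k];
    double b = angles[ivw];
    double cb = std::cos(b), sb = std::sin(b);
    double wk = view_weight[k];
    const double* fr = pf + (size_t)k * nu * nv;
    size_t idx = 0;
    for (int kz = 0; kz < g.nz; ++kz) {
      double z = g.oz + kz * g.vs;
      for (int ky = 0; ky < g.ny; ++ky) {
        double y = g.oy + ky * g.vs;
        for (int kx = 0; kx < g.nx; ++kx, ++idx) {
          double x = g.ox + kx * g.vs;
          double U = sid - (x * cb + y * sb);
          if (U < 1e-3) continue;
          double ubar = sid * (-x * sb + y * cb) / U;
          double vbar = sid * z / U;
          double fu = (ubar - off_iso) / tau_u + (nu - 1) / 2.0;
          double fv = vbar / tau_v + (nv - 1) / 2.0;
          if (fu < 0.0 || fu > nu - 1.0 || fv < 0.0 || fv > nv - 1.0) continue;
          int iu = (int)std::floor(fu), iv2 = (int)std::floor(fv);
          if (iu >= nu - 1) iu = nu - 2;
          if (iv2 >= nv - 1) iv2 = nv - 2;
          double wu = fu - iu, wv = fv - iv2;
          double f00 = fr[(size_t)iv2 * nu + iu];
          double f10 = fr[(size_t)iv2 * nu + iu + 1];
          double f01 = fr[(size_t)(iv2 + 1) * nu + iu];
          double f11 = fr[(size_t)(iv2 + 1) * nu + iu + 1];
          double val = (1 - wv) * ((1 - wu) * f00 + wu * f10) +
                       wv * ((1 - wu) * f01 + wu * f11);
          v[idx] += wk * (sid * sid) / (U * U) * val;
        }
      }
    }
  }
  return out;
}
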