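// Analytic deformable thorax phantom.
//
// The anatomy is defined by geometric primitives in a reference
// configuration (end-exhale). Breathing is modelled as a one-parameter
// family of invertible pull maps phi_a acting on current coordinates,
//   phi_a(x,y,z) = (x, y + a*h(y), z + a*g(x,y)*psi(z)),
// so that the motion state with amplitude a is f_a(r) = f0(phi_a(r)).
// g is a lateral raised-cosine envelope (small at the chest wall, so ribs
// stay nearly static), psi decays from 1 below the diaphragm to 0 at the
// lung apex (superior-inferior displacement decaying toward the apex),
// and h is a mild anterior-posterior chest expansion. Because each
// component is a monotone 1-D map, phi_a can be inverted per voxel with a
// few Newton steps, which makes the displacement field between ANY two
// amplitudes exact:
//   u_{src->tgt}(r) = phi_{a_src}^{-1}(phi_{a_tgt}(r)) - r,
// i.e. f_src(r + u(r)) = f_tgt(r) holds analytically.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Thorax {
  double body_ax, body_ay, body_az; int body_zexp;
  double env_cx, env_cy, env_ax, env_ay, env_flat;
  double psi_zbase, psi_zapex;
  double ap_frac, ap_y0;
  double dome_cx, dome_cy, dome_z, dome_R;
  double dia_thick, dia_rad;
  double lung_c[2][3], lung_s[2][3];
  double heart_c[3], heart_s[3];
  double rib_rho, rib_th, rib_z0, rib_dz, rib_half, rib_zmin, rib_zmax, rib_gap;
  std::vector<double> nod;  // rows of (cx, cy, cz, r)
  int n_nod;
  double hu_body, hu_lung, hu_heart, hu_dia, hu_rib, hu_nodule, hu_air;
  double edge_mm;
};

static Thorax as_thorax(const List& p) {
  Thorax t;
  t.body_ax = as<double>(p["body_ax"]); t.body_ay = as<double>(p["body_ay"]);
  t.body_az = as<double>(p["body_az"]); t.body_zexp = as<int>(p["body_zexp"]);
  t.env_cx = as<double>(p["env_cx"]); t.env_cy = as<double>(p["env_cy"]);
  t.env_ax = as<double>(p["env_ax"]); t.env_ay = as<double>(p["env_ay"]);
  t.env_flat = as<double>(p["env_flat"]);
  t.psi_zbase = as<double>(p["psi_zbase"]); t.psi_zapex = as<double>(p["psi_zapex"]);
  t.ap_frac = as<double>(p["ap_frac"]); t.ap_y0 = as<double>(p["ap_y0"]);
  t.dome_cx = as<double>(p["dome_cx"]); t.dome_cy = as<double>(p["dome_cy"]);
  t.dome_z = as<double>(p["dome_z"]); t.dome_R = as<double>(p["dome_R"]);
  t.dia_thick = as<double>(p["dia_thick"]); t.dia_rad = as<double>(p["dia_rad"]);
  NumericMatrix lc = p["lung_c"], ls = p["lung_s"];
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 3; ++j) {
    t.lung_c[i][j] = lc(i, j); t.lung_s[i][j] = ls(i, j);
  }
  NumericVector hc = p["heart_c"], hs = p["heart_s"];
  for (int j = 0; j < 3; ++j) { t.heart_c[j] = hc[j]; t.heart_s[j] = hs[j]; }
  t.rib_rho = as<double>(p["rib_rho"]); t.rib_th = as<double>(p["rib_th"]);
  t.rib_z0 = as<double>(p["rib_z0"]); t.rib_dz = as<double>(p["rib_dz"]);
  t.rib_half = as<double>(p["rib_half"]);
  t.rib_zmin = as<double>(p["rib_zmin"]); t.rib_zmax = as<double>(p["rib_zmax"]);
  t.rib_gap = as<double>(p["rib_gap"]);
  NumericMatrix nm = p["nodules"];
  t.n_nod = nm.nrow();
  t.nod.resize(4 * t.n_nod);
  for (int i = 0; i < t.n_nod; ++i)
    for (int j = 0; j < 4; ++j) t.nod[4 * i + j] = nm(i, j);
  t.hu_body = as<double>(p["hu_body"]); t.hu_lung = as<double>(p["hu_lung"]);
  t.hu_heart = as<double>(p["hu_heart"]); t.hu_dia = as<double>(p["hu_dia"]);
  t.hu_rib = as<double>(p["hu_rib"]); t.hu_nodule = as<double>(p["hu_nodule"]);
  t.hu_air = as<double>(p["hu_air"]);
  t.edge_mm = as<double>(p["edge_mm"]);
  return t;
}

// ---- breathing map components -------------------------------------------
static inline double env_g(const Thorax& t, double x, double y) {
  // flat core (full displacement over the diaphragm dome), raised-cosine
  // decay toward the chest wall so ribs stay nearly static
  double rx = (x - t.env_cx) / t.env_ax, ry = (y - t.env_cy) / t.env_ay;
  double rho = std::sqrt(rx * rx + ry * ry);
  if (rho <= t.env_flat) return 1.0;
  if (rho >= 1.0) return 0.0;
  double c = std::cos(M_PI_2 * (rho - t.env_flat) / (1.0 - t.env_flat));
  return c * c;
}
static inline double psi_z(const Thorax& t, double z) {
  if (z <= t.psi_zbase) return 1.0;
  if (z >= t.psi_zapex) return 0.0;
  double c = std::cos(M_PI_2 * (z - t.psi_zbase) / (t.psi_zapex - t.psi_zbase));
  return c * c;
}
static inline double dpsi_z(const Thorax& t, double z) {
  if (z <= t.psi_zbase || z >= t.psi_zapex) return 0.0;
  double L = t.psi_zapex - t.psi_zbase;
  double th = M_PI_2 * (z - t.psi_zbase) / L;
  return -M_PI_2 / L * std::sin(2.0 * th);
}
static inline double ap_h(const Thorax& t, double y) {
  double y1 = t.body_ay;
  if (y <= t.ap_y0) return 0.0;
  double s = (y - t.ap_y0) / (y1 - t.ap_y0);
  if (s > 1.0) s = 1.0;
  return -t.ap_frac * s * s * (3.0 - 2.0 * s);
}
static inline double dap_h(const Thorax& t, double y) {
  double y1 = t.body_ay;
  if (y <= t.ap_y0 || y >= y1) return 0.0;
  double s = (y - t.ap_y0) / (y1 - t.ap_y0);
  return -t.ap_frac * 6.0 * s * (1.0 - s) / (y1 - t.ap_y0);
}

// forward map: current coordinates -> reference coordinates
static inline void phi_fwd(const Thorax& t, double a,
                           double x, double y, double z,
                           double& xr, double& yr, double& zr) {
  xr = x;
  yr = y + a * ap_h(t, y);
  zr = z + a * env_g(t, x, y) * psi_z(t, z);
}

// inverse map: reference coordinates -> current coordinates (Newton, 1-D each)
static inline void phi_inv(const Thorax& t, double a,
                           double xr, double yr, double zr,
                           double& x, double& y, double& z) {
  x = xr;
  if (a == 0.0) { y = yr; z = zr; return; }
  y = yr;
  for (int it = 0; it < 30; ++it) {
    double f = y + a * ap_h(t, y) - yr;
    if (std::fabs(f) < 1e-9) break;
    y -= f / (1.0 + a * dap_h(t, y));
  }
  double ag = a * env_g(t, x, y);
  z = zr;
  if (ag != 0.0) {
    for (int it = 0; it < 40; ++it) {
      double f = z + ag * psi_z(t, z) - zr;
      if (std::fabs(f) < 1e-9) break;
      double der = 1.0 + ag * dpsi_z(t, z);
      if (der < 0.05) der = 0.05;  // safeguarded Newton
      z -= f / der;
    }
  }
}

// ---- anatomy in the reference configuration -----------------------------
static inline double alpha_d(double d, double w) {
  // soft membership: 1 inside (d < -w/2), 0 outside (d > w/2)
  double a = 0.5 - d / w;
  return a < 0.0 ? 0.0 : (a > 1.0 ? 1.0 : a);
}
// first-order signed distance (F - 1) / |grad F| for implicit F(r) = 1
static inline double sd_ellipsoid(double x, double y, double z,
                                  const double c[3], const double s[3]) {
  double ux = (x - c[0]) / s[0], uy = (y - c[1]) / s[1], uz = (z - c[2]) / s[2];
  double F = ux * ux + uy * uy + uz * uz;
  double gx = 2 * ux / s[0], gy = 2 * uy / s[1], gz = 2 * uz / s[2];
  double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
  if (gn < 1e-9) gn = 1e-9;
  return (F - 1.0) / gn;
}
static inline double sd_body(const Thorax& t, double x, double y, double z) {
  double ux = x / t.body_ax, uy = y / t.body_ay, uz = z / t.body_az;
  double p = 1.0;
  for (int i = 0; i < t.body_zexp; ++i) p *= uz;
  if (t.body_zexp % 2 == 1) p = std::fabs(p);  // even exponent expected
  double F = ux * ux + uy * uy + p;
  double gx = 2 * ux / t.body_ax, gy = 2 * uy / t.body_ay;
  double gz = t.body_zexp * (uz == 0.0 ? 0.0 : p / uz) / t.body_az;
  double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
  if (gn < 1e-9) gn = 1e-9;
  return (F - 1.0) / gn;
}
static inline double dome_z_of(const Thorax& t, double x, double y) {
  double dx = x - t.dome_cx, dy = y - t.dome_cy;
  return t.dome_z - (dx * dx + dy * dy) / (2.0 * t.dome_R);
}

// evaluate HU (smooth blend) and label (hard, highest priority wins) at a
// reference-configuration point
static inline void anatomy_eval(const Thorax& t, double x, double y, double z,
                                double& hu, int& label) {
  double w = t.edge_mm;
  double db = sd_body(t, x, y, z);
  double ab = alpha_d(db, w);
  hu = t.hu_air + ab * (t.hu_body - t.hu_air);
  label = db < 0.0 ? 6 : 0;
  if (ab <= 0.0) return;

  double zd = dome_z_of(t, x, y);
  // lungs: two ellipsoids clipped to the region above the diaphragm dome
  double a_lung = 0.0;
  for (int i = 0; i < 2; ++i) {
    double d = sd_ellipsoid(x, y, z, t.lung_c[i], t.lung_s[i]);
    double al = alpha_d(d, w) * alpha_d(zd - z, w);
    if (al > a_lung) a_lung = al;
  }
  a_lung *= ab;
  hu = hu + a_lung * (t.hu_lung - hu);
  if (a_lung > 0.5) label = 1;

  // heart
  double dh = sd_ellipsoid(x, y, z, t.heart_c, t.heart_s);
  double ah = alpha_d(dh, w) * ab;
  hu = hu + ah * (t.hu_heart - hu);
  if (ah > 0.5) label = 3;

  // diaphragm: dome-following band of thickness dia_thick below the dome
  double ddx = x - t.dome_cx, ddy = y - t.dome_cy;
  double rlat = std::sqrt(ddx * ddx + ddy * ddy);
  double a_dia = alpha_d(z - zd, w) * alpha_d((zd - t.dia_thick) - z, w) *
                 alpha_d(rlat - t.dia_rad, w) * ab;
  hu = hu + a_dia * (t.hu_dia - hu);
  if (a_dia > 0.5) label = 5;

  // ribs: thin bands on an elliptical shell, periodic in z, anterior gap
  if (z > t.rib_zmin && z < t.rib_zmax) {
    double rx = x / (t.rib_rho * t.body_ax), ry = y / (t.rib_rho * t.body_ay);
    double rho = std::sqrt(rx * rx + ry * ry);
    double rxy = std::sqrt(x * x + y * y);
    double d_shell = std::fabs(rho - 1.0) * (rho > 1e-6 ? rxy / rho : 1.0) - t.rib_th;
    double zz = z - t.rib_z0;
    double k = std::floor(zz / t.rib_dz + 0.5);
    double d_z = std::fabs(zz - k * t.rib_dz) - t.rib_half;
    double theta = std::atan2(x, y);  // 0 at anterior (+y)
    bool in_gap = std::fabs(theta) < t.rib_gap;
    if (!in_gap) {
      double a_rib = alpha_d(d_shell, w) * alpha_d(d_z, w) * ab;
      hu = hu + a_rib * (t.hu_rib - hu);
      if (a_rib > 0.5) label = 4;
    }
  }

  // lung nodules
  for (int i = 0; i < t.n_nod; ++i) {
    double c[3] = { t.nod[4 * i], t.nod[4 * i + 1], t.nod[4 * i + 2] };
    double s[3] = { t.nod[4 * i + 3], t.nod[4 * i + 3], t.nod[4 * i + 3] };
    double d = sd_ellipsoid(x, y, z, c, s);
    double an = alpha_d(d, w);
    if (an > 0.0) {
      hu = hu + an * (t.hu_nodule - hu);
      if (an > 0.5) label = 2;
    }
  }
}

// [[Rcpp::export(name = ".cpp_thorax_render")]]
List cpp_thorax_render(List grid, List params, double amplitude) {
  int nx = as<int>(grid["nx"]), ny = as<int>(grid["ny"]), nz = as<int>(grid["nz"]);
  double vs = as<double>(grid["voxel_size"]);
  NumericVector org = grid["origin"];
  Thorax t = as_thorax(params);
  NumericVector hu(Dimension(nx, ny, nz));
  IntegerVector lab(Dimension(nx, ny, nz));
  double* ph = REAL(hu);
  int* pl = INTEGER(lab);
  size_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    double z = org[2] + kz * vs;
    for (int ky = 0; ky < ny; ++ky) {
      double y = org[1] + ky * vs;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double x = org[0] + kx * vs;
        double xr, yr, zr;
        phi_fwd(t, amplitude, x, y, z, xr, yr, zr);
        double h; int l;
        anatomy_eval(t, xr, yr, zr, h, l);
        ph[idx] = h; pl[idx] = l;
      }
    }
  }
  return List::create(_["hu"] = hu, _["labels"] = lab);
}

// exact DVF between two amplitudes: u(r) = phi_src^{-1}(phi_tgt(r)) - r
// [[Rcpp::export(name = ".cpp_thorax_dvf")]]
NumericVector cpp_thorax_dvf(List grid, List params, double a_src, double a_tgt) {
  int nx = as<int>(grid["nx"]), ny = as<int>(grid["ny"]), nz = as<int>(grid["nz"]);
  double vs = as<double>(grid["voxel_size"]);
  NumericVector org = grid["origin"];
  Thorax t = as_thorax(params);
  NumericVector u((size_t)nx * ny * nz * 3);
  u.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  double* pu = REAL(u);
  size_t nvox = (size_t)nx * ny * nz, idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    double z = org[2] + kz * vs;
    for (int ky = 0; ky < ny; ++ky) {
      double y = org[1] + ky * vs;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double x = org[0] + kx * vs;
        double xr, yr, zr, xs, ys, zs;
        phi_fwd(t, a_tgt, x, y, z, xr, yr, zr);
        phi_inv(t, a_src, xr, yr, zr, xs, ys, zs);
        pu[idx] = xs - x;
        pu[idx + nvox] = ys - y;
        pu[idx + 2 * nvox] = zs - z;
      }
    }
  }
  return u;
}

// minimum Jacobian diagonal terms of phi_a over the grid (fold detection)
// [[Rcpp::export(name = ".cpp_thorax_jac_min")]]
double cpp_thorax_jac_min(List grid, List params, double amplitude) {
  int nx = as<int>(grid["nx"]), ny = as<int>(grid["ny"]), nz = as<int>(grid["nz"]);
  double vs = as<double>(grid["voxel_size"]);
  NumericVector org = grid["origin"];
  Thorax t = as_thorax(params);
  double jmin = 1e30;
  for (int kz = 0; kz < nz; ++kz) {
    double z = org[2] + kz * vs;
    for (int ky = 0; ky < ny; ++ky) {
      double y = org[1] + ky * vs;
      double jy = 1.0 + amplitude * dap_h(t, y);
      if (jy < jmin) jmin = jy;
      for (int kx = 0; kx < nx; ++kx) {
        double x = org[0] + kx * vs;
        double jz = 1.0 + amplitude * env_g(t, x, y) * dpsi_z(t, z);
        if (jz < jmin) jmin = jz;
      }
    }
  }
  return jmin;
}
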