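// Compact deterministic 3-D U-Net: forward pass and analytic backward pass
// (reverse-mode) for training with MSE loss.
//
// Architecture (configurable stages S, base filters F):
//   encoder stage k: conv3(3x3x3) -> PReLU -> conv3 -> PReLU, channels F*2^k,
//                    followed by 2x2x2 max pooling (except deepest stage)
//   decoder stage k: 2x2x2 nearest-neighbour upsampling, concatenation with
//                    the encoder skip tensor, conv3 -> PReLU -> conv3 -> PReLU
//   head: 3x3x3 convolution with linear activation to out_ch channels.
// PReLU slopes are per-channel learnable parameters. All state lives in a
// flat parameter vector; the layout is exposed so initialization can be
// done (seeded) from R. Single-threaded and bit-reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Tensor {
  int c, nx, ny, nz;
  std::vector<double> v;
  Tensor() : c(0), nx(0), ny(0), nz(0) {}
  Tensor(int c_, int nx_, int ny_, int nz_)
    : c(c_), nx(nx_), ny(ny_), nz(nz_), v((size_t)c_ * nx_ * ny_ * nz_, 0.0) {}
  size_t sp() const { return (size_t)nx * ny * nz; }
};

// ---- layers --------------------------------------------------------------
static void conv3_fwd(const Tensor& in, Tensor& out,
                      const double* W, const double* b) {
  int nx = in.nx, ny = in.ny, nz = in.nz;
  size_t sp = in.sp();
  for (int co = 0; co < out.c; ++co) {
    double* o = out.v.data() + (size_t)co * sp;
    for (size_t i = 0; i < sp; ++i) o[i] = b[co];
    for (int ci = 0; ci < in.c; ++ci) {
      const double* x = in.v.data() + (size_t)ci * sp;
      const double* w = W + ((size_t)co * in.c + ci) * 27;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            double wv = w[(kz + 1) * 9 + (ky + 1) * 3 + (kx + 1)];
            if (wv == 0.0) continue;
            int z0 = std::max(0, -kz), z1 = std::min(nz, nz - kz);
            int y0 = std::max(0, -ky), y1 = std::min(ny, ny - ky);
            int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double* orow = o + ((size_t)z * ny + y) * nx;
                const double* xrow = x + ((size_t)(z + kz) * ny + (y + ky)) * nx + kx;
                for (int xx = x0; xx < x1; ++xx) orow[xx] += wv * xrow[xx];
              }
          }
    }
  }
}

static void conv3_bwd(const Tensor& in, const Tensor& gout, Tensor& gin,
                      const double* W, double* gW, double* gb) {
  int nx = in.nx, ny = in.ny, nz = in.nz;
  size_t sp = in.sp();
  for (int co = 0; co < gout.c; ++co) {
    const double* go = gout.v.data() + (size_t)co * sp;
    double s = 0.0;
    for (size_t i = 0; i < sp; ++i) s += go[i];
    gb[co] += s;
    for (int ci = 0; ci < in.c; ++ci) {
      const double* x = in.v.data() + (size_t)ci * sp;
      double* gx = gin.v.data() + (size_t)ci * sp;
      const double* w = W + ((size_t)co * in.c + ci) * 27;
      double* gw = gW + ((size_t)co * in.c + ci) * 27;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            int ki = (kz + 1) * 9 + (ky + 1) * 3 + (kx + 1);
            double wv = w[ki], gwv = 0.0;
            int z0 = std::max(0, -kz), z1 = std::min(nz, nz - kz);
            int y0 = std::max(0, -ky), y1 = std::min(ny, ny - ky);
            int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const double* gorow = go + ((size_t)z * ny + y) * nx;
                const double* xrow = x + ((size_t)(z + kz) * ny + (y + ky)) * nx + kx;
                double* gxrow = gx + ((size_t)(z + kz) * ny + (y + ky)) * nx + kx;
                for (int xx = x0; xx < x1; ++xx) {
                  gwv += gorow[xx] * xrow[xx];
                  gxrow[xx] += gorow[xx] * wv;
                }
              }
            gw[ki] += gwv;
          }
    }
  }
}

static void prelu_fwd(const Tensor& in, Tensor& out, const double* a) {
  size_t sp = in.sp();
  for (int c = 0; c < in.c; ++c) {
    const double* x = in.v.data() + (size_t)c * sp;
    double* o = out.v.data() + (size_t)c * sp;
    double ac = a[c];
    for (size_t i = 0; i < sp; ++i) o[i] = x[i] > 0.0 ? x[i] : ac * x[i];
  }
}
static void prelu_bwd(const Tensor& in, const Tensor& gout, Tensor& gin,
                      const double* a, double* ga) {
  size_t sp = in.sp();
  for (int c = 0; c < in.c; ++c) {
    const double* x = in.v.data() + (size_t)c * sp;
    const double* go = gout.v.data() + (size_t)c * sp;
    double* gx = gin.v.data() + (size_t)c * sp;
    double ac = a[c], gac = 0.0;
    for (size_t i = 0; i < sp; ++i) {
      if (x[i] > 0.0) gx[i] += go[i];
      else { gx[i] += ac * go[i]; gac += go[i] * x[i]; }
    }
    ga[c] += gac;
  }
}

static void pool_fwd(const Tensor& in, Tensor& out, std::vector<int>& argmax) {
  int nx = out.nx, ny = out.ny, nz = out.nz;
  size_t spo = out.sp(), spi = in.sp();
  argmax.resize((size_t)out.c * spo);
  for (int c = 0; c < in.c; ++c) {
    const double* x = in.v.data() + (size_t)c * spi;
    double* o = out.v.data() + (size_t)c * spo;
    int* am = argmax.data() + (size_t)c * spo;
    size_t oi = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xx = 0; xx < nx; ++xx, ++oi) {
          double best = -1e300; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int ii = ((2 * z + dz) * in.ny + (2 * y + dy)) * in.nx + (2 * xx + dx);
                if (x[ii] > best) { best = x[ii]; bi = ii; }
              }
          o[oi] = best; am[oi] = bi;
        }
  }
}
static void pool_bwd(const Tensor& gout, Tensor& gin, const std::vector<int>& argmax) {
  size_t spo = gout.sp(), spi = gin.sp();
  for (int c = 0; c < gout.c; ++c) {
    const double* go = gout.v.data() + (size_t)c * spo;
    const int* am = argmax.data() + (size_t)c * spo;
    double* gx = gin.v.data() + (size_t)c * spi;
    for (size_t i = 0; i < spo; ++i) gx[am[i]] += go[i];
  }
}

static void up_fwd(const Tensor& in, Tensor& out) {
  size_t spo = out.sp(), spi = in.sp();
  for (int c = 0; c < in.c; ++c) {
    const double* x = in.v.data() + (size_t)c * spi;
    double* o = out.v.data() + (size_t)c * spo;
    for (int z = 0; z < out.nz; ++z)
      for (int y = 0; y < out.ny; ++y)
        for (int xx = 0; xx < out.nx; ++xx)
          o[((size_t)z * out.ny + y) * out.nx + xx] =
            x[((size_t)(z / 2) * in.ny + (y / 2)) * in.nx + (xx / 2)];
  }
}
static void up_bwd(const Tensor& gout, Tensor& gin) {
  size_t spo = gout.sp(), spi = gin.sp();
  for (int c = 0; c < gout.c; ++c) {
    const double* go = gout.v.data() + (size_t)c * spo;
    double* gx = gin.v.data() + (size_t)c * spi;
    for (int z = 0; z < gout.nz; ++z)
      for (int y = 0; y < gout.ny; ++y)
        for (int xx = 0; xx < gout.nx; ++xx)
          gx[((size_t)(z / 2) * gin.ny + (y / 2)) * gin.nx + (xx / 2)] +=
            go[((size_t)z * gout.ny + y) * gout.nx + xx];
  }
}

// ---- parameter layout ----------------------------------------------------
struct Cfg { int in_ch, out_ch, stages, base; };

static Cfg as_cfg(const List& cfg) {
  Cfg c;
  c.in_ch = as<int>(cfg["in_ch"]); c.out_ch = as<int>(cfg["out_ch"]);
  c.stages = as<int>(cfg["n_stages"]); c.base = as<int>(cfg["base_filters"]);
  return c;
}

// Enumerate parameter tensors in execution order. Each conv contributes
// (weights, bias, prelu-or-not). Returns total length and, optionally,
// a description for seeded initialization in R.
// [[Rcpp::export(name = ".cpp_unet_layout")]]
List cpp_unet_layout(List cfg) {
  Cfg c = as_cfg(cfg);
  std::vector<int> cout_v, cin_v, act_v;  // act: 1 = PReLU, 0 = linear
  int S = c.stages, F = c.base;
  for (int k = 0; k < S; ++k) {
    int ck = F << k;
    int cin = (k == 0) ? c.in_ch : (F << (k - 1));
    cout_v.push_back(ck); cin_v.push_back(cin); act_v.push_back(1);
    cout_v.push_back(ck); cin_v.push_back(ck); act_v.push_back(1);
  }
  for (int k = S - 2; k >= 0; --k) {
    int ck = F << k;
    int cin = (F << (k + 1)) + ck;  // upsampled + skip
    cout_v.push_back(ck); cin_v.push_back(cin); act_v.push_back(1);
    cout_v.push_back(ck); cin_v.push_back(ck); act_v.push_back(1);
  }
  cout_v.push_back(c.out_ch); cin_v.push_back(F); act_v.push_back(0);
  size_t total = 0;
  for (size_t i = 0; i < cout_v.size(); ++i) {
    total += (size_t)cout_v[i] * cin_v[i] * 27 + cout_v[i];
    if (act_v[i]) total += cout_v[i];
  }
  return List::create(_["n_params"] = (double)total,
                      _["conv_out"] = wrap(cout_v),
                      _["conv_in"] = wrap(cin_v),
                      _["conv_act"] = wrap(act_v));
}

// run the network; if tape != NULL, record intermediates for backward
struct Rec {
  std::vector<Tensor> conv_in;    // input of each conv
  std::vector<Tensor> prelu_in;   // input of each prelu (conv output)
  std::vector<std::vector<int>> pool_arg;
  std::vector<Tensor> pool_in_shape;  // shapes only (c,nx,ny,nz)
  std::vector<int> skip_ch;
};

static Tensor unet_run(const double* P, const Cfg& c, const Tensor& input,
                       Rec* rec) {
  int S = c.stages, F = c.base;
  size_t p = 0;
  Tensor x = input;
  std::vector<Tensor> skips;
  auto do_conv = [&](Tensor& xin, int cin, int cout, int act) -> Tensor {
    const double* W = P + p; p += (size_t)cout * cin * 27;
    const double* b = P + p; p += cout;
    Tensor y(cout, xin.nx, xin.ny, xin.nz);
    conv3_fwd(xin, y, W, b);
    if (rec) rec->conv_in.push_back(xin);
    if (act) {
      const double* a = P + p; p += cout;
      Tensor z(cout, y.nx, y.ny, y.nz);
      prelu_fwd(y, z, a);
      if (rec) rec->prelu_in.push_back(y);
      return z;
    }
    return y;
  };
  for (int k = 0; k < S; ++k) {
    int ck = F << k;
    int cin = (k == 0) ? c.in_ch : (F << (k - 1));
    x = do_conv(x, cin, ck, 1);
    x = do_conv(x, ck, ck, 1);
    if (k < S - 1) {
      skips.push_back(x);
      Tensor y(ck, x.nx / 2, x.ny / 2, x.nz / 2);
      std::vector<int> am;
      pool_fwd(x, y, am);
      if (rec) {
        rec->pool_arg.push_back(am);
        Tensor sh(x.c, x.nx, x.ny, x.nz);
        rec->pool_in_shape.push_back(sh);
      }
      x = y;
    }
  }
  for (int k = S - 2; k >= 0; --k) {
    int ck = F << k;
    Tensor up(x.c, x.nx * 2, x.ny * 2, x.nz * 2);
    up_fwd(x, up);
    Tensor& sk = skips[k];
    Tensor cat(sk.c + up.c, up.nx, up.ny, up.nz);
    std::copy(sk.v.begin(), sk.v.end(), cat.v.begin());
    std::copy(up.v.begin(), up.v.end(), cat.v.begin() + sk.v.size());
    if (rec) rec->skip_ch.push_back(sk.c);
    x = do_conv(cat, cat.c, ck, 1);
    x = do_conv(x, ck, ck, 1);
  }
  x = do_conv(x, F, c.out_ch, 0);
  return x;
}

// [[Rcpp::export(name = ".cpp_unet_forward")]]
NumericVector cpp_unet_forward(NumericVector params, NumericVector input, List cfg) {
  Cfg c = as_cfg(cfg);
  IntegerVector dim = input.attr("dim");
  Tensor x(dim[3], dim[0], dim[1], dim[2]);
  std::copy(input.begin(), input.end(), x.v.begin());
  Tensor y = unet_run(REAL(params), c, x, nullptr);
  NumericVector out((size_t)y.nx * y.ny * y.nz * y.c);
  out.attr("dim") = IntegerVector::create(y.nx, y.ny, y.nz, y.c);
  std::copy(y.v.begin(), y.v.end(), REAL(out));
  return out;
}

// MSE loss and full parameter gradient for one sample
// [[Rcpp::export(name = ".cpp_unet_loss_grad")]]
List cpp_unet_loss_grad(NumericVector params, NumericVector input,
                        NumericVector target, List cfg) {
  Cfg c = as_cfg(cfg);
  IntegerVector dim = input.attr("dim");
  Tensor x(dim[3], dim[0], dim[1], dim[2]);
  std::copy(input.begin(), input.end(), x.v.begin());
  Rec rec;
  Tensor y = unet_run(REAL(params), c, x, &rec);

  size_t n = y.v.size();
  double loss = 0.0;
  Tensor gy(y.c, y.nx, y.ny, y.nz);
  for (size_t i = 0; i < n; ++i) {
    double d = y.v[i] - target[i];
    loss += d * d;
    gy.v[i] = 2.0 * d / n;
  }
  loss /= n;

  // rebuild parameter offsets in execution order
  int S = c.stages, F = c.base;
  struct CInfo { size_t wo, bo, ao; int cin, cout, act; };
  std::vector<CInfo> convs;
  {
    size_t p = 0;
    auto add = [&](int cin, int cout, int act) {
      CInfo ci; ci.cin = cin; ci.cout = cout; ci.act = act;
      ci.wo = p; p += (size_t)cout * cin * 27;
      ci.bo = p; p += cout;
      ci.ao = p; if (act) p += cout;
      convs.push_back(ci);
    };
    for (int k = 0; k < S; ++k) {
      int ck = F << k;
      add((k == 0) ? c.in_ch : (F << (k - 1)), ck, 1);
      add(ck, ck, 1);
    }
    for (int k = S - 2; k >= 0; --k) {
      int ck = F << k;
      add((F << (k + 1)) + ck, ck, 1);
      add(ck, ck, 1);
    }
    add(F, c.out_ch, 0);
  }

  NumericVector grad(params.size());
  const double* P = REAL(params);
  double* G = REAL(grad);

  // walk backward through the recorded structure
  int ci = (int)convs.size() - 1;
  int pi = (int)rec.prelu_in.size() - 1;
  int pool_i = (int)rec.pool_arg.size() - 1;
  int skip_i = (int)rec.skip_ch.size() - 1;

  auto conv_back = [&](Tensor& g) {
    const CInfo& cf = convs[ci];
    Tensor gconv = g;
    if (cf.act) {
      Tensor& pin = rec.prelu_in[pi];
      gconv = Tensor(pin.c, pin.nx, pin.ny, pin.nz);
      prelu_bwd(pin, g, gconv, P + cf.ao, G + cf.ao);
      --pi;
    }
    Tensor& cin_t = rec.conv_in[ci];
    Tensor gin(cin_t.c, cin_t.nx, cin_t.ny, cin_t.nz);
    conv3_bwd(cin_t, gconv, gin, P + cf.wo, G + cf.wo, G + cf.bo);
    --ci;
    return gin;
  };

  Tensor g = conv_back(gy);  // head conv
  std::vector<Tensor> skip_grads(S > 1 ? S - 1 : 0);
  for (int k = 0; k < S - 1; ++k) {
    // decoder stage (reverse order of forward: k ran S-2..0, so backward 0..S-2)
    g = conv_back(g);
    Tensor gcat = conv_back(g);
    int sc = rec.skip_ch[skip_i]; --skip_i;
    int dk = k;  // decoder stage index from bottom of reverse = forward k
    (void)dk;
    Tensor gsk(sc, gcat.nx, gcat.ny, gcat.nz);
    std::copy(gcat.v.begin(), gcat.v.begin() + gsk.v.size(), gsk.v.begin());
    Tensor gup(gcat.c - sc, gcat.nx, gcat.ny, gcat.nz);
    std::copy(gcat.v.begin() + gsk.v.size(), gcat.v.end(), gup.v.begin());
    Tensor gdown(gup.c, gup.nx / 2, gup.ny / 2, gup.nz / 2);
    up_bwd(gup, gdown);
    // forward decoder loop ran k = S-2 .. 0, so reverse visits k = 0 .. S-2;
    // the skip tensor for reverse step j corresponds to encoder stage j
    skip_grads[k] = gsk;
    g = gdown;
  }
  for (int k = S - 1; k >= 0; --k) {
    if (k < S - 1) {
      // g currently holds gradient w.r.t. pooled output of stage k
      Tensor& sh = rec.pool_in_shape[pool_i];
      Tensor gin(sh.c, sh.nx, sh.ny, sh.nz);
      pool_bwd(g, gin, rec.pool_arg[pool_i]);
      --pool_i;
      // add the skip-connection gradient
      Tensor& gsk = skip_grads[k];
      for (size_t i = 0; i < gin.v.size(); ++i) gin.v[i] += gsk.v[i];
      g = gin;
    }
    g = conv_back(g);
    g = conv_back(g);
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
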