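// Constant-width U-Net for sinogram-to-image reconstruction, implemented on
// BLAS GEMM via im2col. Feature maps are stored as (channels x H*W*batch)
// single-precision matrices with column-major spatial indexing s = i + j*H.
//
// Architecture (depth d, width f, post-concat width u):
//   stem:      Conv3x3(1->f)+ReLU ; BN+Conv3x3(f->f)+ReLU          -> skip 1
//   levels 2..d: pool ; [BN+Conv3x3(f->f)+ReLU] x2                 -> skips
//   bottleneck: pool ; [BN+Conv3x3(f->f)+ReLU] x2
//   decoder x d: BN+ConvT3x3/2(f->f)+ReLU ; concat skip ;
//                BN+Conv(2f->u)+ReLU ; BN+Conv(u->f)+ReLU ;
//                BN+Conv(f->f)+ReLU
//   head:      Conv1x1(f->1), linear
// Batch normalisation precedes each convolution except the stem and head
// (the layout of the public satellite-imagery U-Net this family follows).
// MAE loss, Adam. Single precision.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

// ---- spatial helpers -------------------------------------------------------

// im2col for 3x3 'same' convolution over B samples of (F x H*W) maps.
static fmat im2col33(const fmat& X, int F, int H, int W, int B) {
  fmat C((size_t)9 * F, (size_t)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * H * W;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int o = (dj + 1) * 3 + (di + 1);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W || i0 > i1) continue;
          C.submat((size_t)o * F, base + (size_t)j * H + i0,
                   (size_t)(o + 1) * F - 1, base + (size_t)j * H + i1) =
            X.cols(base + (size_t)js * H + i0 + di,
                   base + (size_t)js * H + i1 + di);
        }
      }
  }
  return C;
}

// adjoint: accumulate dC into dX
static void col2im33(const fmat& dC, fmat& dX, int F, int H, int W, int B) {
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * H * W;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int o = (dj + 1) * 3 + (di + 1);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W || i0 > i1) continue;
          dX.cols(base + (size_t)js * H + i0 + di,
                  base + (size_t)js * H + i1 + di) +=
            dC.submat((size_t)o * F, base + (size_t)j * H + i0,
                      (size_t)(o + 1) * F - 1, base + (size_t)j * H + i1);
        }
      }
  }
  return;
}

// ---- layers ----------------------------------------------------------------

struct BN {
  fvec gamma, beta, mmean, mvar;
  fmat xhat;          // cache
  fvec invstd;        // cache
  float eps = 1e-3f, momentum = 0.9f;
  void init(int C) {
    gamma.ones(C); beta.zeros(C); mmean.zeros(C); mvar.ones(C);
  }
  fmat forward(const fmat& x, bool train) {
    const int C = x.n_rows;
    fmat y(arma::size(x));
    invstd.set_size(C);
    if (train) {
      xhat.set_size(arma::size(x));
      for (int c = 0; c < C; ++c) {
        const float mu = arma::mean(x.row(c));
        const float var = arma::mean(arma::square(x.row(c) - mu));
        invstd(c) = 1.0f / std::sqrt(var + eps);
        xhat.row(c) = (x.row(c) - mu) * invstd(c);
        y.row(c) = gamma(c) * xhat.row(c) + beta(c);
        mmean(c) = momentum * mmean(c) + (1 - momentum) * mu;
        mvar(c) = momentum * mvar(c) + (1 - momentum) * var;
      }
    } else {
      for (int c = 0; c < C; ++c) {
        const float is = 1.0f / std::sqrt(mvar(c) + eps);
        y.row(c) = gamma(c) * (x.row(c) - mmean(c)) * is + beta(c);
      }
    }
    return y;
  }
  fmat backward(const fmat& dy, fvec& dgamma, fvec& dbeta) {
    const int C = dy.n_rows;
    const float N = dy.n_cols;
    fmat dx(arma::size(dy));
    dgamma.set_size(C); dbeta.set_size(C);
    for (int c = 0; c < C; ++c) {
      dbeta(c) = arma::accu(dy.row(c));
      dgamma(c) = arma::accu(dy.row(c) % xhat.row(c));
      // dx = g*invstd/N * (N*dy - sum(dy) - xhat * sum(dy*xhat))
      dx.row(c) = gamma(c) * invstd(c) / N *
        (N * dy.row(c) - dbeta(c) - xhat.row(c) * dgamma(c));
    }
    return dx;
  }
};

enum UnitKind { STEM_CONV, BN_CONV, BN_CONVT, OUT_CONV };

struct Unit {
  UnitKind kind;
  int cin, cout, k;   // k = 3 or 1
  BN bn;
  fmat W;             // (k*k*cin x cout)
  fvec b;
  // caches
  fmat conv_in;       // input to the convolution (post-BN / zero-stuffed)
  fmat relu_mask;
  bool relu = true;

  void init(std::mt19937& rng) {
    const int fan_in = k * k * cin, fan_out = k * k * cout;
    const float lim = std::sqrt(6.0f / (fan_in + fan_out));
    std::uniform_real_distribution<float> ud(-lim, lim);
    W.set_size((size_t)k * k * cin, cout);
    W.for_each([&](float& v) { v = ud(rng); });
    b.zeros(cout);
    if (kind == BN_CONV || kind == BN_CONVT) bn.init(cin);
  }

  long n_params() const {
    long p = (long)W.n_elem + b.n_elem;
    if (kind == BN_CONV || kind == BN_CONVT) p += 4L * cin;
    return p;
  }

  // H,W refer to the INPUT spatial size; for BN_CONVT output is 2H x 2W.
  fmat forward(const fmat& x, int H, int Wd, int B, bool train) {
    fmat y0 = (kind == BN_CONV || kind == BN_CONVT) ? bn.forward(x, train) : x;
    fmat z;
    int Ho = H, Wo = Wd;
    if (kind == BN_CONVT) {   // zero-stuff to 2H x 2W
      Ho = 2 * H; Wo = 2 * Wd;
      z.zeros(cin, (size_t)Ho * Wo * B);
      for (int bb = 0; bb < B; ++bb) {
        const size_t bi = (size_t)bb * H * Wd, bo = (size_t)bb * Ho * Wo;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            z.col(bo + (size_t)(2 * j) * Ho + 2 * i) =
              y0.col(bi + (size_t)j * H + i);
      }
    } else z = y0;
    conv_in = z;
    fmat out;
    if (k == 1) out = W.t() * z;
    else {
      fmat C = im2col33(z, cin, Ho, Wo, B);
      out = W.t() * C;
    }
    out.each_col() += b;
    if (relu) {
      relu_mask = arma::conv_to<fmat>::from(out > 0.0f);
      out %= relu_mask;
    }
    return out;
  }

  fmat backward(fmat dy, int H, int Wd, int B, fmat& gW, fvec& gb,
                fvec& ggamma, fvec& gbeta) {
    // H, Wd: input spatial size as in forward
    int Ho = H, Wo = Wd;
    if (kind == BN_CONVT) { Ho = 2 * H; Wo = 2 * Wd; }
    if (relu) dy %= relu_mask;
    gb = arma::sum(dy, 1);
    fmat dz;
    if (k == 1) {
      gW = conv_in * dy.t();
      dz = W * dy;
    } else {
      fmat C = im2col33(conv_in, cin, Ho, Wo, B);
      gW = C * dy.t();
      fmat dC = W * dy;
      dz.zeros(cin, (size_t)Ho * Wo * B);
      col2im33(dC, dz, cin, Ho, Wo, B);
    }
    fmat dy0;
    if (kind == BN_CONVT) {   // un-stuff
      dy0.set_size(cin, (size_t)H * Wd * B);
      for (int bb = 0; bb < B; ++bb) {
        const size_t bi = (size_t)bb * H * Wd, bo = (size_t)bb * Ho * Wo;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            dy0.col(bi + (size_t)j * H + i) =
              dz.col(bo + (size_t)(2 * j) * Ho + 2 * i);
      }
    } else dy0 = dz;
    if (kind == BN_CONV || kind == BN_CONVT)
      return bn.backward(dy0, ggamma, gbeta);
    ggamma.reset(); gbeta.reset();
    return dy0;
  }
};

struct UNet {
  int depth, f, u, in_h, in_w;
  std::vector<Unit> units;   // in forward order (see build)

  // unit index layout:
  // 0: stem conv, 1: stem bnconv -> skip1
  // per level l=2..depth: 2 bnconvs
  // bottleneck: 2 bnconvs
  // per decoder step: convT, bnconv(2f->u), bnconv(u->f), bnconv(f->f)
  // last: out conv1x1
  void build(int depth_, int f_, int u_, int h, int w) {
    depth = depth_; f = f_; u = u_; in_h = h; in_w = w;
    units.clear();
    auto add = [&](UnitKind kind, int cin, int cout, int k, bool relu) {
      Unit uu; uu.kind = kind; uu.cin = cin; uu.cout = cout; uu.k = k;
      uu.relu = relu; units.push_back(uu);
    };
    add(STEM_CONV, 1, f, 3, true);
    add(BN_CONV, f, f, 3, true);
    for (int l = 2; l <= depth; ++l) {
      add(BN_CONV, f, f, 3, true);
      add(BN_CONV, f, f, 3, true);
    }
    add(BN_CONV, f, f, 3, true);   // bottleneck
    add(BN_CONV, f, f, 3, true);
    for (int l = 0; l < depth; ++l) {
      add(BN_CONVT, f, f, 3, true);
      add(BN_CONV, 2 * f, u, 3, true);
      add(BN_CONV, u, f, 3, true);
      add(BN_CONV, f, f, 3, true);
    }
    add(OUT_CONV, f, 1, 1, false);
    units.back().relu = false;
  }

  void init(unsigned seed) {
    std::mt19937 rng(seed);
    for (auto& uu : units) uu.init(rng);
  }

  long n_params() const {
    long p = 0;
    for (auto& uu : units) p += uu.n_params();
    return p;
  }

  // forward with caches for backward; returns output (1 x HW*B)
  std::vector<fmat> skips;       // post-conv maps per level (pre-pool)
  std::vector<arma::uvec> pool_idx;
  std::vector<std::pair<int,int>> sizes_enc;

  fmat pool2(const fmat& x, int H, int Wd, int B, arma::uvec& idx) {
    const int Ho = H / 2, Wo = Wd / 2;
    fmat y(x.n_rows, (size_t)Ho * Wo * B);
    idx.set_size((size_t)x.n_rows * Ho * Wo * B);
    size_t q = 0;
    for (int b = 0; b < B; ++b) {
      const size_t bi = (size_t)b * H * Wd, bo = (size_t)b * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const size_t c00 = bi + (size_t)(2 * j) * H + 2 * i;
          const size_t cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
          for (arma::uword r = 0; r < x.n_rows; ++r) {
            float best = x(r, cand[0]); int bi2 = 0;
            for (int c = 1; c < 4; ++c)
              if (x(r, cand[c]) > best) { best = x(r, cand[c]); bi2 = c; }
            y(r, bo + (size_t)j * Ho + i) = best;
            idx(q++) = (size_t)r + x.n_rows * cand[bi2];
          }
        }
    }
    return y;
  }

  fmat forward(const fmat& x0, int B, bool train) {
    skips.assign(depth, fmat());
    pool_idx.assign(depth, arma::uvec());
    sizes_enc.assign(depth + 1, {0, 0});
    int H = in_h, Wd = in_w;
    size_t ui = 0;
    fmat x = units[ui++].forward(x0, H, Wd, B, train);
    x = units[ui++].forward(x, H, Wd, B, train);
    skips[0] = x; sizes_enc[0] = {H, Wd};
    for (int l = 2; l <= depth; ++l) {
      x = pool2(x, H, Wd, B, pool_idx[l - 2]); H /= 2; Wd /= 2;
      x = units[ui++].forward(x, H, Wd, B, train);
      x = units[ui++].forward(x, H, Wd, B, train);
      skips[l - 1] = x; sizes_enc[l - 1] = {H, Wd};
    }
    x = pool2(x, H, Wd, B, pool_idx[depth - 1]); H /= 2; Wd /= 2;
    x = units[ui++].forward(x, H, Wd, B, train);
    x = units[ui++].forward(x, H, Wd, B, train);
    sizes_enc[depth] = {H, Wd};
    for (int l = depth; l >= 1; --l) {
      x = units[ui++].forward(x, H, Wd, B, train);   // convT: doubles size
      H *= 2; Wd *= 2;
      x = arma::join_cols(x, skips[l - 1]);          // [up; skip]
      x = units[ui++].forward(x, H, Wd, B, train);
      x = units[ui++].forward(x, H, Wd, B, train);
      x = units[ui++].forward(x, H, Wd, B, train);
    }
    x = units[ui++].forward(x, H, Wd, B, train);     // out conv
    return x;
  }
};

// maxpool backward; pool2 fills idx in order (b, j, i, r), and the output
// columns advance exactly column-major in that traversal, so a simple
// (col, r) walk replays it.
static void pool2_backward(const fmat& dy, fmat& dx, const arma::uvec& idx) {
  const int rows = dy.n_rows;
  size_t q = 0;
  for (arma::uword col = 0; col < dy.n_cols; ++col)
    for (int r = 0; r < rows; ++r) {
      const arma::uword flat = idx(q++);
      dx(flat % rows, flat / rows) += dy(r, col);
    }
}

struct UNetGrads {
  std::vector<fmat> gW;
  std::vector<fvec> gb, ggamma, gbeta;
  void resize(size_t n) { gW.resize(n); gb.resize(n); ggamma.resize(n);
                          gbeta.resize(n); }
};

static void unet_backward(UNet& net, const fmat& dOut, int B, UNetGrads& g) {
  const int d = net.depth;
  g.resize(net.units.size());
  size_t ui = net.units.size() - 1;
  int H = net.in_h, Wd = net.in_w;
  fmat dx = net.units[ui].backward(dOut, H, Wd, B, g.gW[ui], g.gb[ui],
                                   g.ggamma[ui], g.gbeta[ui]);
  --ui;
  std::vector<fmat> dskips(d);
  for (int l = 1; l <= d; ++l) {
    // decoder blocks are stored in order l = depth..1; walking backwards we
    // encounter l = 1 first at the tail of the unit list.
    auto hw = net.sizes_enc[l - 1];
    H = hw.first; Wd = hw.second;
    dx = net.units[ui].backward(dx, H, Wd, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
    dx = net.units[ui].backward(dx, H, Wd, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
    dx = net.units[ui].backward(dx, H, Wd, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
    // split concat [up; skip]
    const int f = net.f;
    fmat dup = dx.rows(0, f - 1);
    dskips[l - 1] = dx.rows(f, 2 * f - 1);
    // convT consumed input at half size
    dx = net.units[ui].backward(dup, H / 2, Wd / 2, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
  }
  // bottleneck
  auto hw = net.sizes_enc[d];
  H = hw.first; Wd = hw.second;
  dx = net.units[ui].backward(dx, H, Wd, B, g.gW[ui], g.gb[ui],
                              g.ggamma[ui], g.gbeta[ui]); --ui;
  dx = net.units[ui].backward(dx, H, Wd, B, g.gW[ui], g.gb[ui],
                              g.ggamma[ui], g.gbeta[ui]); --ui;
  for (int l = d; l >= 2; --l) {
    auto hwp = net.sizes_enc[l - 1];
    const int Hp = hwp.first, Wp = hwp.second;
    fmat dpre(net.f, (size_t)Hp * Wp * B, arma::fill::zeros);
    pool2_backward(dx, dpre, net.pool_idx[l - 1]);
    dpre += dskips[l - 1];
    dx = net.units[ui].backward(dpre, Hp, Wp, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
    dx = net.units[ui].backward(dx, Hp, Wp, B, g.gW[ui], g.gb[ui],
                                g.ggamma[ui], g.gbeta[ui]); --ui;
  }
  auto hw0 = net.sizes_enc[0];
  fmat dpre(net.f, (size_t)hw0.first * hw0.second * B, arma::fill::zeros);
  pool2_backward(dx, dpre, net.pool_idx[0]);
  dpre += dskips[0];
  dx = net.units[ui].backward(dpre, hw0.first, hw0.second, B, g.gW[ui],
                              g.gb[ui], g.ggamma[ui], g.gbeta[ui]); --ui;
  net.units[ui].backward(dx, hw0.first, hw0.second, B, g.gW[ui], g.gb[ui],
                         g.ggamma[ui], g.gbeta[ui]);
}

// ---- Adam over the whole net ----------------------------------------------

struct AdamU {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb, mg, vg, mB, vB;
  float lr, beta1 = 0.9f, beta2 = 0.999f, eps = 1e-7f;
  long t = 0;
  void init(UNet& net, float lr_) {
    lr = lr_;
    for (auto& uu : net.units) {
      mW.push_back(arma::zeros<fmat>(arma::size(uu.W)));
      vW.push_back(arma::zeros<fmat>(arma::size(uu.W)));
      mb.push_back(arma::zeros<fvec>(uu.b.n_elem));
      vb.push_back(arma::zeros<fvec>(uu.b.n_elem));
      const int nb = (uu.kind == BN_CONV || uu.kind == BN_CONVT) ? uu.cin : 0;
      mg.push_back(arma::zeros<fvec>(nb)); vg.push_back(arma::zeros<fvec>(nb));
      mB.push_back(arma::zeros<fvec>(nb)); vB.push_back(arma::zeros<fvec>(nb));
    }
  }
  void step(UNet& net, UNetGrads& g) {
    ++t;
    const float c1 = 1.0f - std::pow(beta1, (float)t);
    const float c2 = 1.0f - std::pow(beta2, (float)t);
    for (size_t i = 0; i < net.units.size(); ++i) {
      auto& uu = net.units[i];
      mW[i] = beta1 * mW[i] + (1 - beta1) * g.gW[i];
      vW[i] = beta2 * vW[i] + (1 - beta2) * arma::square(g.gW[i]);
      uu.W -= lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
      mb[i] = beta1 * mb[i] + (1 - beta1) * g.gb[i];
      vb[i] = beta2 * vb[i] + (1 - beta2) * arma::square(g.gb[i]);
      uu.b -= lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
      if (g.ggamma[i].n_elem) {
        mg[i] = beta1 * mg[i] + (1 - beta1) * g.ggamma[i];
        vg[i] = beta2 * vg[i] + (1 - beta2) * arma::square(g.ggamma[i]);
        uu.bn.gamma -= lr * (mg[i] / c1) / (arma::sqrt(vg[i] / c2) + eps);
        mB[i] = beta1 * mB[i] + (1 - beta1) * g.gbeta[i];
        vB[i] = beta2 * vB[i] + (1 - beta2) * arma::square(g.gbeta[i]);
        uu.bn.beta -= lr * (mB[i] / c1) / (arma::sqrt(vB[i] / c2) + eps);
      }
    }
  }
};

// ---- serialization ---------------------------------------------------------

static List unet_to_list(const UNet& net) {
  List layers(net.units.size());
  for (size_t i = 0; i < net.units.size(); ++i) {
    const auto& uu = net.units[i];
    List li = List::create(
      _["W"] = wrap(arma::conv_to<arma::mat>::from(uu.W)),
      _["b"] = wrap(arma::conv_to<arma::vec>::from(uu.b)));
    if (uu.kind == BN_CONV || uu.kind == BN_CONVT) {
      li["gamma"] = wrap(arma::conv_to<arma::vec>::from(uu.bn.gamma));
      li["beta"] = wrap(arma::conv_to<arma::vec>::from(uu.bn.beta));
      li["mmean"] = wrap(arma::conv_to<arma::vec>::from(uu.bn.mmean));
      li["mvar"] = wrap(arma::conv_to<arma::vec>::from(uu.bn.mvar));
    }
    layers[i] = li;
  }
  return layers;
}

static void unet_from_list(UNet& net, const List& layers) {
  for (size_t i = 0; i < net.units.size(); ++i) {
    List li = layers[i];
    auto& uu = net.units[i];
    uu.W = arma::conv_to<fmat>::from(as<arma::mat>(li["W"]));
    uu.b = arma::conv_to<fvec>::from(as<arma::vec>(li["b"]));
    if (uu.kind == BN_CONV || uu.kind == BN_CONVT) {
      uu.bn.gamma = arma::conv_to<fvec>::from(as<arma::vec>(li["gamma"]));
      uu.bn.beta = arma::conv_to<fvec>::from(as<arma::vec>(li["beta"]));
      uu.bn.mmean = arma::conv_to<fvec>::from(as<arma::vec>(li["mmean"]));
      uu.bn.mvar = arma::conv_to<fvec>::from(as<arma::vec>(li["mvar"]));
    }
  }
}

// [[Rcpp::export]]
double unet_param_count_cpp(const int depth, const int features,
                            const int post_concat_features, const int in_h,
                            const int in_w) {
  UNet net;
  net.build(depth, features, post_concat_features, in_h, in_w);
  net.init(1u);
  return (double)net.n_params();
}

double ssim_cpp(const arma::mat& a, const arma::mat& b, const double dr);

// [[Rcpp::export]]
List train_unet_cpp(const arma::mat& Xtr, const arma::mat& Ytr,
                    const arma::mat& Xval, const arma::mat& Yval,
                    const List cfg, const int seed) {
  const int depth = as<int>(cfg["depth"]);
  const int f = as<int>(cfg["base_features"]);
  const int u = as<int>(cfg["post_concat_features"]);
  const int h = as<int>(cfg["input_h"]), w = as<int>(cfg["input_w"]);
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const float lr = as<double>(cfg["learning_rate"]);
  const bool verbose = cfg.containsElementNamed("verbose") ?
    as<bool>(cfg["verbose"]) : false;
  if (h % (1 << depth) || w % (1 << depth))
    stop("input size must be divisible by 2^depth");
  if (Xval.n_rows == 0) stop("validation set must not be empty");

  const int Ntr = Xtr.n_rows, Nv = Xval.n_rows;
  const size_t HW = (size_t)h * w;
  if (Xtr.n_cols != HW || Ytr.n_cols != HW) stop("flattened size mismatch");

  UNet net;
  net.build(depth, f, u, h, w);
  net.init((unsigned)seed);
  AdamU opt;
  opt.init(net, lr);

  fmat Xt = arma::conv_to<fmat>::from(Xtr.t());  // HW x N
  fmat Yt = arma::conv_to<fmat>::from(Ytr.t());
  fmat Xv = arma::conv_to<fmat>::from(Xval.t());
  fmat Yv = arma::conv_to<fmat>::from(Yval.t());

  std::mt19937 rng((unsigned)seed + 1000u);
  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  std::vector<double> h_loss, h_vmae, h_vrmse, h_vssim, h_vpsnr;
  UNetGrads g;

  auto eval_val = [&](double& mae, double& rmse, double& ssim, double& psnr) {
    double sae = 0, sse = 0, ssim_acc = 0;
    int ssim_n = 0;
    const int chunk = std::max(1, (int)(4e6 / HW));
    for (int s0 = 0; s0 < Nv; s0 += chunk) {
      const int B = std::min(chunk, Nv - s0);
      fmat xb(1, HW * B);
      for (int i = 0; i < B; ++i)
        xb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
          Xv.col(s0 + i).t();
      fmat out = net.forward(xb, B, false);
      for (int i = 0; i < B; ++i) {
        arma::frowvec pr = out.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1)
                              .row(0);
        arma::fvec tr = Yv.col(s0 + i);
        arma::fvec d = pr.t() - tr;
        sae += arma::accu(arma::abs(d));
        sse += arma::accu(arma::square(d));
        if (ssim_n < 16 && h >= 11 && w >= 11) {
          arma::mat A(h, w), Bm(h, w);
          for (int jj = 0; jj < w; ++jj)
            for (int ii = 0; ii < h; ++ii) {
              A(ii, jj) = tr((size_t)jj * h + ii);
              Bm(ii, jj) = pr((size_t)jj * h + ii);
            }
          ssim_acc += ssim_cpp(A, Bm, 1.0);
          ++ssim_n;
        }
      }
    }
    const double mse = sse / ((double)Nv * HW);
    mae = sae / ((double)Nv * HW);
    rmse = std::sqrt(mse);
    ssim = ssim_n ? ssim_acc / ssim_n : NA_REAL;
    psnr = mse > 0 ? 10.0 * std::log10(1.0 / mse) : R_PosInf;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int nb = 0;
    for (int s0 = 0; s0 < Ntr; s0 += batch) {
      const int B = std::min(batch, Ntr - s0);
      fmat xb(1, HW * B), yb(1, HW * B);
      for (int i = 0; i < B; ++i) {
        xb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
          Xt.col(order[s0 + i]).t();
        yb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
          Yt.col(order[s0 + i]).t();
      }
      fmat out = net.forward(xb, B, true);
      fmat r = out - yb;
      ep_loss += arma::mean(arma::mean(arma::abs(r)));
      ++nb;
      fmat dOut = arma::sign(r) / (float)r.n_elem;   // MAE gradient
      unet_backward(net, dOut, B, g);
      opt.step(net, g);
    }
    double vmae, vrmse, vssim, vpsnr;
    eval_val(vmae, vrmse, vssim, vpsnr);
    h_loss.push_back(ep_loss / nb);
    h_vmae.push_back(vmae);
    h_vrmse.push_back(vrmse);
    h_vssim.push_back(vssim);
    h_vpsnr.push_back(vpsnr);
    if (verbose)
      Rcout << "epoch " << ep + 1 << " mae " << ep_loss / nb
            << " val_mae " << vmae << " val_ssim " << vssim << "\n";
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["layers"] = unet_to_list(net),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["loss"] = h_loss,
      _["val_mae"] = h_vmae, _["val_rmse"] = h_vrmse,
      _["val_ssim"] = h_vssim, _["val_psnr"] = h_vpsnr),
    _["n_params"] = (double)net.n_params());
}

// [[Rcpp::export]]
arma::mat predict_unet_cpp(const arma::mat& X, const List layers,
                           const List cfg) {
  const int depth = as<int>(cfg["depth"]);
  const int f = as<int>(cfg["base_features"]);
  const int u = as<int>(cfg["post_concat_features"]);
  const int h = as<int>(cfg["input_h"]), w = as<int>(cfg["input_w"]);
  UNet net;
  net.build(depth, f, u, h, w);
  net.init(1u);
  unet_from_list(net, layers);
  const int N = X.n_rows;
  const size_t HW = (size_t)h * w;
  arma::mat out(N, HW);
  const int chunk = std::max(1, (int)(4e6 / HW));
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int B = std::min(chunk, N - s0);
    fmat xb(1, HW * B);
    for (int i = 0; i < B; ++i)
      xb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
        arma::conv_to<fmat>::from(X.row(s0 + i));
    fmat y = net.forward(xb, B, false);
    for (int i = 0; i < B; ++i)
      out.row(s0 + i) = arma::conv_to<arma::mat>::from(
        y.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1));
  }
  return out;
}

// Finite-difference support: loss and one analytic gradient entry for a
// seeded network on one batch (training mode, MAE loss). Used by the test
// suite to verify the backward pass.
// [[Rcpp::export]]
List unet_lossgrad_cpp(const arma::mat& X, const arma::mat& Y,
                       const List cfg, const int seed,
                       const int unit_idx, const int param_kind,
                       const int elem_idx, const double eps) {
  const int depth = as<int>(cfg["depth"]);
  const int f = as<int>(cfg["base_features"]);
  const int u = as<int>(cfg["post_concat_features"]);
  const int h = as<int>(cfg["input_h"]), w = as<int>(cfg["input_w"]);
  const int B = X.n_rows;
  const size_t HW = (size_t)h * w;
  UNet net;
  net.build(depth, f, u, h, w);
  net.init((unsigned)seed);
  // param_kind: 0=W, 1=b, 2=gamma, 3=beta
  if (unit_idx < 0 || unit_idx >= (int)net.units.size())
    stop("unit index out of range");
  auto& uu = net.units[unit_idx];
  if ((param_kind == 2 || param_kind == 3) &&
      !(uu.kind == BN_CONV || uu.kind == BN_CONVT))
    stop("unit has no batch norm");
  if (eps != 0.0) {
    if (param_kind == 0) uu.W(elem_idx) += (float)eps;
    else if (param_kind == 1) uu.b(elem_idx) += (float)eps;
    else if (param_kind == 2) uu.bn.gamma(elem_idx) += (float)eps;
    else uu.bn.beta(elem_idx) += (float)eps;
  }
  fmat xb(1, HW * B), yb(1, HW * B);
  for (int i = 0; i < B; ++i) {
    xb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
      arma::conv_to<fmat>::from(X.row(i));
    yb.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
      arma::conv_to<fmat>::from(Y.row(i));
  }
  fmat out = net.forward(xb, B, true);
  fmat r = out - yb;
  const double loss = arma::mean(arma::mean(arma::abs(r)));
  fmat dOut = arma::sign(r) / (float)r.n_elem;
  UNetGrads g;
  unet_backward(net, dOut, B, g);
  double grad = NA_REAL;
  if (param_kind == 0) grad = g.gW[unit_idx](elem_idx);
  else if (param_kind == 1) grad = g.gb[unit_idx](elem_idx);
  else if (param_kind == 2) grad = g.ggamma[unit_idx](elem_idx);
  else grad = g.gbeta[unit_idx](elem_idx);
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
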