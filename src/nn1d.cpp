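// 1D convolutional network for spectral net-signal regression, implemented
// directly on BLAS GEMM. Architecture (fixed family, sizes from the
// hyperparameter list): input (L,1) -> Gaussian noise (train only) ->
// conv(F1,k1)+ELU -> conv(F2,k2)+ELU -> dropout -> flatten -> dense(D)+ELU
// -> dense(1) linear. Huber loss, Adam, early stopping on validation loss
// with best-weight restoration. Single precision throughout.
//
// The first convolution uses a small im2col (single input channel); the
// second, much larger one is computed as k2 offset-view GEMMs over the
// batch-concatenated feature axis (valid windows that straddle sample
// boundaries are junk and are simply never gathered), which avoids
// materialising the (k2*F1 x L2*B) im2col matrix entirely.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

// direct single-precision GEMM with beta-accumulation (avoids the large
// temporaries Armadillo materialises for `view += A * B`)
extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

static inline void sgemm_acc(char ta, char tb, int m, int n, int k,
                             float alpha, const float* A, int lda,
                             const float* B, int ldb, float beta, float* C,
                             int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static inline void elu_inplace(fmat& x) {
  x.for_each([](float& v) { if (v < 0.0f) v = std::expm1(v); });
}
// dx *= elu'(activated output), fused single pass without temporaries
static inline void elu_grad_mul(fmat& dx, const fmat& a) {
  float* d = dx.memptr();
  const float* p = a.memptr();
  const size_t n = a.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] <= 0.0f) d[i] *= p[i] + 1.0f;
}

struct CNN1DParams {
  fmat W1, W2, W3, W4;   // (k1 x F1), (k2*F1 x F2), (flat x D), (D x 1)
  fvec b1, b2, b3, b4;
  std::vector<fmat*> all() { return {&W1, &W2, &W3, &W4}; }
  std::vector<fvec*> allb() { return {&b1, &b2, &b3, &b4}; }
};

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  float lr, beta1 = 0.9f, beta2 = 0.999f, eps = 1e-7f;
  long t = 0;
  void init(CNN1DParams& p, float lr_) {
    lr = lr_;
    for (auto* w : p.all()) { mW.push_back(arma::zeros<fmat>(arma::size(*w)));
                              vW.push_back(arma::zeros<fmat>(arma::size(*w))); }
    for (auto* b : p.allb()) { mb.push_back(arma::zeros<fvec>(b->n_elem));
                               vb.push_back(arma::zeros<fvec>(b->n_elem)); }
  }
  template <typename T>
  void upd(T& w, T& m, T& v, const T& g, float c1, float c2) {
    float* wp = w.memptr(); float* mp = m.memptr(); float* vp = v.memptr();
    const float* gp = g.memptr();
    const float sc2 = 1.0f / std::sqrt(c2);
    for (size_t i = 0; i < w.n_elem; ++i) {   // fused single pass
      mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
      vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
      wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i]) * sc2 + eps);
    }
  }
  void step(CNN1DParams& p, std::vector<fmat>& gW, std::vector<fvec>& gb) {
    ++t;
    const float c1 = 1.0f - std::pow(beta1, (float)t);
    const float c2 = 1.0f - std::pow(beta2, (float)t);
    auto ws = p.all(); auto bs = p.allb();
    for (size_t i = 0; i < ws.size(); ++i) {
      upd(*ws[i], mW[i], vW[i], gW[i], c1, c2);
      upd(*bs[i], mb[i], vb[i], gb[i], c1, c2);
    }
  }
};

// im2col over a single-channel batch: X (L x B) -> (k x Lout*B)
static fmat im2col1(const fmat& X, int k, int Lout) {
  const int B = X.n_cols;
  fmat C(k, (size_t)Lout * B);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lout; ++t)
      C.col((size_t)b * Lout + t) = X.col(b).subvec(t, t + k - 1);
  return C;
}

struct Sizes { int L, k1, F1, L1, k2, F2, L2, flat, D; };

struct Cache {
  fmat C1, A1, A2f, Flat, drop, H, out;
  size_t Lfull;   // full-axis conv2 output length
};

static void forward(const fmat& Xb, const CNN1DParams& p, const Sizes& sz,
                    Cache& c, bool train, float noise_sd, float drop_rate,
                    std::mt19937* rng) {
  const int B = Xb.n_cols;
  fmat X = Xb;
  if (train && noise_sd > 0.0f && rng) {
    std::normal_distribution<float> nd(0.0f, noise_sd);
    X.for_each([&](float& v) { v += nd(*rng); });
  }
  c.C1 = im2col1(X, sz.k1, sz.L1);                    // k1 x L1*B
  c.A1 = p.W1.t() * c.C1;                             // F1 x L1*B
  c.A1.each_col() += p.b1;
  elu_inplace(c.A1);

  // conv2 over the concatenated axis: Lfull = L1*B - k2 + 1 windows
  const size_t Lfull = (size_t)sz.L1 * B - sz.k2 + 1;
  c.Lfull = Lfull;
  c.A2f.zeros(sz.F2, Lfull);
  const int ldW2 = sz.k2 * sz.F1;
  for (int j = 0; j < sz.k2; ++j)
    sgemm_acc('T', 'N', sz.F2, (int)Lfull, sz.F1, 1.0f,
              p.W2.memptr() + (size_t)j * sz.F1, ldW2,
              c.A1.colptr(j), sz.F1, 1.0f, c.A2f.memptr(), sz.F2);
  c.A2f.each_col() += p.b2;
  elu_inplace(c.A2f);

  // gather the per-sample valid windows into the flat dense input
  c.Flat.set_size((size_t)sz.flat, B);
  for (int b = 0; b < B; ++b) {
    const fmat blk = c.A2f.cols((size_t)b * sz.L1,
                                (size_t)b * sz.L1 + sz.L2 - 1);
    std::copy(blk.memptr(), blk.memptr() + (size_t)sz.F2 * sz.L2,
              c.Flat.colptr(b));
  }
  if (train && drop_rate > 0.0f && rng) {
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    c.drop.set_size(arma::size(c.Flat));
    const float keep = 1.0f - drop_rate;
    c.drop.for_each([&](float& v) { v = (ud(*rng) < keep) ? 1.0f / keep : 0.0f; });
    c.Flat %= c.drop;
  }
  c.H = p.W3.t() * c.Flat;
  c.H.each_col() += p.b3;
  elu_inplace(c.H);
  c.out = p.W4.t() * c.H;
  c.out.each_col() += p.b4;
}

// [[Rcpp::export]]
List train_cnn1d_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                     const arma::mat& Xval, const arma::vec& yval,
                     const List hyper, const int seed) {
  Sizes sz;
  sz.L = Xtr.n_cols;
  sz.k1 = as<int>(hyper["conv1_kernel"]);
  sz.F1 = as<int>(hyper["conv1_filters"]);
  sz.k2 = as<int>(hyper["conv2_kernel"]);
  sz.F2 = as<int>(hyper["conv2_filters"]);
  sz.D = as<int>(hyper["dense_units"]);
  sz.L1 = sz.L - sz.k1 + 1;
  sz.L2 = sz.L1 - sz.k2 + 1;
  sz.flat = sz.L2 * sz.F2;
  const float lr = as<double>(hyper["learning_rate"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int patience = as<int>(hyper["early_stop_patience"]);
  const float delta = as<double>(hyper["huber_delta"]);
  const float noise_sd = as<double>(hyper["input_noise_sd"]);
  const float drop_rate = as<double>(hyper["dropout_rate"]);
  const bool verbose = hyper.containsElementNamed("verbose") ?
    as<bool>(hyper["verbose"]) : false;

  if (Xval.n_rows == 0) stop("validation set must not be empty");

  const int Ntr = Xtr.n_rows;
  fmat Xt = arma::conv_to<fmat>::from(Xtr.t());   // L x N
  fvec yt = arma::conv_to<fvec>::from(ytr);
  fmat Xv = arma::conv_to<fmat>::from(Xval.t());
  fvec yv = arma::conv_to<fvec>::from(yval);

  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int fan_in, int fan_out, int r, int c) {
    const float lim = std::sqrt(6.0f / (fan_in + fan_out));
    std::uniform_real_distribution<float> ud(-lim, lim);
    fmat w(r, c);
    w.for_each([&](float& v) { v = ud(rng); });
    return w;
  };
  CNN1DParams p;
  p.W1 = glorot(sz.k1, sz.F1, sz.k1, sz.F1);
  p.b1 = arma::zeros<fvec>(sz.F1);
  p.W2 = glorot(sz.k2 * sz.F1, sz.F2, sz.k2 * sz.F1, sz.F2);
  p.b2 = arma::zeros<fvec>(sz.F2);
  p.W3 = glorot(sz.flat, sz.D, sz.flat, sz.D);
  p.b3 = arma::zeros<fvec>(sz.D);
  p.W4 = glorot(sz.D, 1, sz.D, 1);
  p.b4 = arma::zeros<fvec>(1);

  Adam opt;
  opt.init(p, lr);

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  std::vector<double> h_loss, h_val_loss, h_val_mae, h_val_rmse, h_val_r2;
  CNN1DParams best = p;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, wait = 0, epochs_run = 0;
  Cache c;

  auto huber_mean = [&](const fvec& r) {
    double acc = 0;
    for (auto v : r) {
      const float a = std::fabs(v);
      acc += (a <= delta) ? 0.5 * a * a : delta * (a - 0.5 * delta);
    }
    return acc / r.n_elem;
  };

  auto predict_all = [&](const fmat& X) {
    const int N = X.n_cols;
    fvec out(N);
    Cache cc;
    for (int s0 = 0; s0 < N; s0 += 512) {
      const int s1 = std::min(s0 + 512, N) - 1;
      forward(X.cols(s0, s1), p, sz, cc, false, 0.0f, 0.0f, nullptr);
      out.subvec(s0, s1) = cc.out.row(0).t();
    }
    return out;
  };

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int nb = 0;
    for (int s0 = 0; s0 < Ntr; s0 += batch) {
      const int B = std::min(batch, Ntr - s0);
      fmat Xb(sz.L, B);
      fvec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.col(i) = Xt.col(order[s0 + i]);
        yb(i) = yt(order[s0 + i]);
      }
      forward(Xb, p, sz, c, true, noise_sd, drop_rate, &rng);

      fvec r = c.out.row(0).t() - yb;
      ep_loss += huber_mean(r);
      ++nb;
      fvec g = r;
      g.for_each([&](float& v) {
        v = (std::fabs(v) <= delta) ? v : delta * ((v > 0) - (v < 0)); });
      fmat dOut = (g / (float)B).t();                  // 1 x B

      std::vector<fmat> gW(4);
      std::vector<fvec> gb(4);
      gW[3] = c.H * dOut.t();                          // D x 1
      gb[3] = arma::sum(dOut, 1);
      fmat dH = p.W4 * dOut;
      elu_grad_mul(dH, c.H);
      gW[2] = c.Flat * dH.t();
      gb[2] = arma::sum(dH, 1);
      fmat dFlat = p.W3 * dH;                          // flat x B
      if (drop_rate > 0.0f) dFlat %= c.drop;

      // scatter per-sample blocks back onto the concatenated conv2 axis
      fmat dA2f(sz.F2, c.Lfull, arma::fill::zeros);
      for (int b = 0; b < B; ++b)
        std::copy(dFlat.colptr(b), dFlat.colptr(b) + (size_t)sz.flat,
                  dA2f.colptr((size_t)b * sz.L1));
      elu_grad_mul(dA2f, c.A2f);

      gW[1].set_size((size_t)sz.k2 * sz.F1, sz.F2);
      fmat dA1(sz.F1, (size_t)sz.L1 * B, arma::fill::zeros);
      const int ldW2b = sz.k2 * sz.F1;
      for (int j = 0; j < sz.k2; ++j) {
        sgemm_acc('N', 'T', sz.F1, sz.F2, (int)c.Lfull, 1.0f,
                  c.A1.colptr(j), sz.F1, dA2f.memptr(), sz.F2, 0.0f,
                  gW[1].memptr() + (size_t)j * sz.F1, ldW2b);
        sgemm_acc('N', 'N', sz.F1, (int)c.Lfull, sz.F2, 1.0f,
                  p.W2.memptr() + (size_t)j * sz.F1, ldW2b,
                  dA2f.memptr(), sz.F2, 1.0f, dA1.colptr(j), sz.F1);
      }
      gb[1] = arma::sum(dA2f, 1);
      elu_grad_mul(dA1, c.A1);
      gW[0] = c.C1 * dA1.t();
      gb[0] = arma::sum(dA1, 1);

      opt.step(p, gW, gb);
    }
    epochs_run = ep + 1;
    fvec pv = predict_all(Xv);
    fvec rv = pv - yv;
    const double vloss = huber_mean(rv);
    const double vmae = arma::mean(arma::abs(rv));
    const double vrmse = std::sqrt(arma::mean(arma::square(rv)));
    const double sstot = arma::accu(arma::square(yv - arma::mean(yv)));
    const double vr2 = (sstot > 0) ?
      1.0 - arma::accu(arma::square(rv)) / sstot : NA_REAL;
    h_loss.push_back(ep_loss / nb);
    h_val_loss.push_back(vloss);
    h_val_mae.push_back(vmae);
    h_val_rmse.push_back(vrmse);
    h_val_r2.push_back(vr2);
    if (verbose)
      Rcout << "epoch " << ep + 1 << " loss " << ep_loss / nb
            << " val_loss " << vloss << " val_r2 " << vr2 << "\n";

    if (vloss < best_val - 1e-9) {
      best_val = vloss;
      best = p;
      best_epoch = ep + 1;
      wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  p = best;   // reinstate optimal weights

  auto wrap_f = [](const fmat& m) {
    return wrap(arma::conv_to<arma::mat>::from(m));
  };
  auto wrap_v = [](const fvec& v) {
    return wrap(arma::conv_to<arma::vec>::from(v));
  };
  return List::create(
    _["weights"] = List::create(
      _["W1"] = wrap_f(best.W1), _["b1"] = wrap_v(best.b1),
      _["W2"] = wrap_f(best.W2), _["b2"] = wrap_v(best.b2),
      _["W3"] = wrap_f(best.W3), _["b3"] = wrap_v(best.b3),
      _["W4"] = wrap_f(best.W4), _["b4"] = wrap_v(best.b4)),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs_run), _["loss"] = h_loss,
      _["val_loss"] = h_val_loss, _["val_mae"] = h_val_mae,
      _["val_rmse"] = h_val_rmse, _["val_r2"] = h_val_r2),
    _["best_epoch"] = best_epoch,
    _["best_val_loss"] = best_val,
    _["epochs_run"] = epochs_run);
}

// [[Rcpp::export]]
arma::vec predict_cnn1d_cpp(const arma::mat& X, const List weights,
                            const List hyper) {
  Sizes sz;
  sz.L = X.n_cols;
  sz.k1 = as<int>(hyper["conv1_kernel"]);
  sz.F1 = as<int>(hyper["conv1_filters"]);
  sz.k2 = as<int>(hyper["conv2_kernel"]);
  sz.F2 = as<int>(hyper["conv2_filters"]);
  sz.D = as<int>(hyper["dense_units"]);
  sz.L1 = sz.L - sz.k1 + 1;
  sz.L2 = sz.L1 - sz.k2 + 1;
  sz.flat = sz.L2 * sz.F2;
  CNN1DParams p;
  p.W1 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W1"]));
  p.b1 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b1"]));
  p.W2 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W2"]));
  p.b2 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b2"]));
  p.W3 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W3"]));
  p.b3 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b3"]));
  p.W4 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W4"]));
  p.b4 = arma::conv_to<fvec>::from(as<arma::vec>(weights["b4"]));

  fmat Xt = arma::conv_to<fmat>::from(X.t());
  const int N = Xt.n_cols;
  arma::vec out(N);
  Cache c;
  for (int s0 = 0; s0 < N; s0 += 512) {
    const int s1 = std::min(s0 + 512, N) - 1;
    forward(Xt.cols(s0, s1), p, sz, c, false, 0.0f, 0.0f, nullptr);
    for (int i = s0; i <= s1; ++i) out(i) = c.out(0, i - s0);
  }
  return out;
}
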