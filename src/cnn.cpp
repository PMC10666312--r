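// Convolutional regression core: one-hot DNA window -> conv/ReLU/maxpool
// blocks -> flatten -> concat(half-life, miRNA features) -> dense ReLU
// (+ optional dropout) -> linear output. Trained with plain SGD on MSE,
// early stopping on validation loss with best-epoch weight restoration.
//
// Templated on the element type: float for training/prediction speed,
// double for the finite-difference gradient checks in the test suite.
//
// Sequences are passed as integer code matrices (n_genes x W) with
// 0 = N/ambiguous (all-zero one-hot row), 1..4 = A,C,G,T.

#include <RcppArmadillo.h>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Arch {
  int W;            // window length (bases)
  int n_extra;      // half-life + miRNA feature count
  std::vector<int> filters, widths, dils, pools;
  int dense_units;
  // per-layer derived dims
  std::vector<int> Lin, Cin, Lout, Lp;
  int nflat;

  Arch(int W_, int n_extra_, const IntegerVector& f, const IntegerVector& w,
       const IntegerVector& d, const IntegerVector& p, int dense)
      : W(W_), n_extra(n_extra_), dense_units(dense) {
    int L = W, C = 4;
    for (int l = 0; l < f.size(); ++l) {
      filters.push_back(f[l]);
      widths.push_back(w[l]);
      dils.push_back(d[l]);
      pools.push_back(p[l]);
      Lin.push_back(L);
      Cin.push_back(C);
      int lo = L - (w[l] - 1) * d[l];
      if (lo < 1) stop("conv layer %d: receptive field exceeds input length", l + 1);
      int lp = lo / p[l];
      if (lp < 1) stop("conv layer %d: pooled length < 1", l + 1);
      Lout.push_back(lo);
      Lp.push_back(lp);
      L = lp;
      C = f[l];
    }
    nflat = L * C;
  }
  int n_layers() const { return (int)filters.size(); }
};

template <typename eT>
struct Params {
  std::vector<arma::Mat<eT>> Wc;
  std::vector<arma::Row<eT>> bc;
  arma::Mat<eT> W1;
  arma::Row<eT> b1;
  arma::Col<eT> w2;
  eT b2;
};

template <typename eT>
Params<eT> params_from_list(const List& wl) {
  Params<eT> p;
  List Wc = wl["Wc"], bc = wl["bc"];
  for (int l = 0; l < Wc.size(); ++l) {
    arma::mat W = as<arma::mat>(Wc[l]);
    arma::rowvec b = as<arma::rowvec>(bc[l]);
    p.Wc.push_back(arma::conv_to<arma::Mat<eT>>::from(W));
    p.bc.push_back(arma::conv_to<arma::Row<eT>>::from(b));
  }
  p.W1 = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(wl["W1"]));
  p.b1 = arma::conv_to<arma::Row<eT>>::from(as<arma::rowvec>(wl["b1"]));
  p.w2 = arma::conv_to<arma::Col<eT>>::from(as<arma::vec>(wl["w2"]));
  p.b2 = (eT)as<double>(wl["b2"]);
  return p;
}

template <typename eT>
List params_to_list(const Params<eT>& p) {
  List Wc(p.Wc.size()), bc(p.bc.size());
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    Wc[l] = wrap(arma::conv_to<arma::mat>::from(p.Wc[l]));
    bc[l] = wrap(arma::conv_to<arma::rowvec>::from(p.bc[l]));
  }
  return List::create(_["Wc"] = Wc, _["bc"] = bc,
                      _["W1"] = wrap(arma::conv_to<arma::mat>::from(p.W1)),
                      _["b1"] = wrap(arma::conv_to<arma::rowvec>::from(p.b1)),
                      _["w2"] = wrap(arma::conv_to<arma::vec>::from(p.w2)),
                      _["b2"] = (double)p.b2);
}

// He-uniform initialisation, own RNG so results are independent of R's state
template <typename eT>
Params<eT> init_params(const Arch& a, int seed) {
  std::mt19937 rng((unsigned)seed);
  Params<eT> p;
  auto he = [&](int fan_in, int nr, int nc) {
    double lim = std::sqrt(6.0 / fan_in);
    std::uniform_real_distribution<double> U(-lim, lim);
    arma::Mat<eT> M(nr, nc);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i) M(i, j) = (eT)U(rng);
    return M;
  };
  for (int l = 0; l < a.n_layers(); ++l) {
    int fan = a.widths[l] * a.Cin[l];
    p.Wc.push_back(he(fan, fan, a.filters[l]));
    p.bc.push_back(arma::Row<eT>(a.filters[l], arma::fill::zeros));
  }
  int nin = a.nflat + a.n_extra;
  p.W1 = he(nin, nin, a.dense_units);
  p.b1 = arma::Row<eT>(a.dense_units, arma::fill::zeros);
  arma::Mat<eT> w2m = he(a.dense_units, a.dense_units, 1);
  p.w2 = w2m.col(0);
  p.b2 = (eT)0;
  return p;
}

template <typename eT>
arma::Mat<eT> one_hot_batch(const IntegerMatrix& codes, const std::vector<int>& idx, int W) {
  int B = (int)idx.size();
  arma::Mat<eT> A(B * W, 4, arma::fill::zeros);
  for (int g = 0; g < B; ++g) {
    int r = idx[g];
    for (int pth = 0; pth < W; ++pth) {
      int c = codes(r, pth);
      if (c > 0) A(g * W + pth, c - 1) = (eT)1;
    }
  }
  return A;
}

template <typename eT>
arma::Mat<eT> im2col(const arma::Mat<eT>& A, int B, int Lin, int width, int dil, int Lout) {
  int C = A.n_cols;
  arma::Mat<eT> P(B * Lout, width * C);
  for (int g = 0; g < B; ++g)
    for (int o = 0; o < width; ++o)
      P.submat(g * Lout, o * C, g * Lout + Lout - 1, o * C + C - 1) =
          A.rows(g * Lin + o * dil, g * Lin + o * dil + Lout - 1);
  return P;
}

template <typename eT>
arma::Mat<eT> col2im(const arma::Mat<eT>& dP, int B, int Lin, int C, int width, int dil, int Lout) {
  arma::Mat<eT> dA(B * Lin, C, arma::fill::zeros);
  for (int g = 0; g < B; ++g)
    for (int o = 0; o < width; ++o)
      dA.rows(g * Lin + o * dil, g * Lin + o * dil + Lout - 1) +=
          dP.submat(g * Lout, o * C, g * Lout + Lout - 1, o * C + C - 1);
  return dA;
}

template <typename eT>
arma::Mat<eT> maxpool(const arma::Mat<eT>& Z, int B, int Lout, int pw, int Lp, arma::umat& amax) {
  int F = Z.n_cols;
  arma::Mat<eT> O(B * Lp, F);
  amax.set_size(B * Lp, F);
  for (int g = 0; g < B; ++g)
    for (int q = 0; q < Lp; ++q) {
      int base = g * Lout + q * pw;
      for (int f = 0; f < F; ++f) {
        int bi = base;
        eT bv = Z(base, f);
        for (int r = 1; r < pw; ++r)
          if (Z(base + r, f) > bv) { bv = Z(base + r, f); bi = base + r; }
        O(g * Lp + q, f) = bv;
        amax(g * Lp + q, f) = (arma::uword)bi;
      }
    }
  return O;
}

template <typename eT>
struct Cache {
  std::vector<arma::Mat<eT>> P;      // im2col inputs per conv layer (empty for layer 0)
  std::vector<arma::Mat<eT>> Zpre;   // pre-ReLU conv outputs (layer 0: pooled output)
  std::vector<arma::umat> amax;      // argmax rows per pool
  arma::Mat<eT> D;                   // dense input (B x nflat+n_extra)
  arma::Mat<eT> Hpre, H;             // dense hidden pre/post activation
  arma::Mat<eT> drop;                // inverted-dropout mask (empty if unused)
};

// first conv layer specialised for one-hot input: a convolution over a
// one-hot sequence is a per-position lookup-sum of weight rows, so the
// dense im2col GEMM is skipped entirely (ReLU fused)
template <typename eT>
arma::Mat<eT> conv1_onehot(const Params<eT>& p, const Arch& a,
                           const IntegerMatrix& codes, const std::vector<int>& idx) {
  int B = (int)idx.size(), Lin = a.Lin[0], Lout = a.Lout[0];
  int w = a.widths[0], dil = a.dils[0], F = a.filters[0];
  arma::Mat<eT> Z(B * Lout, F);
  std::vector<int> cg(Lin);
  // weight table padded with a zero slot at code 0 so the inner loop is
  // branchless: wext[o*5 + code], code 0 (= N) contributes 0
  std::vector<eT> wext((size_t)w * 5);
  for (int g = 0; g < B; ++g) {
    int r = idx[g];
    for (int q = 0; q < Lin; ++q) cg[q] = codes(r, q);
    for (int f = 0; f < F; ++f) {
      const eT* wc = p.Wc[0].colptr(f);
      for (int o = 0; o < w; ++o) {
        wext[o * 5] = (eT)0;
        for (int b = 0; b < 4; ++b) wext[o * 5 + b + 1] = wc[o * 4 + b];
      }
      eT bias = p.bc[0](f);
      eT* zc = Z.colptr(f) + g * Lout;
      for (int q = 0; q < Lout; ++q) {
        eT acc = bias;
        const int* cq = cg.data() + q;
        for (int o = 0; o < w; ++o) acc += wext[o * 5 + cq[o * dil]];
        zc[q] = acc > (eT)0 ? acc : (eT)0;
      }
    }
  }
  return Z;
}

template <typename eT>
arma::Col<eT> forward(const Params<eT>& p, const Arch& a, const IntegerMatrix& codes,
                      const arma::Mat<eT>& extra, const std::vector<int>& idx,
                      Cache<eT>* cache, double dropout, std::mt19937* rng) {
  int B = (int)idx.size();
  arma::Mat<eT> A;
  if (a.n_layers() == 0) A = one_hot_batch<eT>(codes, idx, a.W);
  for (int l = 0; l < a.n_layers(); ++l) {
    arma::Mat<eT> Zr;
    if (l == 0) {
      Zr = conv1_onehot<eT>(p, a, codes, idx);
      if (cache) cache->P.push_back(arma::Mat<eT>());
    } else {
      arma::Mat<eT> P = im2col<eT>(A, B, a.Lin[l], a.widths[l], a.dils[l], a.Lout[l]);
      arma::Mat<eT> Z = P * p.Wc[l];
      Z.each_row() += p.bc[l];
      if (cache) {
        cache->P.push_back(P);
        cache->Zpre.push_back(Z);
      }
      Zr = arma::clamp(Z, (eT)0, std::numeric_limits<eT>::max());
    }
    arma::umat amax;
    A = maxpool<eT>(Zr, B, a.Lout[l], a.pools[l], a.Lp[l], amax);
    if (cache) {
      cache->amax.push_back(amax);
      if (l == 0) {
        // layer 0 stores its pooled activations: a positive pooled value
        // certifies the winning pre-activation was positive (ReLU mask)
        cache->Zpre.insert(cache->Zpre.begin(), A);
      }
    }
  }
  // flatten position-major per gene, then append extra features
  int Lp = a.n_layers() ? a.Lp.back() : a.W;
  int F = a.n_layers() ? a.filters.back() : 4;
  arma::Mat<eT> D(B, a.nflat + a.n_extra);
  for (int g = 0; g < B; ++g)
    for (int q = 0; q < Lp; ++q)
      for (int f = 0; f < F; ++f) D(g, q * F + f) = A(g * Lp + q, f);
  for (int g = 0; g < B; ++g)
    for (int j = 0; j < a.n_extra; ++j) D(g, a.nflat + j) = extra(idx[g], j);
  arma::Mat<eT> Hpre = D * p.W1;
  Hpre.each_row() += p.b1;
  arma::Mat<eT> H = arma::clamp(Hpre, (eT)0, std::numeric_limits<eT>::max());
  arma::Mat<eT> drop;
  if (dropout > 0 && rng) {
    std::bernoulli_distribution keep(1.0 - dropout);
    drop.set_size(H.n_rows, H.n_cols);
    eT scale = (eT)(1.0 / (1.0 - dropout));
    for (arma::uword j = 0; j < H.n_cols; ++j)
      for (arma::uword i = 0; i < H.n_rows; ++i) drop(i, j) = keep(*rng) ? scale : (eT)0;
    H %= drop;
  }
  if (cache) {
    cache->D = D;
    cache->Hpre = Hpre;
    cache->H = H;
    cache->drop = drop;
  }
  return H * p.w2 + p.b2;
}

// MSE backward pass; returns gradients in the same shapes as the parameters
template <typename eT>
Params<eT> backward(const Params<eT>& p, const Arch& a, const Cache<eT>& c,
                    const arma::Col<eT>& yhat, const arma::Col<eT>& y,
                    const IntegerMatrix& codes, const std::vector<int>& idx) {
  int B = (int)y.n_elem;
  Params<eT> g;
  arma::Col<eT> dy = (eT)(2.0 / B) * (yhat - y);
  g.b2 = arma::accu(dy);
  g.w2 = c.H.t() * dy;
  arma::Mat<eT> dH = dy * p.w2.t();
  if (c.drop.n_elem) dH %= c.drop;
  arma::Mat<eT> dHpre = dH % arma::conv_to<arma::Mat<eT>>::from(c.Hpre > (eT)0);
  g.W1 = c.D.t() * dHpre;
  g.b1 = arma::sum(dHpre, 0);
  arma::Mat<eT> dD = dHpre * p.W1.t();

  int nl = a.n_layers();
  g.Wc.resize(nl);
  g.bc.resize(nl);
  if (nl == 0) return g;
  // un-flatten conv part of dD
  int Lp = a.Lp.back();
  int F = a.filters.back();
  arma::Mat<eT> dO(B * Lp, F);
  for (int gg = 0; gg < B; ++gg)
    for (int q = 0; q < Lp; ++q)
      for (int f = 0; f < F; ++f) dO(gg * Lp + q, f) = dD(gg, q * F + f);

  for (int l = nl - 1; l >= 1; --l) {
    // un-pool: scatter into pre-pool shape at the argmax rows
    arma::Mat<eT> dZr(B * a.Lout[l], a.filters[l], arma::fill::zeros);
    for (arma::uword j = 0; j < dO.n_cols; ++j)
      for (arma::uword i = 0; i < dO.n_rows; ++i) dZr(c.amax[l](i, j), j) += dO(i, j);
    arma::Mat<eT> dZ = dZr % arma::conv_to<arma::Mat<eT>>::from(c.Zpre[l] > (eT)0);
    g.Wc[l] = c.P[l].t() * dZ;
    g.bc[l] = arma::sum(dZ, 0);
    arma::Mat<eT> dP = dZ * p.Wc[l].t();
    dO = col2im<eT>(dP, B, a.Lin[l], a.Cin[l], a.widths[l], a.dils[l], a.Lout[l]);
  }
  // layer 0 (one-hot input): the pooled gradient is sparse — scatter the
  // surviving entries straight into the weight rows picked out by the
  // base codes at the winning positions
  {
    int w = a.widths[0], dil = a.dils[0], F = a.filters[0], Lout = a.Lout[0];
    g.Wc[0].zeros(w * 4, F);
    g.bc[0].zeros(F);
    const arma::Mat<eT>& O0 = c.Zpre[0];   // pooled activations of layer 0
    for (int f = 0; f < F; ++f)
      for (arma::uword i = 0; i < dO.n_rows; ++i) {
        eT v = dO(i, f);
        if (v == (eT)0 || O0(i, f) <= (eT)0) continue;
        arma::uword src = c.amax[0](i, f);
        int gg = (int)(src / Lout), q = (int)(src % Lout);
        int r = idx[gg];
        g.bc[0](f) += v;
        for (int o = 0; o < w; ++o) {
          int cc = codes(r, q + o * dil);
          if (cc) g.Wc[0](o * 4 + cc - 1, f) += v;
        }
      }
  }
  return g;
}

template <typename eT>
void sgd_step(Params<eT>& p, const Params<eT>& g, eT lr) {
  for (size_t l = 0; l < p.Wc.size(); ++l) {
    p.Wc[l] -= lr * g.Wc[l];
    p.bc[l] -= lr * g.bc[l];
  }
  p.W1 -= lr * g.W1;
  p.b1 -= lr * g.b1;
  p.w2 -= lr * g.w2;
  p.b2 -= lr * g.b2;
}

template <typename eT>
double mse_over(const Params<eT>& p, const Arch& a, const IntegerMatrix& codes,
                const arma::Mat<eT>& extra, const arma::Col<eT>& y, int chunk = 128) {
  int n = (int)y.n_elem;
  double sse = 0;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    arma::Col<eT> yh = forward<eT>(p, a, codes, extra, idx, nullptr, 0.0, nullptr);
    for (int i = s; i < e; ++i) {
      double d = (double)yh(i - s) - (double)y(i);
      sse += d * d;
    }
  }
  return sse / n;
}

// [[Rcpp::export]]
List cnn_fit(IntegerMatrix seq_tr, NumericMatrix ex_tr, NumericVector y_tr,
             IntegerMatrix seq_va, NumericMatrix ex_va, NumericVector y_va,
             IntegerVector filters, IntegerVector widths, IntegerVector dils,
             IntegerVector pools, int dense_units, double dropout,
             int batch_size, double lr, int max_epochs, int patience, int seed) {
  typedef float eT;
  Arch a(seq_tr.ncol(), ex_tr.ncol(), filters, widths, dils, pools, dense_units);
  int n_tr = seq_tr.nrow();
  arma::Mat<eT> Etr = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(ex_tr));
  arma::Mat<eT> Eva = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(ex_va));
  arma::Col<eT> ytr = arma::conv_to<arma::Col<eT>>::from(as<arma::vec>(y_tr));
  arma::Col<eT> yva = arma::conv_to<arma::Col<eT>>::from(as<arma::vec>(y_va));

  std::mt19937 rng((unsigned)seed + 1u);
  Params<eT> p = init_params<eT>(a, seed);
  Params<eT> best = p;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, epochs_run = 0;
  std::vector<double> tr_curve, va_curve;
  std::vector<int> perm(n_tr);
  for (int i = 0; i < n_tr; ++i) perm[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double sse = 0;
    for (int s = 0; s < n_tr; s += batch_size) {
      int e = std::min(n_tr, s + batch_size);
      std::vector<int> idx(perm.begin() + s, perm.begin() + e);
      Cache<eT> cache;
      arma::Col<eT> yh = forward<eT>(p, a, seq_tr, Etr, idx, &cache, dropout, &rng);
      arma::Col<eT> yb(idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yb(i) = ytr(idx[i]);
      arma::Col<eT> resid = yh - yb;
      sse += (double)arma::dot(resid, resid);
      if (lr > 0) {
        Params<eT> g = backward<eT>(p, a, cache, yh, yb, seq_tr, idx);
        sgd_step<eT>(p, g, (eT)lr);
      }
    }
    double tr_loss = sse / n_tr;
    double va_loss = mse_over<eT>(p, a, seq_va, Eva, yva);
    if (!std::isfinite(tr_loss) || !std::isfinite(va_loss))
      stop("training diverged at epoch %d (non-finite loss); lower the learning rate", epoch);
    tr_curve.push_back(tr_loss);
    va_curve.push_back(va_loss);
    epochs_run = epoch;
    if (va_loss < best_val) {
      best_val = va_loss;
      best_epoch = epoch;
      best = p;
    }
    if (epoch - best_epoch >= patience) break;
  }
  return List::create(_["weights"] = params_to_list<eT>(best),
                      _["train_loss"] = wrap(tr_curve), _["val_loss"] = wrap(va_curve),
                      _["best_epoch"] = best_epoch, _["epochs_run"] = epochs_run,
                      _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
NumericVector cnn_forward(List weights, IntegerMatrix seqs, NumericMatrix extra,
                          IntegerVector filters, IntegerVector widths, IntegerVector dils,
                          IntegerVector pools, int dense_units) {
  typedef float eT;
  Arch a(seqs.ncol(), extra.ncol(), filters, widths, dils, pools, dense_units);
  Params<eT> p = params_from_list<eT>(weights);
  arma::Mat<eT> E = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(extra));
  int n = seqs.nrow();
  NumericVector out(n);
  int chunk = 128;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    arma::Col<eT> yh = forward<eT>(p, a, seqs, E, idx, nullptr, 0.0, nullptr);
    for (int i = s; i < e; ++i) out[i] = (double)yh(i - s);
  }
  return out;
}

// [[Rcpp::export]]
List cnn_init_weights(int W, int n_extra, IntegerVector filters, IntegerVector widths,
                      IntegerVector dils, IntegerVector pools, int dense_units, int seed) {
  IntegerMatrix dummy(1, W);
  Arch a(W, n_extra, filters, widths, dils, pools, dense_units);
  return params_to_list<double>(init_params<double>(a, seed));
}

// double-precision loss and analytic gradient, used by the test suite's
// finite-difference oracle
// [[Rcpp::export]]
double cnn_mse_dbl(List weights, IntegerMatrix seqs, NumericMatrix extra, NumericVector y,
                   IntegerVector filters, IntegerVector widths, IntegerVector dils,
                   IntegerVector pools, int dense_units) {
  Arch a(seqs.ncol(), extra.ncol(), filters, widths, dils, pools, dense_units);
  Params<double> p = params_from_list<double>(weights);
  arma::mat E = as<arma::mat>(extra);
  arma::vec yy = as<arma::vec>(y);
  return mse_over<double>(p, a, seqs, E, yy, seqs.nrow());
}

// [[Rcpp::export]]
List cnn_grad_dbl(List weights, IntegerMatrix seqs, NumericMatrix extra, NumericVector y,
                  IntegerVector filters, IntegerVector widths, IntegerVector dils,
                  IntegerVector pools, int dense_units) {
  Arch a(seqs.ncol(), extra.ncol(), filters, widths, dils, pools, dense_units);
  Params<double> p = params_from_list<double>(weights);
  arma::mat E = as<arma::mat>(extra);
  arma::vec yy = as<arma::vec>(y);
  int n = seqs.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Cache<double> cache;
  arma::vec yh = forward<double>(p, a, seqs, E, idx, &cache, 0.0, nullptr);
  Params<double> g = backward<double>(p, a, cache, yh, yy, seqs, idx);
  return params_to_list<double>(g);
}
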