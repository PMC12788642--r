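// Compact two-block convolutional network for pseudo-image classification:
//   [conv 3x3 same -> batchnorm -> ReLU -> maxpool 2x2] x 2
//   -> dense(relu) -> dropout -> dense(1) -> sigmoid, binary cross-entropy.
// Trained with Adam, learning-rate reduction on validation-loss plateau and
// early stopping with best-weight restoration.  All randomness (weight
// initialisation, epoch shuffling, dropout masks) comes from a private
// mt19937 stream so that a fit is bit-reproducible given its seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::umat;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(unsigned int seed) : gen(seed) {}
  double unif() { return (gen() + 0.5) / 4294967296.0; }
  // explicit Box-Muller: std::normal_distribution is not portable
  double norm() {
    const double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Fisher-Yates shuffle
  void shuffle(std::vector<arma::uword>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = (size_t)(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
  }
};

// neighbour table for 3x3 same-padding convolution on an H x W grid
// (row-major pixel order); entry -1 marks a padded position.
arma::imat neighbour_table(int H, int W) {
  arma::imat nb(H * W, 9);
  int o = 0;
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc, ++o) {
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          const int r2 = r + dr, c2 = c + dc;
          nb(r * W + c, o) =
              (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W) ? r2 * W + c2 : -1;
        }
      }
    }
  }
  return nb;
}

// im2col: activations A ((B*HW) x C, sample-major rows) -> patches (B*HW) x 9C
mat build_patches(const mat& A, const arma::imat& nb, int B, int HW) {
  const int C = A.n_cols;
  mat P(B * HW, 9 * C, arma::fill::zeros);
  for (int o = 0; o < 9; ++o) {
    for (int c = 0; c < C; ++c) {
      const double* src = A.colptr(c);
      double* dst = P.colptr(o * C + c);
      for (int s = 0; s < B; ++s) {
        const int base = s * HW;
        for (int pix = 0; pix < HW; ++pix) {
          const long n2 = nb(pix, o);
          if (n2 >= 0) dst[base + pix] = src[base + n2];
        }
      }
    }
  }
  return P;
}

// transpose of build_patches: accumulate patch gradients back onto dA
void scatter_patches(const mat& dP, const arma::imat& nb, int B, int HW, mat& dA) {
  const int C = dA.n_cols;
  for (int o = 0; o < 9; ++o) {
    for (int c = 0; c < C; ++c) {
      const double* src = dP.colptr(o * C + c);
      double* dst = dA.colptr(c);
      for (int s = 0; s < B; ++s) {
        const int base = s * HW;
        for (int pix = 0; pix < HW; ++pix) {
          const long n2 = nb(pix, o);
          if (n2 >= 0) dst[base + n2] += src[base + pix];
        }
      }
    }
  }
}

// 2x2 max-pool, stride 2, incomplete windows dropped (output floor(H/2) etc.)
void pool_fwd(const mat& A, int B, int H, int W, mat& Y, umat& arg) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  Y.set_size(B * HW2, C);
  arg.set_size(B * HW2, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = Y.colptr(c);
    arma::uword* am = arg.colptr(c);
    for (int s = 0; s < B; ++s) {
      const int ib = s * HW, ob = s * HW2;
      for (int r2 = 0; r2 < H2; ++r2) {
        for (int c2 = 0; c2 < W2; ++c2) {
          const int cand[4] = {ib + (2 * r2) * W + 2 * c2,
                               ib + (2 * r2) * W + 2 * c2 + 1,
                               ib + (2 * r2 + 1) * W + 2 * c2,
                               ib + (2 * r2 + 1) * W + 2 * c2 + 1};
          int best = cand[0];
          for (int k = 1; k < 4; ++k)
            if (src[cand[k]] > src[best]) best = cand[k];
          dst[ob + r2 * W2 + c2] = src[best];
          am[ob + r2 * W2 + c2] = best;
        }
      }
    }
  }
}

void pool_bwd(const mat& dY, const umat& arg, int rowsA, mat& dA) {
  const int C = dY.n_cols;
  dA.zeros(rowsA, C);
  for (int c = 0; c < C; ++c) {
    const double* g = dY.colptr(c);
    const arma::uword* am = arg.colptr(c);
    double* dst = dA.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) dst[am[r]] += g[r];
  }
}

struct BNCache { mat xhat; arma::rowvec invstd; };

const double BN_EPS = 1e-5;

mat bn_fwd_train(const mat& Z, const arma::rowvec& g, const arma::rowvec& be,
                 arma::rowvec& rmu, arma::rowvec& rvar, double mom, BNCache& cc) {
  const arma::rowvec mu = arma::mean(Z, 0);
  arma::rowvec var = arma::var(Z, 1, 0);  // biased
  cc.invstd = 1.0 / arma::sqrt(var + BN_EPS);
  cc.xhat = (Z.each_row() - mu).each_row() % cc.invstd;
  rmu = mom * rmu + (1.0 - mom) * mu;
  rvar = mom * rvar + (1.0 - mom) * var;
  return (cc.xhat.each_row() % g).each_row() + be;
}

mat bn_fwd_infer(const mat& Z, const arma::rowvec& g, const arma::rowvec& be,
                 const arma::rowvec& rmu, const arma::rowvec& rvar) {
  const arma::rowvec invstd = 1.0 / arma::sqrt(rvar + BN_EPS);
  mat xhat = (Z.each_row() - rmu).each_row() % invstd;
  return (xhat.each_row() % g).each_row() + be;
}

mat bn_bwd(const mat& dY, const arma::rowvec& g, const BNCache& cc,
           arma::rowvec& dg, arma::rowvec& dbe) {
  const double m = (double)dY.n_rows;
  dg = arma::sum(dY % cc.xhat, 0);
  dbe = arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  arma::rowvec s1 = arma::sum(dxhat, 0);
  arma::rowvec s2 = arma::sum(dxhat % cc.xhat, 0);
  mat dx = m * dxhat;
  dx.each_row() -= s1;
  dx -= cc.xhat.each_row() % s2;
  dx.each_row() %= (cc.invstd / m);
  return dx;
}

struct Adam { mat m, v; };

void adam_step(mat& w, const mat& g, Adam& st, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  if (st.m.n_elem == 0) { st.m.zeros(w.n_rows, w.n_cols); st.v.zeros(w.n_rows, w.n_cols); }
  st.m = b1 * st.m + (1.0 - b1) * g;
  st.v = b2 * st.v + (1.0 - b2) * (g % g);
  const double corr = lr * std::sqrt(1.0 - std::pow(b2, t)) / (1.0 - std::pow(b1, t));
  w -= corr * (st.m / (arma::sqrt(st.v) + eps));
}

struct Net {
  int H, W, H2, W2, H4, W4, f1, f2, dense, flat;
  mat Wc1, Wc2, Wd1, Wd2;
  arma::rowvec bc1, bc2, bd1, bd2v;
  arma::rowvec g1, be1, rm1, rv1, g2, be2, rm2, rv2;
  arma::imat nb1, nb2;
};

void net_init(Net& n, int H, int W, int f1, int f2, int dense, Rng& rng) {
  n.H = H; n.W = W; n.H2 = H / 2; n.W2 = W / 2; n.H4 = n.H2 / 2; n.W4 = n.W2 / 2;
  if (n.H4 < 1 || n.W4 < 1) stop("image grid too small for two 2x2 pooling stages");
  n.f1 = f1; n.f2 = f2; n.dense = dense; n.flat = n.H4 * n.W4 * f2;
  auto fill_norm = [&rng](mat& M, int r, int c, double sd) {
    M.set_size(r, c);
    for (arma::uword i = 0; i < M.n_elem; ++i) M(i) = sd * rng.norm();
  };
  fill_norm(n.Wc1, 9, f1, std::sqrt(2.0 / 9.0));
  fill_norm(n.Wc2, 9 * f1, f2, std::sqrt(2.0 / (9.0 * f1)));
  fill_norm(n.Wd1, n.flat, dense, std::sqrt(2.0 / n.flat));
  fill_norm(n.Wd2, dense, 1, std::sqrt(1.0 / dense));
  n.bc1.zeros(f1); n.bc2.zeros(f2); n.bd1.zeros(dense); n.bd2v.zeros(1);
  n.g1.ones(f1); n.be1.zeros(f1); n.rm1.zeros(f1); n.rv1.ones(f1);
  n.g2.ones(f2); n.be2.zeros(f2); n.rm2.zeros(f2); n.rv2.ones(f2);
  n.nb1 = neighbour_table(H, W);
  n.nb2 = neighbour_table(n.H2, n.W2);
}

// inference-mode forward; X rows are samples, columns row-major pixels
arma::vec net_predict(const Net& n, const mat& X) {
  const int B = X.n_rows, HW = n.H * n.W;
  mat A0(B * HW, 1);
  for (int s = 0; s < B; ++s)
    for (int pix = 0; pix < HW; ++pix) A0(s * HW + pix, 0) = X(s, pix);
  mat Z1 = build_patches(A0, n.nb1, B, HW) * n.Wc1;
  Z1.each_row() += n.bc1;
  mat A1 = bn_fwd_infer(Z1, n.g1, n.be1, n.rm1, n.rv1);
  A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat P1; umat arg1;
  pool_fwd(A1, B, n.H, n.W, P1, arg1);
  mat Z2 = build_patches(P1, n.nb2, B, n.H2 * n.W2) * n.Wc2;
  Z2.each_row() += n.bc2;
  mat A2 = bn_fwd_infer(Z2, n.g2, n.be2, n.rm2, n.rv2);
  A2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat P2; umat arg2;
  pool_fwd(A2, B, n.H2, n.W2, P2, arg2);
  const int HW4 = n.H4 * n.W4;
  mat F(B, n.flat);
  for (int c = 0; c < n.f2; ++c)
    for (int pix = 0; pix < HW4; ++pix)
      for (int s = 0; s < B; ++s) F(s, c * HW4 + pix) = P2(s * HW4 + pix, c);
  mat D1 = F * n.Wd1;
  D1.each_row() += n.bd1;
  D1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat Z = D1 * n.Wd2;
  Z.each_row() += n.bd2v;
  return 1.0 / (1.0 + arma::exp(-Z.col(0)));
}

double bce_loss(const arma::vec& p, const arma::vec& y) {
  const arma::vec pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

List net_to_list(const Net& n) {
  return List::create(
      _["H"] = n.H, _["W"] = n.W, _["filters"] = IntegerVector::create(n.f1, n.f2),
      _["dense"] = n.dense,
      _["Wc1"] = wrap(n.Wc1), _["bc1"] = wrap(n.bc1),
      _["g1"] = wrap(n.g1), _["be1"] = wrap(n.be1),
      _["rm1"] = wrap(n.rm1), _["rv1"] = wrap(n.rv1),
      _["Wc2"] = wrap(n.Wc2), _["bc2"] = wrap(n.bc2),
      _["g2"] = wrap(n.g2), _["be2"] = wrap(n.be2),
      _["rm2"] = wrap(n.rm2), _["rv2"] = wrap(n.rv2),
      _["Wd1"] = wrap(n.Wd1), _["bd1"] = wrap(n.bd1),
      _["Wd2"] = wrap(n.Wd2), _["bd2"] = wrap(n.bd2v));
}

Net net_from_list(const List& m) {
  Net n;
  IntegerVector f = m["filters"];
  n.H = m["H"]; n.W = m["W"]; n.f1 = f[0]; n.f2 = f[1]; n.dense = m["dense"];
  n.H2 = n.H / 2; n.W2 = n.W / 2; n.H4 = n.H2 / 2; n.W4 = n.W2 / 2;
  n.flat = n.H4 * n.W4 * n.f2;
  n.Wc1 = as<mat>(m["Wc1"]); n.bc1 = as<arma::rowvec>(m["bc1"]);
  n.g1 = as<arma::rowvec>(m["g1"]); n.be1 = as<arma::rowvec>(m["be1"]);
  n.rm1 = as<arma::rowvec>(m["rm1"]); n.rv1 = as<arma::rowvec>(m["rv1"]);
  n.Wc2 = as<mat>(m["Wc2"]); n.bc2 = as<arma::rowvec>(m["bc2"]);
  n.g2 = as<arma::rowvec>(m["g2"]); n.be2 = as<arma::rowvec>(m["be2"]);
  n.rm2 = as<arma::rowvec>(m["rm2"]); n.rv2 = as<arma::rowvec>(m["rv2"]);
  n.Wd1 = as<mat>(m["Wd1"]); n.bd1 = as<arma::rowvec>(m["bd1"]);
  n.Wd2 = as<mat>(m["Wd2"]); n.bd2v = as<arma::rowvec>(m["bd2"]);
  n.nb1 = neighbour_table(n.H, n.W);
  n.nb2 = neighbour_table(n.H2, n.W2);
  return n;
}

}  // namespace

// [[Rcpp::export]]
List cnn_fit_cpp(NumericMatrix Xtr_, NumericVector ytr_, NumericMatrix Xval_,
                 NumericVector yval_, int H, int W, List cfg, int seed) {
  const mat Xtr = as<mat>(Xtr_), Xval = as<mat>(Xval_);
  const arma::vec ytr = as<arma::vec>(ytr_), yval = as<arma::vec>(yval_);
  const int f1 = cfg["filters1"], f2 = cfg["filters2"], dense = cfg["dense"];
  const int batch = cfg["batch_size"], max_epochs = cfg["max_epochs"];
  const int lr_patience = cfg["lr_patience"], es_patience = cfg["es_patience"];
  const double dropout = cfg["dropout"], lr0 = cfg["learning_rate"];
  const double lr_factor = cfg["lr_factor"], bn_mom = cfg["bn_momentum"];

  Rng rng((unsigned int)seed);
  Net n;
  net_init(n, H, W, f1, f2, dense, rng);
  const int N = Xtr.n_rows, HW = H * W, HW2 = n.H2 * n.W2, HW4 = n.H4 * n.W4;
  const double keep = 1.0 - dropout;

  std::vector<Adam> ad(12);
  int t_adam = 0;
  double lr = lr0;
  double best_val = R_PosInf;
  int lr_wait = 0, es_wait = 0, best_epoch = 0, epochs_run = 0;
  List best_weights = net_to_list(n);
  arma::rowvec brm1, brv1, brm2, brv2;
  std::vector<double> hist_train, hist_val;

  std::vector<arma::uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    rng.shuffle(order);
    double ep_loss = 0.0;
    int ep_count = 0;
    for (int start = 0; start < N; start += batch) {
      int B = std::min(batch, N - start);
      if (B < 2 && start > 0) break;  // drop a trailing singleton batch
      // assemble batch
      mat A0(B * HW, 1);
      arma::vec yb(B);
      for (int s = 0; s < B; ++s) {
        const arma::uword idx = order[start + s];
        yb(s) = ytr(idx);
        for (int pix = 0; pix < HW; ++pix) A0(s * HW + pix, 0) = Xtr(idx, pix);
      }
      // ---- forward ----
      mat Pt1 = build_patches(A0, n.nb1, B, HW);
      mat Z1 = Pt1 * n.Wc1;
      Z1.each_row() += n.bc1;
      BNCache c1;
      mat B1 = bn_fwd_train(Z1, n.g1, n.be1, n.rm1, n.rv1, bn_mom, c1);
      mat R1 = B1;
      R1.transform([](double v) { return v > 0.0 ? v : 0.0; });
      mat P1; umat arg1;
      pool_fwd(R1, B, H, W, P1, arg1);
      mat Pt2 = build_patches(P1, n.nb2, B, HW2);
      mat Z2 = Pt2 * n.Wc2;
      Z2.each_row() += n.bc2;
      BNCache c2;
      mat B2 = bn_fwd_train(Z2, n.g2, n.be2, n.rm2, n.rv2, bn_mom, c2);
      mat R2 = B2;
      R2.transform([](double v) { return v > 0.0 ? v : 0.0; });
      mat P2; umat arg2;
      pool_fwd(R2, B, n.H2, n.W2, P2, arg2);
      mat F(B, n.flat);
      for (int c = 0; c < f2; ++c)
        for (int pix = 0; pix < HW4; ++pix)
          for (int s = 0; s < B; ++s) F(s, c * HW4 + pix) = P2(s * HW4 + pix, c);
      mat D1 = F * n.Wd1;
      D1.each_row() += n.bd1;
      mat D1r = D1;
      D1r.transform([](double v) { return v > 0.0 ? v : 0.0; });
      mat drop_mask(B, dense, arma::fill::ones);
      if (dropout > 0.0) {
        for (arma::uword i = 0; i < drop_mask.n_elem; ++i)
          drop_mask(i) = (rng.unif() < keep) ? 1.0 / keep : 0.0;
      }
      mat D1d = D1r % drop_mask;
      mat Zo = D1d * n.Wd2;
      Zo.each_row() += n.bd2v;
      arma::vec prob = 1.0 / (1.0 + arma::exp(-Zo.col(0)));
      ep_loss += bce_loss(prob, yb) * B;
      ep_count += B;
      // ---- backward ----
      mat dZo((prob - yb) / (double)B);
      mat dWd2 = D1d.t() * dZo;
      arma::rowvec dbd2 = arma::sum(dZo, 0);
      mat dD1d = dZo * n.Wd2.t();
      mat dD1 = (dD1d % drop_mask) % arma::conv_to<mat>::from(D1 > 0.0);
      mat dWd1 = F.t() * dD1;
      arma::rowvec dbd1 = arma::sum(dD1, 0);
      mat dF = dD1 * n.Wd1.t();
      mat dP2(B * HW4, f2);
      for (int c = 0; c < f2; ++c)
        for (int pix = 0; pix < HW4; ++pix)
          for (int s = 0; s < B; ++s) dP2(s * HW4 + pix, c) = dF(s, c * HW4 + pix);
      mat dR2;
      pool_bwd(dP2, arg2, B * HW2, dR2);
      dR2 %= arma::conv_to<mat>::from(B2 > 0.0);
      arma::rowvec dg2, dbe2;
      mat dZ2 = bn_bwd(dR2, n.g2, c2, dg2, dbe2);
      mat dWc2 = Pt2.t() * dZ2;
      arma::rowvec dbc2 = arma::sum(dZ2, 0);
      mat dPt2 = dZ2 * n.Wc2.t();
      mat dP1(B * HW2, f1, arma::fill::zeros);
      scatter_patches(dPt2, n.nb2, B, HW2, dP1);
      mat dR1;
      pool_bwd(dP1, arg1, B * HW, dR1);
      dR1 %= arma::conv_to<mat>::from(B1 > 0.0);
      arma::rowvec dg1, dbe1;
      mat dZ1 = bn_bwd(dR1, n.g1, c1, dg1, dbe1);
      mat dWc1 = Pt1.t() * dZ1;
      arma::rowvec dbc1 = arma::sum(dZ1, 0);
      // ---- Adam updates ----
      ++t_adam;
      adam_step(n.Wc1, dWc1, ad[0], lr, t_adam);
      { mat g(dbc1); mat w(n.bc1); adam_step(w, g, ad[1], lr, t_adam); n.bc1 = w.row(0); }
      { mat g(dg1);  mat w(n.g1);  adam_step(w, g, ad[2], lr, t_adam); n.g1 = w.row(0); }
      { mat g(dbe1); mat w(n.be1); adam_step(w, g, ad[3], lr, t_adam); n.be1 = w.row(0); }
      adam_step(n.Wc2, dWc2, ad[4], lr, t_adam);
      { mat g(dbc2); mat w(n.bc2); adam_step(w, g, ad[5], lr, t_adam); n.bc2 = w.row(0); }
      { mat g(dg2);  mat w(n.g2);  adam_step(w, g, ad[6], lr, t_adam); n.g2 = w.row(0); }
      { mat g(dbe2); mat w(n.be2); adam_step(w, g, ad[7], lr, t_adam); n.be2 = w.row(0); }
      adam_step(n.Wd1, dWd1, ad[8], lr, t_adam);
      { mat g(dbd1); mat w(n.bd1); adam_step(w, g, ad[9], lr, t_adam); n.bd1 = w.row(0); }
      adam_step(n.Wd2, dWd2, ad[10], lr, t_adam);
      { mat g(dbd2); mat w(n.bd2v); adam_step(w, g, ad[11], lr, t_adam); n.bd2v = w.row(0); }
    }
    epochs_run = epoch + 1;
    hist_train.push_back(ep_loss / ep_count);
    const double vloss = bce_loss(net_predict(n, Xval), yval);
    hist_val.push_back(vloss);
    if (vloss < best_val - 1e-5) {
      best_val = vloss;
      best_epoch = epoch + 1;
      best_weights = net_to_list(n);
      lr_wait = 0;
      es_wait = 0;
    } else {
      ++lr_wait;
      ++es_wait;
      if (lr_wait >= lr_patience) {
        lr = std::max(lr * lr_factor, 1e-6);
        lr_wait = 0;
      }
      if (es_wait >= es_patience) break;
    }
  }

  best_weights["history"] = List::create(
      _["train_loss"] = wrap(hist_train), _["val_loss"] = wrap(hist_val),
      _["epochs_run"] = epochs_run, _["best_epoch"] = best_epoch,
      _["best_val_loss"] = best_val);
  return best_weights;
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(List model, NumericMatrix X_) {
  Net n = net_from_list(model);
  const mat X = as<mat>(X_);
  return wrap(net_predict(n, X));
}
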