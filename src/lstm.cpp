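// Stacked LSTM with a sigmoid feed-forward output, trained with MAE loss
// and Adam by full-batch BPTT over equal-horizon, prefix-masked sequences.
// Weights live in an R list so initialization (and therefore seeding) stays
// on the R side; gate rows are ordered [input; forget; candidate; output].
// The input-weight products are batched over all timesteps (one GEMM per
// layer per pass) because the per-day matrices are tiny.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  int L;                       // recurrent layers
  std::vector<mat> W, U;       // (4H x Fin), (4H x H)
  std::vector<vec> b;          // 4H
  vec v;                       // output weights (H_top)
  double c0;                   // output bias

  static Net from_list(const Rcpp::List& params) {
    Net net;
    net.L = Rcpp::as<int>(params["n_layers"]);
    Rcpp::List Wl = params["W"], Ul = params["U"], bl = params["b"];
    for (int l = 0; l < net.L; ++l) {
      net.W.push_back(Rcpp::as<mat>(Wl[l]));
      net.U.push_back(Rcpp::as<mat>(Ul[l]));
      net.b.push_back(Rcpp::as<vec>(bl[l]));
    }
    net.v = Rcpp::as<vec>(params["v"]);
    net.c0 = Rcpp::as<double>(params["c0"]);
    return net;
  }

  Rcpp::List to_list() const {
    Rcpp::List Wl(L), Ul(L), bl(L);
    for (int l = 0; l < L; ++l) { Wl[l] = W[l]; Ul[l] = U[l]; bl[l] = b[l]; }
    return Rcpp::List::create(Rcpp::Named("n_layers") = L,
                              Rcpp::Named("W") = Wl, Rcpp::Named("U") = Ul,
                              Rcpp::Named("b") = bl, Rcpp::Named("v") = v,
                              Rcpp::Named("c0") = c0);
  }
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  std::vector<cube> G4, C, Hs, TC;  // gates (4H x P x T), states (H x P x T)
  std::vector<mat> zerosH;
  mat yhat;                         // T x P

  void init(const Net& net, int P, int T) {
    G4.clear(); C.clear(); Hs.clear(); TC.clear(); zerosH.clear();
    for (int l = 0; l < net.L; ++l) {
      int H = net.U[l].n_cols;
      G4.emplace_back(4 * H, P, T);
      C.emplace_back(H, P, T);
      Hs.emplace_back(H, P, T);
      TC.emplace_back(H, P, T);
      zerosH.emplace_back(H, P, fill::zeros);
    }
    yhat.set_size(T, P);
  }
};

// forward over the whole batch; X is F x P x T, viewed as F x (P*T)
void forward(const Net& net, const cube& X, Cache& cc) {
  const int T = X.n_slices, P = X.n_cols;
  const mat Xf(const_cast<double*>(X.memptr()), X.n_rows, P * T, false, true);
  std::vector<mat> WX(net.L);
  WX[0] = net.W[0] * Xf;                       // 4H x (P*T)
  for (int t = 0; t < T; ++t) {
    for (int l = 0; l < net.L; ++l) {
      int H = net.U[l].n_cols;
      const mat& h_prev = (t == 0) ? cc.zerosH[l] : cc.Hs[l].slice(t - 1);
      const mat& c_prev = (t == 0) ? cc.zerosH[l] : cc.C[l].slice(t - 1);
      mat& a = cc.G4[l].slice(t);
      if (l == 0) {
        a = WX[0].cols(t * P, t * P + P - 1);
      } else {
        a = net.W[l] * cc.Hs[l - 1].slice(t);
      }
      a += net.U[l] * h_prev;
      a.each_col() += net.b[l];
      a.rows(0, 2 * H - 1) = sigm(a.rows(0, 2 * H - 1));          // i, f
      a.rows(2 * H, 3 * H - 1) = tanh(a.rows(2 * H, 3 * H - 1));  // g
      a.rows(3 * H, 4 * H - 1) = sigm(a.rows(3 * H, 4 * H - 1));  // o
      cc.C[l].slice(t) = a.rows(H, 2 * H - 1) % c_prev +
                         a.rows(0, H - 1) % a.rows(2 * H, 3 * H - 1);
      cc.TC[l].slice(t) = tanh(cc.C[l].slice(t));
      cc.Hs[l].slice(t) = a.rows(3 * H, 4 * H - 1) % cc.TC[l].slice(t);
    }
    cc.yhat.row(t) = sigm(net.v.t() * cc.Hs[net.L - 1].slice(t) + net.c0);
  }
}

struct Grads {
  std::vector<mat> W, U;
  std::vector<vec> b;
  vec v;
  double c0;
  explicit Grads(const Net& net) : c0(0.0) {
    for (int l = 0; l < net.L; ++l) {
      W.emplace_back(size(net.W[l]), fill::zeros);
      U.emplace_back(size(net.U[l]), fill::zeros);
      b.emplace_back(net.b[l].n_elem, fill::zeros);
    }
    v = vec(net.v.n_elem, fill::zeros);
  }
};

// backward pass for MAE loss; M is the T x P prefix mask, nobs = accu(M)
Grads backward(const Net& net, const cube& X, const mat& Y, const mat& M,
               const Cache& cc) {
  const int T = X.n_slices, P = X.n_cols, L = net.L;
  const double nobs = accu(M);
  Grads g(net);
  mat dY = sign(cc.yhat - Y) % M / nobs;           // d MAE / d yhat
  mat dpre = dY % cc.yhat % (1.0 - cc.yhat);       // through output sigmoid

  std::vector<cube> dA(L);                         // stored for batched GEMMs
  std::vector<mat> dh_next(L), dc_next(L);
  for (int l = 0; l < L; ++l) {
    int H = net.U[l].n_cols;
    dA[l].set_size(4 * H, P, T);
    dh_next[l] = mat(H, P, fill::zeros);
    dc_next[l] = mat(H, P, fill::zeros);
  }
  for (int t = T - 1; t >= 0; --t) {
    mat dh_from_above;   // W_{l+1}^T * da_{l+1} at this t
    for (int l = L - 1; l >= 0; --l) {
      int H = net.U[l].n_cols;
      mat dh = dh_next[l];
      if (l == L - 1) {
        dh += net.v * dpre.row(t);
        g.v += cc.Hs[l].slice(t) * dpre.row(t).t();
        g.c0 += accu(dpre.row(t));
      } else {
        dh += dh_from_above;
      }
      const mat& a = cc.G4[l].slice(t);
      auto i = a.rows(0, H - 1);
      auto f = a.rows(H, 2 * H - 1);
      auto gg = a.rows(2 * H, 3 * H - 1);
      auto o = a.rows(3 * H, 4 * H - 1);
      const mat& tc = cc.TC[l].slice(t);
      const mat& c_prev = (t == 0) ? cc.zerosH[l] : cc.C[l].slice(t - 1);
      mat dc = dh % o % (1.0 - tc % tc) + dc_next[l];
      mat& da = dA[l].slice(t);
      da.rows(0, H - 1) = (dc % gg) % i % (1.0 - i);
      da.rows(H, 2 * H - 1) = (dc % c_prev) % f % (1.0 - f);
      da.rows(2 * H, 3 * H - 1) = (dc % i) % (1.0 - gg % gg);
      da.rows(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
      if (t > 0) g.U[l] += da * cc.Hs[l].slice(t - 1).t();
      dh_next[l] = net.U[l].t() * da;
      dc_next[l] = dc % f;
      if (l > 0) dh_from_above = net.W[l].t() * da;
    }
  }
  // input-weight and bias grads in one GEMM per layer
  const mat Xf(const_cast<double*>(X.memptr()), X.n_rows, P * T, false, true);
  for (int l = 0; l < L; ++l) {
    const mat dAf(const_cast<double*>(dA[l].memptr()), dA[l].n_rows, P * T,
                  false, true);
    if (l == 0) {
      g.W[0] = dAf * Xf.t();
    } else {
      const mat Hf(const_cast<double*>(cc.Hs[l - 1].memptr()),
                   cc.Hs[l - 1].n_rows, P * T, false, true);
      g.W[l] = dAf * Hf.t();
    }
    g.b[l] = sum(dAf, 1);
  }
  return g;
}

struct Adam {
  double lr, b1, b2, eps;
  long t;
  std::vector<mat> mW, vW, mU, vU;
  std::vector<vec> mb, vb;
  vec mv, vv;
  double mc, vc;
  Adam(const Net& net, double lr_) : lr(lr_), b1(0.9), b2(0.999), eps(1e-8),
                                     t(0), mc(0), vc(0) {
    for (int l = 0; l < net.L; ++l) {
      mW.emplace_back(size(net.W[l]), fill::zeros);
      vW.emplace_back(size(net.W[l]), fill::zeros);
      mU.emplace_back(size(net.U[l]), fill::zeros);
      vU.emplace_back(size(net.U[l]), fill::zeros);
      mb.emplace_back(net.b[l].n_elem, fill::zeros);
      vb.emplace_back(net.b[l].n_elem, fill::zeros);
    }
    mv = vec(net.v.n_elem, fill::zeros);
    vv = vec(net.v.n_elem, fill::zeros);
  }
  template <class A> void upd(A& w, A& m, A& v2, const A& grad) {
    m = b1 * m + (1 - b1) * grad;
    v2 = b2 * v2 + (1 - b2) * (grad % grad);
    A mhat = m / (1 - std::pow(b1, (double)t));
    A vhat = v2 / (1 - std::pow(b2, (double)t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
  void step(Net& net, const Grads& g) {
    ++t;
    for (int l = 0; l < net.L; ++l) {
      upd(net.W[l], mW[l], vW[l], g.W[l]);
      upd(net.U[l], mU[l], vU[l], g.U[l]);
      upd(net.b[l], mb[l], vb[l], g.b[l]);
    }
    upd(net.v, mv, vv, g.v);
    double m1 = (mc = b1 * mc + (1 - b1) * g.c0);
    double v1 = (vc = b2 * vc + (1 - b2) * g.c0 * g.c0);
    net.c0 -= lr * (m1 / (1 - std::pow(b1, (double)t))) /
              (std::sqrt(v1 / (1 - std::pow(b2, (double)t))) + eps);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List params, arma::cube X, arma::mat Y,
                          arma::mat M, double lr, int max_epochs,
                          int patience) {
  Net net = Net::from_list(params);
  Adam adam(net, lr);
  const double nobs = accu(M);
  if (nobs <= 0) Rcpp::stop("mask selects no observations");
  std::vector<double> losses;
  double best = datum::inf;
  int best_epoch = -1, since_best = 0;
  Net best_net = net;
  Cache cc;
  cc.init(net, X.n_cols, X.n_slices);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    forward(net, X, cc);
    double loss = accu(abs(cc.yhat - Y) % M) / nobs;
    losses.push_back(loss);
    if (loss < best) {
      best = loss; best_epoch = epoch; best_net = net; since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    Grads g = backward(net, X, Y, M, cc);
    adam.step(net, g);
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = best_net.to_list(),
      Rcpp::Named("loss_history") = losses,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("best_loss") = best);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(Rcpp::List params, arma::mat X, int inject_col) {
  // X is F x T for one patient; inject_col is 0-based, -1 = no autoregression
  Net net = Net::from_list(params);
  const int T = X.n_cols;
  std::vector<vec> h(net.L), c(net.L);
  for (int l = 0; l < net.L; ++l) {
    h[l] = vec(net.U[l].n_cols, fill::zeros);
    c[l] = vec(net.U[l].n_cols, fill::zeros);
  }
  vec yhat(T);
  for (int t = 0; t < T; ++t) {
    vec input = X.col(t);
    if (inject_col >= 0 && t > 0) input(inject_col) = yhat(t - 1);
    for (int l = 0; l < net.L; ++l) {
      int H = net.U[l].n_cols;
      vec a = net.W[l] * input + net.U[l] * h[l] + net.b[l];
      vec i = 1.0 / (1.0 + exp(-a.rows(0, H - 1)));
      vec f = 1.0 / (1.0 + exp(-a.rows(H, 2 * H - 1)));
      vec g = tanh(a.rows(2 * H, 3 * H - 1));
      vec o = 1.0 / (1.0 + exp(-a.rows(3 * H, 4 * H - 1)));
      c[l] = f % c[l] + i % g;
      h[l] = o % tanh(c[l]);
      input = h[l];
    }
    yhat(t) = 1.0 / (1.0 + std::exp(-(dot(net.v, h[net.L - 1]) + net.c0)));
  }
  return yhat;
}

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(Rcpp::List params, arma::cube X) {
  Net net = Net::from_list(params);
  Cache cc;
  cc.init(net, X.n_cols, X.n_slices);
  forward(net, X, cc);
  return cc.yhat;  // T x P
}
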