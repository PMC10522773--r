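// Compact depthwise-separable convolutional latency regressor.
// Block 1: temporal conv (1xK, same padding, no bias) -> batch-norm ->
//          depthwise spatial conv (Cx1, depth multiplier 2, max-norm 1,
//          no bias) -> batch-norm -> ELU -> average-pool 1x4 -> dropout.
// Block 2: separable conv (depthwise 1xK2 + pointwise, no bias) ->
//          batch-norm -> ELU -> average-pool 1x8 -> dropout.
// Head:    flatten -> dense 1, linear.
// Trained with Adam on the mean-squared-error of the latency target.
#include "nn_common.h"
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct EEGNet {
  int C = 20, T = 101, K = 64, F1 = 8, D = 2, K2 = 16, P1 = 4, P2 = 8;
  int F2, T2, T3, FL;
  arma::mat W1;        // K x F1 temporal kernels
  arma::mat W2;        // C x F2 spatial kernels (cols 2f, 2f+1 from map f)
  arma::mat Wd;        // K2 x F2 depthwise temporal kernels
  arma::mat Wp;        // F2 x F2 pointwise mixing
  arma::mat Wf, bf;    // FL x 1 dense, 1 x 1 bias
  BatchNorm bn1, bn2, bn3;
  double drop_p = 0.5;

  void derive_dims() {
    F2 = F1 * D; T2 = T / P1; T3 = T2 / P2; FL = F2 * T3;
  }

  void init(int C_, int T_, int seed) {
    C = C_; T = T_;
    derive_dims();
    std::mt19937 rng((unsigned)seed);
    W1 = glorot(K, F1, K, (double)K * F1, rng);
    W2 = glorot(C, F2, C, (double)C * D, rng);
    Wd = glorot(K2, F2, K2, (double)K2, rng);
    Wp = glorot(F2, F2, F2, F2, rng);
    Wf = glorot(FL, 1, FL, 1, rng);
    bf.zeros(1, 1);
    bn1.init(F1); bn2.init(F2); bn3.init(F2);
  }

  std::vector<arma::mat*> params() {
    return {&W1, &W2, &Wd, &Wp, &Wf, &bf,
            &bn1.gamma, &bn1.beta, &bn2.gamma, &bn2.beta,
            &bn3.gamma, &bn3.beta};
  }

  // ---- caches from the training forward pass -------------------------
  arma::mat P_im2col;            // (N*C*T) x K
  arma::mat A1;                  // post-bn1 (N*C*T) x F1
  std::vector<arma::mat> Bf;     // per input map: (N*T) x C gathers
  arma::mat E2;                  // elu output (N*T) x F2
  arma::mat M2, P2d;             // dropout mask + dropped pool1 output
  std::vector<arma::mat> Dg;     // per feature: (N*T2) x K2 im2col
  arma::mat S1;                  // depthwise temporal output
  arma::mat E3, M3, P3d;         // block2 elu out, dropout, dropped pool2
  arma::mat Fl;                  // N x FL flatten
  std::vector<arma::uvec> gidx;  // channel gathers (depend on N)
  int cachedN = -1;

  void build_gather(int N) {
    if (cachedN == N) return;
    gidx.assign(C, arma::uvec((arma::uword)N * T));
    for (int c = 0; c < C; ++c) {
      arma::uvec& gc = gidx[c];
      for (int n = 0; n < N; ++n)
        for (int t = 0; t < T; ++t)
          gc[(arma::uword)n * T + t] =
            ((arma::uword)n * C + c) * (arma::uword)T + t;
    }
    cachedN = N;
  }

  // X: (n_trials, C, T) cube; idx: batch rows
  arma::vec forward(const arma::cube& X, const arma::uvec& idx,
                    bool training, std::mt19937* rng) {
    const int N = (int)idx.n_elem;
    build_gather(N);
    const int padb = (K - 1) / 2;
    const arma::uword M = (arma::uword)N * C;
    arma::mat S((arma::uword)T + K - 1, M, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < T; ++t)
          S((arma::uword)padb + t, (arma::uword)n * C + c) = X(idx[n], c, t);

    P_im2col.set_size((arma::uword)T * M, K);
    for (int k = 0; k < K; ++k)
      P_im2col.col(k) = arma::vectorise(S.rows(k, k + T - 1));

    arma::mat A1raw = P_im2col * W1;          // (N*C*T) x F1
    A1 = bn1.forward(A1raw, training);

    arma::mat Z((arma::uword)N * T, F2);
    Bf.assign(F1, arma::mat());
    for (int f = 0; f < F1; ++f) {
      arma::mat B((arma::uword)N * T, C);
      arma::vec a1f = A1.col(f);
      for (int c = 0; c < C; ++c) B.col(c) = a1f.elem(gidx[c]);
      Bf[f] = B;
      Z.cols(2 * f, 2 * f + 1) = B * W2.cols(2 * f, 2 * f + 1);
    }

    arma::mat Zb = bn2.forward(Z, training);
    E2 = elu(Zb);

    arma::mat P2m((arma::uword)N * T2, F2, arma::fill::zeros);
    for (int q = 0; q < P1; ++q)
      for (int n = 0; n < N; ++n)
        P2m.rows((arma::uword)n * T2, (arma::uword)(n + 1) * T2 - 1) +=
          E2.rows(arma::regspace<arma::uvec>((arma::uword)n * T + q,
                                             P1, (arma::uword)n * T + q +
                                             (arma::uword)P1 * (T2 - 1)));
    P2m /= (double)P1;

    if (training) {
      M2 = dropout_mask(P2m.n_rows, P2m.n_cols, drop_p, *rng);
      P2d = P2m % M2;
    } else P2d = P2m;

    const int padb2 = (K2 - 1) / 2;
    S1.set_size((arma::uword)N * T2, F2);
    Dg.assign(F2, arma::mat());
    for (int j = 0; j < F2; ++j) {
      arma::mat Sp((arma::uword)T2 + K2 - 1, N, arma::fill::zeros);
      Sp.rows(padb2, padb2 + T2 - 1) = arma::reshape(P2d.col(j), T2, N);
      arma::mat Dj((arma::uword)N * T2, K2);
      for (int k = 0; k < K2; ++k)
        Dj.col(k) = arma::vectorise(Sp.rows(k, k + T2 - 1));
      Dg[j] = Dj;
      S1.col(j) = Dj * Wd.col(j);
    }
    arma::mat S2 = S1 * Wp;
    arma::mat S2b = bn3.forward(S2, training);
    E3 = elu(S2b);

    arma::mat P3m((arma::uword)N * T3, F2, arma::fill::zeros);
    for (int q = 0; q < P2; ++q)
      for (int n = 0; n < N; ++n)
        for (int tp = 0; tp < T3; ++tp)
          P3m.row((arma::uword)n * T3 + tp) +=
            E3.row((arma::uword)n * T2 + P2 * tp + q);
    P3m /= (double)P2;

    if (training) {
      M3 = dropout_mask(P3m.n_rows, P3m.n_cols, drop_p, *rng);
      P3d = P3m % M3;
    } else P3d = P3m;

    Fl.set_size(N, FL);
    for (int j = 0; j < F2; ++j)
      for (int tp = 0; tp < T3; ++tp)
        for (int n = 0; n < N; ++n)
          Fl(n, j * T3 + tp) = P3d((arma::uword)n * T3 + tp, j);

    return Fl * Wf + bf(0, 0);
  }

  // gradients, aligned with params()
  struct Grads {
    arma::mat W1, W2, Wd, Wp, Wf, bf, g1, b1, g2, b2, g3, b3;
    std::vector<arma::mat*> ptrs() {
      return {&W1, &W2, &Wd, &Wp, &Wf, &bf, &g1, &b1, &g2, &b2, &g3, &b3};
    }
  };

  void backward(const arma::vec& dy, Grads& g) {
    const int N = (int)dy.n_elem;
    g.Wf = Fl.t() * dy;
    g.bf = arma::mat(1, 1, arma::fill::value(arma::accu(dy)));
    arma::mat dFl = dy * Wf.t();              // N x FL

    arma::mat dP3d((arma::uword)N * T3, F2, arma::fill::zeros);
    for (int j = 0; j < F2; ++j)
      for (int tp = 0; tp < T3; ++tp)
        for (int n = 0; n < N; ++n)
          dP3d((arma::uword)n * T3 + tp, j) = dFl(n, j * T3 + tp);
    dP3d %= M3;

    arma::mat dE3(arma::size(E3), arma::fill::zeros);
    for (int q = 0; q < P2; ++q)
      for (int n = 0; n < N; ++n)
        for (int tp = 0; tp < T3; ++tp)
          dE3.row((arma::uword)n * T2 + P2 * tp + q) +=
            dP3d.row((arma::uword)n * T3 + tp) / (double)P2;

    arma::mat dS2b = elu_backward(dE3, E3);
    arma::mat dS2 = bn3.backward(dS2b, g.g3, g.b3);
    g.Wp = S1.t() * dS2;
    arma::mat dS1 = dS2 * Wp.t();

    const int padb2 = (K2 - 1) / 2;
    g.Wd.zeros(K2, F2);
    arma::mat dP2d((arma::uword)N * T2, F2, arma::fill::zeros);
    for (int j = 0; j < F2; ++j) {
      g.Wd.col(j) = Dg[j].t() * dS1.col(j);
      arma::mat dSp((arma::uword)T2 + K2 - 1, N, arma::fill::zeros);
      arma::mat dcol = arma::reshape(dS1.col(j), T2, N);
      for (int k = 0; k < K2; ++k)
        dSp.rows(k, k + T2 - 1) += dcol * Wd(k, j);
      dP2d.col(j) = arma::vectorise(dSp.rows(padb2, padb2 + T2 - 1));
    }
    dP2d %= M2;

    arma::mat dE2(arma::size(E2), arma::fill::zeros);
    for (int q = 0; q < P1; ++q)
      for (int n = 0; n < N; ++n)
        dE2.rows(arma::regspace<arma::uvec>((arma::uword)n * T + q, P1,
                 (arma::uword)n * T + q + (arma::uword)P1 * (T2 - 1))) +=
          dP2d.rows((arma::uword)n * T2, (arma::uword)(n + 1) * T2 - 1) /
          (double)P1;

    arma::mat dZb = elu_backward(dE2, E2);
    arma::mat dZ = bn2.backward(dZb, g.g2, g.b2);

    g.W2.zeros(C, F2);
    arma::mat dA1(arma::size(A1), arma::fill::zeros);
    for (int f = 0; f < F1; ++f) {
      g.W2.cols(2 * f, 2 * f + 1) = Bf[f].t() * dZ.cols(2 * f, 2 * f + 1);
      arma::mat dB = dZ.cols(2 * f, 2 * f + 1) *
                     W2.cols(2 * f, 2 * f + 1).t();
      arma::vec da1f(dA1.n_rows, arma::fill::zeros);
      for (int c = 0; c < C; ++c) da1f.elem(gidx[c]) = dB.col(c);
      dA1.col(f) = da1f;
    }

    arma::mat dA1raw = bn1.backward(dA1, g.g1, g.b1);
    g.W1 = P_im2col.t() * dA1raw;
  }

  void constrain() {
    // max-norm 1 on each depthwise spatial filter, as in the source model
    for (int j = 0; j < F2; ++j) {
      double nr = arma::norm(W2.col(j), 2);
      if (nr > 1.0) W2.col(j) /= nr;
    }
  }

  Rcpp::List to_list() const {
    return Rcpp::List::create(
      Rcpp::Named("type") = "eegnet",
      Rcpp::Named("dims") = Rcpp::IntegerVector::create(C, T, K, F1, D, K2),
      Rcpp::Named("W1") = W1, Rcpp::Named("W2") = W2,
      Rcpp::Named("Wd") = Wd, Rcpp::Named("Wp") = Wp,
      Rcpp::Named("Wf") = Wf, Rcpp::Named("bf") = bf,
      Rcpp::Named("bn1") = bn1.to_list(), Rcpp::Named("bn2") = bn2.to_list(),
      Rcpp::Named("bn3") = bn3.to_list());
  }
  void from_list(const Rcpp::List& l) {
    Rcpp::IntegerVector d = l["dims"];
    C = d[0]; T = d[1]; K = d[2]; F1 = d[3]; D = d[4]; K2 = d[5];
    derive_dims();
    W1 = Rcpp::as<arma::mat>(l["W1"]); W2 = Rcpp::as<arma::mat>(l["W2"]);
    Wd = Rcpp::as<arma::mat>(l["Wd"]); Wp = Rcpp::as<arma::mat>(l["Wp"]);
    Wf = Rcpp::as<arma::mat>(l["Wf"]); bf = Rcpp::as<arma::mat>(l["bf"]);
    bn1.from_list(l["bn1"]); bn2.from_list(l["bn2"]); bn3.from_list(l["bn3"]);
  }
};

double mse(const arma::vec& a, const arma::vec& b) {
  arma::vec d = a - b;
  return arma::dot(d, d) / d.n_elem;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List eegnet_init_cpp(int n_channels, int n_samples, int seed) {
  EEGNet net;
  net.init(n_channels, n_samples, seed);
  return net.to_list();
}

// [[Rcpp::export]]
Rcpp::DataFrame eegnet_param_counts_cpp(const Rcpp::List& w) {
  EEGNet net; net.from_list(w);
  // batch-norm counts include the moving mean/variance (4 per feature),
  // matching how layer summaries conventionally report them
  std::vector<std::string> layer = {
    "conv_temporal", "batchnorm_1", "conv_depthwise", "batchnorm_2",
    "conv_separable", "batchnorm_3", "flatten", "dense"};
  Rcpp::IntegerVector n = {
    (int)net.W1.n_elem, 4 * net.F1, (int)net.W2.n_elem, 4 * net.F2,
    (int)(net.Wd.n_elem + net.Wp.n_elem), 4 * net.F2, 0,
    (int)(net.Wf.n_elem + 1)};
  Rcpp::IntegerVector out = {0, 0, 0, 0, 0, 0, net.FL, 1};
  return Rcpp::DataFrame::create(Rcpp::Named("layer") = layer,
                                 Rcpp::Named("params") = n,
                                 Rcpp::Named("units") = out);
}

// [[Rcpp::export]]
Rcpp::List eegnet_train_cpp(const Rcpp::List& w, const arma::cube& X,
                            const arma::vec& y, const arma::cube& Xval,
                            const arma::vec& yval, int max_epochs,
                            int batch_size, double lr, int patience,
                            int seed, double lr_decay, int lr_steps) {
  EEGNet net; net.from_list(w);
  if ((int)X.n_cols != net.C || (int)X.n_slices != net.T)
    Rcpp::stop("input shape mismatch: expected %d x %d, got %d x %d",
               net.C, net.T, (int)X.n_cols, (int)X.n_slices);
  AdamState adam; adam.lr = lr;
  auto params = net.params();
  adam.init(params);
  std::mt19937 rng((unsigned)seed);

  const int N = (int)X.n_rows;
  arma::uvec order = arma::regspace<arma::uvec>(0, N - 1);
  arma::uvec all_val = arma::regspace<arma::uvec>(0, Xval.n_rows - 1);

  std::vector<double> tr_hist, val_hist;
  double best_val = arma::datum::inf;
  Rcpp::List best_weights = net.to_list();
  int best_epoch = 0, wait = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // stepped learning-rate schedule: the rate is multiplied by lr_decay
    // at each of lr_steps evenly spaced milestones across the run
    int stage = (int)(((long)epoch * (lr_steps + 1)) / max_epochs);
    adam.lr = lr * std::pow(lr_decay, (double)stage);
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0; int nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      int stop = std::min(start + batch_size, N);
      arma::uvec idx = order.subvec(start, stop - 1);
      arma::vec yb = y.elem(idx);
      arma::vec pred = net.forward(X, idx, true, &rng);
      tr_loss += mse(pred, yb); ++nb;
      arma::vec dy = 2.0 * (pred - yb) / (double)yb.n_elem;
      EEGNet::Grads g;
      net.backward(dy, g);
      auto gp = g.ptrs();
      adam.step(params, gp);
      net.constrain();
    }
    tr_hist.push_back(tr_loss / nb);
    arma::vec pv = net.forward(Xval, all_val, false, nullptr);
    double vl = mse(pv, yval);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-12) {
      best_val = vl; best_epoch = epoch; wait = 0;
      best_weights = net.to_list();
    } else if (++wait >= patience) break;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = best_weights,
                            Rcpp::Named("train_loss") = tr_hist,
                            Rcpp::Named("val_loss") = val_hist,
                            Rcpp::Named("best_epoch") = best_epoch + 1,
                            Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::vec eegnet_predict_cpp(const Rcpp::List& w, const arma::cube& X) {
  EEGNet net; net.from_list(w);
  if ((int)X.n_cols != net.C || (int)X.n_slices != net.T)
    Rcpp::stop("input shape mismatch: expected %d x %d, got %d x %d",
               net.C, net.T, (int)X.n_cols, (int)X.n_slices);
  arma::uvec all = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  return net.forward(X, all, false, nullptr);
}
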