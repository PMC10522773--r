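// Convolutional LSTM latency regressor on a 5x5 electrode grid.
// Layer 1: ConvLSTM, 6 filters 2x2 (valid on input, same-padded recurrent
//          conv on the hidden state), tanh cell activation, logistic gates,
//          dropout 0.2 / recurrent dropout 0.1 -> batch-norm (last spatial
//          axis). Layer 2: same ConvLSTM spec on the 6x4x4 sequence ->
//          batch-norm. Head: per-timestep max over filters and cells ->
//          flatten (T) -> dense 1, linear. Trained with Adam on MSE.
//
// States are (N*P x C) matrices: row n*P + p for cell p = row*W + col of an
// H x W grid, one column per channel/filter.
#include "nn_common.h"
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// 2x2 conv patches from a grid state. pad = false: valid (Ho=H-1);
// pad = true: right/bottom zero padding, output H x W (recurrent conv).
arma::mat make_patches(const arma::mat& state, int N, int H, int W, int C,
                       bool pad) {
  const int Ho = pad ? H : H - 1, Wo = pad ? W : W - 1;
  const int P = Ho * Wo;
  arma::mat out((arma::uword)N * P, 4 * C, arma::fill::zeros);
  for (int dr = 0; dr < 2; ++dr)
    for (int dc = 0; dc < 2; ++dc)
      for (int ch = 0; ch < C; ++ch) {
        const int col = (dr * 2 + dc) * C + ch;
        for (int r = 0; r < Ho; ++r)
          for (int c = 0; c < Wo; ++c) {
            const int sr = r + dr, sc = c + dc;
            if (sr >= H || sc >= W) continue;
            const int p = r * Wo + c, ps = sr * W + sc;
            for (int n = 0; n < N; ++n)
              out((arma::uword)n * P + p, col) =
                state((arma::uword)n * (H * W) + ps, ch);
          }
      }
  return out;
}

// adjoint of make_patches: accumulate patch grads back onto the state
arma::mat scatter_patches(const arma::mat& dpatch, int N, int H, int W,
                          int C, bool pad) {
  const int Ho = pad ? H : H - 1, Wo = pad ? W : W - 1;
  const int P = Ho * Wo;
  arma::mat dstate((arma::uword)N * H * W, C, arma::fill::zeros);
  for (int dr = 0; dr < 2; ++dr)
    for (int dc = 0; dc < 2; ++dc)
      for (int ch = 0; ch < C; ++ch) {
        const int col = (dr * 2 + dc) * C + ch;
        for (int r = 0; r < Ho; ++r)
          for (int c = 0; c < Wo; ++c) {
            const int sr = r + dr, sc = c + dc;
            if (sr >= H || sc >= W) continue;
            const int p = r * Wo + c, ps = sr * W + sc;
            for (int n = 0; n < N; ++n)
              dstate((arma::uword)n * (H * W) + ps, ch) +=
                dpatch((arma::uword)n * P + p, col);
          }
      }
  return dstate;
}

struct ConvLSTMLayer {
  int Cin, F, Hin, Win, Ho, Wo, P;
  arma::mat Wx, Wh, b;  // (4*Cin x 4F), (4F x 4F), (1 x 4F)
  double drop_in = 0.2, drop_rec = 0.1;

  void init(int Cin_, int F_, int Hin_, int Win_, std::mt19937& rng) {
    Cin = Cin_; F = F_; Hin = Hin_; Win = Win_;
    Ho = Hin - 1; Wo = Win - 1; P = Ho * Wo;
    Wx = glorot(4 * Cin, 4 * F, 4.0 * Cin, 4.0 * F, rng);
    Wh = glorot(4 * F, 4 * F, 4.0 * F, 4.0 * F, rng);
    b.zeros(1, 4 * F);
    b.cols(F, 2 * F - 1).ones();  // unit forget-gate bias
  }
  int n_params() const { return (int)(Wx.n_elem + Wh.n_elem + b.n_elem); }

  // caches
  std::vector<arma::mat> h_seq, c_seq, gi, gf, gc, go;
  arma::mat Mx, Mh;  // dropout masks (shared across timesteps)

  // in_seq: T states (N*Hin*Win x Cin). Returns nothing; h_seq holds output.
  void forward(const std::vector<arma::mat>& in_seq, int N, bool training,
               std::mt19937* rng) {
    const int T = (int)in_seq.size();
    h_seq.assign(T, arma::mat()); c_seq.assign(T, arma::mat());
    gi.assign(T, arma::mat()); gf.assign(T, arma::mat());
    gc.assign(T, arma::mat()); go.assign(T, arma::mat());
    if (training) {
      Mx = dropout_mask((arma::uword)N * Hin * Win, Cin, drop_in, *rng);
      Mh = dropout_mask((arma::uword)N * P, F, drop_rec, *rng);
    } else {
      Mx.ones((arma::uword)N * Hin * Win, Cin);
      Mh.ones((arma::uword)N * P, F);
    }
    arma::mat h((arma::uword)N * P, F, arma::fill::zeros);
    arma::mat c((arma::uword)N * P, F, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      arma::mat Pm = make_patches(in_seq[t] % Mx, N, Hin, Win, Cin, false);
      arma::mat Pr = make_patches(h % Mh, N, Ho, Wo, F, true);
      arma::mat G = Pm * Wx + Pr * Wh;
      G.each_row() += b.row(0);
      gi[t] = sigm(G.cols(0, F - 1));
      gf[t] = sigm(G.cols(F, 2 * F - 1));
      gc[t] = arma::tanh(G.cols(2 * F, 3 * F - 1));
      go[t] = sigm(G.cols(3 * F, 4 * F - 1));
      c = gf[t] % c + gi[t] % gc[t];
      h = go[t] % arma::tanh(c);
      c_seq[t] = c; h_seq[t] = h;
    }
  }

  // dH_ext: external gradient on h_seq. Returns gradient on in_seq;
  // fills dWx, dWh, db.
  std::vector<arma::mat> backward(const std::vector<arma::mat>& in_seq,
                                  const std::vector<arma::mat>& dH_ext,
                                  int N, arma::mat& dWx, arma::mat& dWh,
                                  arma::mat& db) {
    const int T = (int)in_seq.size();
    dWx.zeros(arma::size(Wx)); dWh.zeros(arma::size(Wh));
    db.zeros(arma::size(b));
    std::vector<arma::mat> dIn(T);
    arma::mat dh_next((arma::uword)N * P, F, arma::fill::zeros);
    arma::mat dc_next((arma::uword)N * P, F, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat dh = dH_ext[t] + dh_next;
      arma::mat th = arma::tanh(c_seq[t]);
      arma::mat dgo = dh % th;
      arma::mat dc = dc_next + dh % go[t] % (1.0 - th % th);
      arma::mat c_prev = t > 0 ? c_seq[t - 1]
        : arma::mat((arma::uword)N * P, F, arma::fill::zeros);
      arma::mat dgi = dc % gc[t];
      arma::mat dgc = dc % gi[t];
      arma::mat dgf = dc % c_prev;
      dc_next = dc % gf[t];
      arma::mat dG((arma::uword)N * P, 4 * F);
      dG.cols(0, F - 1) = dgi % gi[t] % (1.0 - gi[t]);
      dG.cols(F, 2 * F - 1) = dgf % gf[t] % (1.0 - gf[t]);
      dG.cols(2 * F, 3 * F - 1) = dgc % (1.0 - gc[t] % gc[t]);
      dG.cols(3 * F, 4 * F - 1) = dgo % go[t] % (1.0 - go[t]);

      arma::mat Pm = make_patches(in_seq[t] % Mx, N, Hin, Win, Cin, false);
      arma::mat h_prev = t > 0 ? h_seq[t - 1]
        : arma::mat((arma::uword)N * P, F, arma::fill::zeros);
      arma::mat Pr = make_patches(h_prev % Mh, N, Ho, Wo, F, true);

      dWx += Pm.t() * dG;
      dWh += Pr.t() * dG;
      db += arma::sum(dG, 0);
      dIn[t] = scatter_patches(dG * Wx.t(), N, Hin, Win, Cin, false) % Mx;
      dh_next = scatter_patches(dG * Wh.t(), N, Ho, Wo, F, true) % Mh;
    }
    return dIn;
  }

  Rcpp::List to_list() const {
    return Rcpp::List::create(Rcpp::Named("Wx") = Wx, Rcpp::Named("Wh") = Wh,
                              Rcpp::Named("b") = b);
  }
  void from_list(const Rcpp::List& l, int Cin_, int F_, int Hin_, int Win_) {
    Cin = Cin_; F = F_; Hin = Hin_; Win = Win_;
    Ho = Hin - 1; Wo = Win - 1; P = Ho * Wo;
    Wx = Rcpp::as<arma::mat>(l["Wx"]); Wh = Rcpp::as<arma::mat>(l["Wh"]);
    b = Rcpp::as<arma::mat>(l["b"]);
  }
};

// reshuffle a sequence of (N*P x F) states into a row-observation matrix
// with the last spatial axis (grid column) as the feature, for batch-norm
arma::mat seq_to_bn(const std::vector<arma::mat>& seq, int N, int Ho,
                    int Wo, int F) {
  const int T = (int)seq.size(), P = Ho * Wo;
  arma::mat out((arma::uword)T * N * F * Ho, Wo);
  for (int t = 0; t < T; ++t)
    for (int f = 0; f < F; ++f)
      for (int r = 0; r < Ho; ++r)
        for (int c = 0; c < Wo; ++c)
          for (int n = 0; n < N; ++n)
            out(((arma::uword)t * N + n) * F * Ho + (arma::uword)f * Ho + r,
                c) = seq[t]((arma::uword)n * P + r * Wo + c, f);
  return out;
}

std::vector<arma::mat> bn_to_seq(const arma::mat& bnm, int T, int N, int Ho,
                                 int Wo, int F) {
  const int P = Ho * Wo;
  std::vector<arma::mat> seq(T);
  for (int t = 0; t < T; ++t) {
    seq[t].set_size((arma::uword)N * P, F);
    for (int f = 0; f < F; ++f)
      for (int r = 0; r < Ho; ++r)
        for (int c = 0; c < Wo; ++c)
          for (int n = 0; n < N; ++n)
            seq[t]((arma::uword)n * P + r * Wo + c, f) =
              bnm(((arma::uword)t * N + n) * F * Ho + (arma::uword)f * Ho + r,
                  c);
  }
  return seq;
}

struct ConvLSTMNet {
  int H = 5, W = 5, T = 101, F = 6;
  ConvLSTMLayer l1, l2;
  BatchNorm bn1, bn2;
  arma::mat wd, bd;  // (T x 1), (1 x 1)

  void init(int T_, int seed) {
    T = T_;
    std::mt19937 rng((unsigned)seed);
    l1.init(1, F, H, W, rng);
    l2.init(F, F, l1.Ho, l1.Wo, rng);
    bn1.init(l1.Wo);
    bn2.init(l2.Wo);
    wd = glorot(T, 1, T, 1, rng);
    bd.zeros(1, 1);
  }
  std::vector<arma::mat*> params() {
    return {&l1.Wx, &l1.Wh, &l1.b, &l2.Wx, &l2.Wh, &l2.b,
            &bn1.gamma, &bn1.beta, &bn2.gamma, &bn2.beta, &wd, &bd};
  }

  // caches
  std::vector<arma::mat> in_seq, bn1out, bn2out;
  arma::umat amax_p, amax_f;  // N x T argmax of the pooling step
  arma::mat V;                // N x T pooled values

  // x: flat array [N, T, 5, 5] (R array layout), idx: batch rows
  arma::vec forward(const double* x, int Nall, const arma::uvec& idx,
                    bool training, std::mt19937* rng) {
    const int N = (int)idx.n_elem;
    in_seq.assign(T, arma::mat());
    for (int t = 0; t < T; ++t) {
      arma::mat st((arma::uword)N * H * W, 1);
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c)
          for (int n = 0; n < N; ++n)
            st((arma::uword)n * H * W + r * W + c, 0) =
              x[idx[n] + (arma::uword)Nall * t +
                (arma::uword)Nall * T * r + (arma::uword)Nall * T * H * c];
      in_seq[t] = st;
    }
    l1.forward(in_seq, N, training, rng);
    arma::mat b1 = bn1.forward(seq_to_bn(l1.h_seq, N, l1.Ho, l1.Wo, F),
                               training);
    bn1out = bn_to_seq(b1, T, N, l1.Ho, l1.Wo, F);
    l2.forward(bn1out, N, training, rng);
    arma::mat b2 = bn2.forward(seq_to_bn(l2.h_seq, N, l2.Ho, l2.Wo, F),
                               training);
    bn2out = bn_to_seq(b2, T, N, l2.Ho, l2.Wo, F);

    const int P2 = l2.P;
    V.set_size(N, T); amax_p.set_size(N, T); amax_f.set_size(N, T);
    for (int t = 0; t < T; ++t)
      for (int n = 0; n < N; ++n) {
        double best = -arma::datum::inf; int bp = 0, bff = 0;
        for (int f = 0; f < F; ++f)
          for (int p = 0; p < P2; ++p) {
            double v = bn2out[t]((arma::uword)n * P2 + p, f);
            if (v > best) { best = v; bp = p; bff = f; }
          }
        V(n, t) = best; amax_p(n, t) = bp; amax_f(n, t) = bff;
      }
    return V * wd + bd(0, 0);
  }

  struct Grads {
    arma::mat Wx1, Wh1, b1, Wx2, Wh2, b2, g1, be1, g2, be2, wd, bd;
    std::vector<arma::mat*> ptrs() {
      return {&Wx1, &Wh1, &b1, &Wx2, &Wh2, &b2,
              &g1, &be1, &g2, &be2, &wd, &bd};
    }
  };

  void backward(const arma::vec& dy, Grads& g) {
    const int N = (int)dy.n_elem, P2 = l2.P;
    g.wd = V.t() * dy;
    g.bd = arma::mat(1, 1, arma::fill::value(arma::accu(dy)));
    arma::mat dV = dy * wd.t();  // N x T

    std::vector<arma::mat> dbn2(T);
    for (int t = 0; t < T; ++t) {
      dbn2[t].zeros((arma::uword)N * P2, F);
      for (int n = 0; n < N; ++n)
        dbn2[t]((arma::uword)n * P2 + amax_p(n, t), amax_f(n, t)) = dV(n, t);
    }
    arma::mat dh2big = bn2.backward(seq_to_bn(dbn2, N, l2.Ho, l2.Wo, F),
                                    g.g2, g.be2);
    std::vector<arma::mat> dh2 = bn_to_seq(dh2big, T, N, l2.Ho, l2.Wo, F);
    std::vector<arma::mat> dbn1out =
      l2.backward(bn1out, dh2, N, g.Wx2, g.Wh2, g.b2);
    arma::mat dh1big = bn1.backward(seq_to_bn(dbn1out, N, l1.Ho, l1.Wo, F),
                                    g.g1, g.be1);
    std::vector<arma::mat> dh1 = bn_to_seq(dh1big, T, N, l1.Ho, l1.Wo, F);
    l1.backward(in_seq, dh1, N, g.Wx1, g.Wh1, g.b1);
  }

  Rcpp::List to_list() const {
    return Rcpp::List::create(
      Rcpp::Named("type") = "convlstm",
      Rcpp::Named("dims") = Rcpp::IntegerVector::create(H, W, T, F),
      Rcpp::Named("l1") = l1.to_list(), Rcpp::Named("l2") = l2.to_list(),
      Rcpp::Named("bn1") = bn1.to_list(), Rcpp::Named("bn2") = bn2.to_list(),
      Rcpp::Named("wd") = wd, Rcpp::Named("bd") = bd);
  }
  void from_list(const Rcpp::List& l) {
    Rcpp::IntegerVector d = l["dims"];
    H = d[0]; W = d[1]; T = d[2]; F = d[3];
    l1.from_list(l["l1"], 1, F, H, W);
    l2.from_list(l["l2"], F, F, H - 1, W - 1);
    bn1.from_list(l["bn1"]); bn2.from_list(l["bn2"]);
    wd = Rcpp::as<arma::mat>(l["wd"]); bd = Rcpp::as<arma::mat>(l["bd"]);
  }
};

double mse_v(const arma::vec& a, const arma::vec& b) {
  arma::vec d = a - b;
  return arma::dot(d, d) / d.n_elem;
}

arma::uvec check_grid(const Rcpp::NumericVector& x, int& N, int& T) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 4 || dim[2] != 5 || dim[3] != 5)
    Rcpp::stop("input must be a [trials, time, 5, 5] grid array");
  N = dim[0]; T = dim[1];
  return arma::regspace<arma::uvec>(0, N - 1);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List convlstm_init_cpp(int n_samples, int seed) {
  ConvLSTMNet net;
  net.init(n_samples, seed);
  return net.to_list();
}

// [[Rcpp::export]]
Rcpp::DataFrame convlstm_param_counts_cpp(const Rcpp::List& w) {
  ConvLSTMNet net; net.from_list(w);
  std::vector<std::string> layer = {"convlstm_1", "batchnorm_1",
                                    "convlstm_2", "batchnorm_2",
                                    "maxpool", "flatten", "dense"};
  Rcpp::IntegerVector n = {net.l1.n_params(), 4 * net.l1.Wo,
                           net.l2.n_params(), 4 * net.l2.Wo, 0, 0,
                           (int)(net.wd.n_elem + 1)};
  Rcpp::IntegerVector units = {0, 0, 0, 0, 0, net.T, 1};
  return Rcpp::DataFrame::create(Rcpp::Named("layer") = layer,
                                 Rcpp::Named("params") = n,
                                 Rcpp::Named("units") = units);
}

// [[Rcpp::export]]
Rcpp::List convlstm_train_cpp(const Rcpp::List& w,
                              const Rcpp::NumericVector& X,
                              const arma::vec& y,
                              const Rcpp::NumericVector& Xval,
                              const arma::vec& yval, int max_epochs,
                              int batch_size, double lr, int patience,
                              int seed, double lr_decay, int lr_steps) {
  ConvLSTMNet net; net.from_list(w);
  int N, T, Nv, Tv;
  check_grid(X, N, T);
  arma::uvec all_val = check_grid(Xval, Nv, Tv);
  if (T != net.T || Tv != net.T) Rcpp::stop("time length mismatch");
  AdamState adam; adam.lr = lr;
  auto params = net.params();
  adam.init(params);
  std::mt19937 rng((unsigned)seed);
  arma::uvec order = arma::regspace<arma::uvec>(0, N - 1);

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
      arma::vec pred = net.forward(X.begin(), N, idx, true, &rng);
      tr_loss += mse_v(pred, yb); ++nb;
      arma::vec dy = 2.0 * (pred - yb) / (double)yb.n_elem;
      ConvLSTMNet::Grads g;
      net.backward(dy, g);
      auto gp = g.ptrs();
      adam.step(params, gp);
    }
    tr_hist.push_back(tr_loss / nb);
    arma::vec pv = net.forward(Xval.begin(), Nv, all_val, false, nullptr);
    double vl = mse_v(pv, yval);
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
arma::vec convlstm_predict_cpp(const Rcpp::List& w,
                               const Rcpp::NumericVector& X) {
  ConvLSTMNet net; net.from_list(w);
  int N, T;
  arma::uvec all = check_grid(X, N, T);
  if (T != net.T) Rcpp::stop("time length mismatch");
  return net.forward(X.begin(), N, all, false, nullptr);
}
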