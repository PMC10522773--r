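// Shared helpers for the natively implemented neural-network regressors:
// Adam optimiser state, batch normalisation forward/backward, ELU, and a
// seeded Mersenne-Twister RNG for initialisation and dropout.
#ifndef ERTRIAL_NN_COMMON_H
#define ERTRIAL_NN_COMMON_H

#include <RcppArmadillo.h>
#include <random>
#include <vector>

struct AdamState {
  std::vector<arma::mat> m, v;
  double lr = 0.001, b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;

  void init(const std::vector<arma::mat*>& params) {
    m.clear(); v.clear();
    for (auto* p : params) {
      m.emplace_back(arma::size(*p), arma::fill::zeros);
      v.emplace_back(arma::size(*p), arma::fill::zeros);
    }
  }
  // one Adam step over all parameter blocks (grads aligned with params)
  void step(const std::vector<arma::mat*>& params,
            const std::vector<arma::mat*>& grads) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0 - b2) * arma::square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// Batch normalisation over the rows of a column-feature matrix. Parameters
// are 1 x n matrices so the optimiser can treat them like any other block;
// moving mean/variance are used at inference (Keras-style).
struct BatchNorm {
  arma::mat gamma, beta, rmean, rvar;
  // eps as in the reference implementation; the moving-average momentum is
  // lowered from 0.99 to 0.9 because training runs here involve few
  // updates per epoch and the inference statistics must track them
  double momentum = 0.9, eps = 1e-3;
  // caches from the last training forward
  arma::rowvec mu, var;
  arma::mat xhat;

  void init(arma::uword n) {
    gamma.ones(1, n); beta.zeros(1, n); rmean.zeros(1, n); rvar.ones(1, n);
  }
  arma::mat forward(const arma::mat& x, bool training) {
    arma::rowvec g = gamma.row(0), b = beta.row(0);
    if (training) {
      mu = arma::mean(x, 0);
      var = arma::var(x, 1, 0);  // biased, as in batch statistics
      rmean.row(0) = momentum * rmean.row(0) + (1.0 - momentum) * mu;
      rvar.row(0)  = momentum * rvar.row(0)  + (1.0 - momentum) * var;
      xhat = (x.each_row() - mu).each_row() / arma::sqrt(var + eps);
      return (xhat.each_row() % g).each_row() + b;
    }
    arma::rowvec rm = rmean.row(0), rv = rvar.row(0);
    arma::mat xh = (x.each_row() - rm).each_row() / arma::sqrt(rv + eps);
    return (xh.each_row() % g).each_row() + b;
  }
  // returns dx; fills dgamma/dbeta (1 x n)
  arma::mat backward(const arma::mat& dy, arma::mat& dgamma,
                     arma::mat& dbeta) const {
    const double n = (double)dy.n_rows;
    dgamma = arma::sum(dy % xhat, 0);
    dbeta = arma::sum(dy, 0);
    arma::rowvec inv_sd = 1.0 / arma::sqrt(var + eps);
    arma::mat dxh = dy.each_row() % gamma.row(0);
    arma::rowvec m1 = arma::sum(dxh, 0) / n;
    arma::rowvec m2 = arma::sum(dxh % xhat, 0) / n;
    arma::mat dx = dxh;
    dx.each_row() -= m1;
    dx -= xhat.each_row() % m2;
    dx.each_row() %= inv_sd;
    return dx;
  }
  Rcpp::List to_list() const {
    return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                              Rcpp::Named("beta") = beta,
                              Rcpp::Named("rmean") = rmean,
                              Rcpp::Named("rvar") = rvar);
  }
  void from_list(const Rcpp::List& l) {
    gamma = Rcpp::as<arma::mat>(l["gamma"]);
    beta = Rcpp::as<arma::mat>(l["beta"]);
    rmean = Rcpp::as<arma::mat>(l["rmean"]);
    rvar = Rcpp::as<arma::mat>(l["rvar"]);
  }
};

inline arma::mat elu(const arma::mat& x) {
  arma::mat y = x;
  y.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  return y;
}
// dx from dy and the elu *output*
inline arma::mat elu_backward(const arma::mat& dy, const arma::mat& out) {
  arma::mat g = out;
  g.transform([](double v) { return v > 0 ? 1.0 : v + 1.0; });
  return dy % g;
}

inline arma::mat glorot(arma::uword nr, arma::uword nc, double fan_in,
                        double fan_out, std::mt19937& rng) {
  const double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> U(-lim, lim);
  arma::mat w(nr, nc);
  for (arma::uword j = 0; j < nc; ++j)
    for (arma::uword i = 0; i < nr; ++i) w(i, j) = U(rng);
  return w;
}

// inverted dropout mask: entries are 0 or 1/(1-p)
inline arma::mat dropout_mask(arma::uword nr, arma::uword nc, double p,
                              std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  arma::mat mmat(nr, nc);
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < nc; ++j)
    for (arma::uword i = 0; i < nr; ++i)
      mmat(i, j) = U(rng) < p ? 0.0 : scale;
  return mmat;
}

#endif
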