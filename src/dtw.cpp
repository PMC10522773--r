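// Dependent multichannel dynamic time warping: local cost between template
// column i and segment column j is the squared Euclidean distance summed
// over channels; steps {(1,0),(0,1),(1,1)}; full alignment of the template
// onto the segment.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List dtw_align_cpp(const arma::mat& tpl, const arma::mat& seg) {
  const arma::uword n = tpl.n_cols, m = seg.n_cols;
  if (tpl.n_rows != seg.n_rows)
    Rcpp::stop("template and segment must have the same channel count");
  if (m < 1 || n < 1) Rcpp::stop("empty inputs");

  arma::mat local(n, m);
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec d = tpl.col(i) - seg.col(j);
      local(i, j) = arma::dot(d, d);
    }

  const double INF = std::numeric_limits<double>::infinity();
  arma::mat D(n, m);
  D(0, 0) = local(0, 0);
  for (arma::uword i = 1; i < n; ++i) D(i, 0) = D(i - 1, 0) + local(i, 0);
  for (arma::uword j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + local(0, j);
  for (arma::uword i = 1; i < n; ++i)
    for (arma::uword j = 1; j < m; ++j) {
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = local(i, j) + best;
    }

  // backtrack from (n-1, m-1); ties prefer the diagonal, then (i-1,j)
  std::vector<int> pi, pj;
  arma::uword i = n - 1, j = m - 1;
  pi.push_back((int)i + 1); pj.push_back((int)j + 1);
  while (i > 0 || j > 0) {
    double up = i > 0 ? D(i - 1, j) : INF;
    double left = j > 0 ? D(i, j - 1) : INF;
    double diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : INF;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left) { --i; }
    else { --j; }
    pi.push_back((int)i + 1); pj.push_back((int)j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return Rcpp::List::create(Rcpp::Named("cost") = D,
                            Rcpp::Named("path_i") = pi,
                            Rcpp::Named("path_j") = pj);
}
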