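// Newton-Raphson fit of a multinomial logistic regression (reference
// category 0).  This is the hot kernel of the likelihood-ratio mixed
// conditional-independence test: constraint-based searches perform tens of
// thousands of these fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double nll_probs(const mat& X, const uvec& y0, const mat& W, mat& P) {
  const uword n = X.n_rows;
  mat eta = join_rows(zeros<vec>(n), X * W);
  vec mx = max(eta, 1);
  eta.each_col() -= mx;
  mat ee = exp(eta);
  vec rs = sum(ee, 1);
  P = ee.each_col() / rs;
  double nll = accu(log(rs));
  for (uword i = 0; i < n; ++i) nll -= eta(i, y0[i]);
  return nll;
}

// [[Rcpp::export]]
Rcpp::List cpp_multinom_fit(const arma::mat& X, const arma::ivec& yidx,
                            int k, int max_iter, double tol) {
  const uword n = X.n_rows, d = X.n_cols;
  const int km1 = k - 1;
  uvec y0 = conv_to<uvec>::from(yidx - 1);  // 0-based class index
  mat Y(n, km1, fill::zeros);
  for (uword i = 0; i < n; ++i)
    if (y0[i] > 0) Y(i, y0[i] - 1) = 1.0;
  mat W(d, km1, fill::zeros), P;
  double cur = nll_probs(X, y0, W, P);
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    mat G = X.t() * (P.cols(1, km1) - Y);
    mat H(km1 * d, km1 * d, fill::zeros);
    for (int c1 = 0; c1 < km1; ++c1) {
      for (int c2 = c1; c2 < km1; ++c2) {
        vec w = (c1 == c2) ? vec(P.col(c1 + 1) % (1.0 - P.col(c1 + 1)))
                           : vec(-P.col(c1 + 1) % P.col(c2 + 1));
        mat blk = X.t() * (X.each_col() % w);
        H.submat(c1 * d, c2 * d, (c1 + 1) * d - 1, (c2 + 1) * d - 1) = blk;
        if (c1 != c2)
          H.submat(c2 * d, c1 * d, (c2 + 1) * d - 1, (c1 + 1) * d - 1) = blk.t();
      }
    }
    H.diag() += 1e-10;
    vec step;
    bool ok = solve(step, H, vectorise(G), solve_opts::no_approx);
    if (!ok) break;
    mat S = reshape(step, d, km1);
    double t = 1.0, cand = datum::inf;
    mat Pc;
    while (t >= 1e-6) {
      cand = nll_probs(X, y0, W - t * S, Pc);
      if (std::isfinite(cand) && cand <= cur + 1e-12) break;
      t /= 2.0;
    }
    if (t < 1e-6) break;
    W -= t * S;
    P = Pc;
    if (std::fabs(cur - cand) < tol * (std::fabs(cur) + 1.0)) {
      cur = cand;
      converged = true;
      break;
    }
    cur = cand;
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = -cur,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("npar") = (double)(d * km1));
}
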