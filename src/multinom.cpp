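// Newton-Raphson fitter for a ridge-penalized multinomial logistic model.
// Used per SNP by the association scans, so it is compiled: a chromosome-arm
// scan fits this model (and its intercept-only null) once per SNP.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Penalized log-likelihood. eta: n x (G-1) linear predictors (baseline class
// G-1 has eta = 0). y: integer classes 0..G-1. Penalty: lambda/2 * sum of
// squared coefficients in rows of B flagged by `pen` (slopes, not intercepts).
static double pen_loglik(const mat& X, const ivec& y, const mat& B,
                         const vec& pen, double lambda, double* raw_ll) {
  const uword n = X.n_rows;
  const uword Gm1 = B.n_cols;
  mat eta = X * B;                       // n x (G-1)
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double m = 0.0;                      // max over {0, eta_i.}
    for (uword g = 0; g < Gm1; ++g) m = std::max(m, eta(i, g));
    double se = std::exp(-m);            // baseline term exp(0 - m)
    for (uword g = 0; g < Gm1; ++g) se += std::exp(eta(i, g) - m);
    double lse = m + std::log(se);
    double num = (static_cast<uword>(y(i)) < Gm1) ? eta(i, y(i)) : 0.0;
    ll += num - lse;
  }
  if (raw_ll) *raw_ll = ll;
  double penterm = 0.0;
  for (uword j = 0; j < B.n_rows; ++j)
    if (pen(j) > 0.5) penterm += dot(B.row(j), B.row(j));
  return ll - 0.5 * lambda * penterm;
}

// Class probabilities for non-baseline classes, n x (G-1).
static mat probs(const mat& X, const mat& B) {
  mat eta = X * B;
  const uword n = eta.n_rows, Gm1 = eta.n_cols;
  mat P(n, Gm1);
  for (uword i = 0; i < n; ++i) {
    double m = 0.0;
    for (uword g = 0; g < Gm1; ++g) m = std::max(m, eta(i, g));
    double se = std::exp(-m);
    for (uword g = 0; g < Gm1; ++g) se += std::exp(eta(i, g) - m);
    for (uword g = 0; g < Gm1; ++g) P(i, g) = std::exp(eta(i, g) - m) / se;
  }
  return P;
}

//' @noRd
// [[Rcpp::export(name = ".multinom_ridge_cpp")]]
Rcpp::List multinom_ridge_cpp(const arma::mat& X, const arma::ivec& y,
                              int n_classes, double lambda,
                              const arma::vec& penalize,
                              const arma::mat& init,
                              int max_iter = 200, double tol = 1e-10) {
  const uword p = X.n_cols;
  const uword Gm1 = static_cast<uword>(n_classes - 1);
  mat B = init;                          // p x (G-1)
  if (B.n_rows != p || B.n_cols != Gm1) B = zeros<mat>(p, Gm1);

  double raw = 0.0;
  double ll = pen_loglik(X, y, B, penalize, lambda, &raw);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    mat P = probs(X, B);                 // n x (G-1)
    // gradient (stacked by class): g_g = X'(1[y==g] - P_g) - lambda*pen.*b_g
    vec grad(p * Gm1);
    for (uword g = 0; g < Gm1; ++g) {
      vec r(X.n_rows);
      for (uword i = 0; i < X.n_rows; ++i)
        r(i) = (static_cast<uword>(y(i)) == g ? 1.0 : 0.0) - P(i, g);
      vec gg = X.t() * r - lambda * (penalize % B.col(g));
      grad.subvec(g * p, (g + 1) * p - 1) = gg;
    }
    if (norm(grad, "inf") < 1e-9) { converged = true; break; }
    // Hessian blocks H_{gh} = -X' diag(P_g (delta - P_h)) X - delta*lambda*diag(pen)
    mat H(p * Gm1, p * Gm1);
    for (uword g = 0; g < Gm1; ++g) {
      for (uword h = g; h < Gm1; ++h) {
        vec w(X.n_rows);
        for (uword i = 0; i < X.n_rows; ++i)
          w(i) = P(i, g) * ((g == h ? 1.0 : 0.0) - P(i, h));
        mat blk = -(X.t() * (X.each_col() % w));
        if (g == h) blk.diag() -= lambda * penalize;
        H.submat(g * p, h * p, (g + 1) * p - 1, (h + 1) * p - 1) = blk;
        if (g != h)
          H.submat(h * p, g * p, (h + 1) * p - 1, (g + 1) * p - 1) = blk.t();
      }
    }
    vec step;
    bool ok = solve(step, H, -grad, solve_opts::likely_sympd);
    if (!ok) { step = -grad; }           // gradient ascent fallback
    // step halving on the penalized objective
    double alpha = 1.0;
    mat Bnew;
    double llnew = -datum::inf;
    for (int half = 0; half < 30; ++half) {
      Bnew = B + alpha * reshape(step, p, Gm1);
      llnew = pen_loglik(X, y, Bnew, penalize, lambda, &raw);
      if (std::isfinite(llnew) && llnew >= ll - 1e-12) break;
      alpha *= 0.5;
    }
    double delta = llnew - ll;
    B = Bnew;
    ll = llnew;
    if (std::abs(delta) < tol) { converged = true; break; }
  }
  double raw_ll = 0.0;
  double pll = pen_loglik(X, y, B, penalize, lambda, &raw_ll);
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = B,
    Rcpp::Named("penalized_loglik") = pll,
    Rcpp::Named("loglik") = raw_ll,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
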