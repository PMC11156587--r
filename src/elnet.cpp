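// Coordinate-descent elastic net with covariance updates.
// Objective: 1/(2n) ||y - X b||^2 + lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
// X is expected column-standardized (so diag(X'X)/n = 1) and y centred;
// the caller back-transforms coefficients. Warm starts along a decreasing
// lambda path; the per-sweep objective trace is returned for the final
// lambda so callers can verify monotone descent.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static double objective(const vec& beta, const mat& G, const vec& xty,
                        double yty_n, double lambda, double alpha) {
  double quad = 0.5 * (yty_n - 2.0 * dot(beta, xty) + dot(beta, G * beta));
  return quad + lambda * (alpha * accu(abs(beta)) +
                          0.5 * (1.0 - alpha) * dot(beta, beta));
}

// [[Rcpp::export(name = ".elnet_path_cpp")]]
Rcpp::List elnet_path_cpp(const arma::mat& X, const arma::vec& y,
                          double alpha, const arma::vec& lambdas,
                          int max_sweeps, double tol) {
  const int n = X.n_rows, p = X.n_cols, L = lambdas.n_elem;
  mat G = (X.t() * X) / n;
  vec xty = (X.t() * y) / n;
  double yty_n = dot(y, y) / n;

  mat betas(p, L, fill::zeros);
  vec beta(p, fill::zeros);
  std::vector<double> last_trace;

  for (int l = 0; l < L; ++l) {
    double lambda = lambdas(l);
    double l1 = lambda * alpha, l2 = lambda * (1.0 - alpha);
    std::vector<double> trace;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdel = 0.0;
      for (int k = 0; k < p; ++k) {
        double denom = G(k, k) + l2;
        if (denom < 1e-12) {        // predictor constant in this fold
          if (beta(k) != 0.0) { maxdel = std::max(maxdel, std::abs(beta(k))); beta(k) = 0.0; }
          continue;
        }
        double gk = xty(k) - dot(G.col(k), beta) + G(k, k) * beta(k);
        double bnew = soft(gk, l1) / denom;
        double del = bnew - beta(k);
        if (std::abs(del) > maxdel) maxdel = std::abs(del);
        beta(k) = bnew;
      }
      trace.push_back(objective(beta, G, xty, yty_n, lambda, alpha));
      if (maxdel < tol) break;
    }
    betas.col(l) = beta;
    if (l == L - 1) last_trace = trace;
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = betas,
    Rcpp::Named("objective_trace") = last_trace);
}
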