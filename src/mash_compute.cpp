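// Inner loops for the multivariate adaptive-shrinkage engine.
// Effects model: bhat_j ~ N(b_j, S_j), b_j ~ sum_m pi_m N(0, U_m),
// S_j = diag(se_j) V diag(se_j). Likelihoods and posterior moments are
// computed per (feature, component) via Cholesky in log space so that
// z-scores up to |z| ~ 40 do not underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// log N(x; 0, Sigma) with a tiny ridge retry on Cholesky failure
static double dmvnorm_log(const vec& x, mat Sigma, int R) {
  mat L;
  if (!chol(L, Sigma, "lower")) {
    Sigma.diag() += 1e-10;
    if (!chol(L, Sigma, "lower")) return -datum::inf;
  }
  vec u = solve(trimatl(L), x);
  double logdet = 2.0 * accu(log(L.diag()));
  return -0.5 * (R * LOG2PI + logdet + dot(u, u));
}

// [[Rcpp::export(name = ".mash_loglik_cpp")]]
arma::mat mash_loglik_cpp(const arma::mat& Bhat, const arma::mat& Shat,
                          const arma::mat& V, const arma::cube& U) {
  const int J = Bhat.n_rows, R = Bhat.n_cols, M = U.n_slices;
  mat out(J, M);
  for (int j = 0; j < J; ++j) {
    vec se = Shat.row(j).t();
    mat Sj = V % (se * se.t());
    vec b = Bhat.row(j).t();
    for (int m = 0; m < M; ++m)
      out(j, m) = dmvnorm_log(b, Sj + U.slice(m), R);
  }
  return out;
}

// Posterior summaries under fixed mixture weights.
// Returns mixture posterior mean, sd, P(b_r < 0) and P(b_r = 0) per
// feature x condition; a component with zero posterior variance and zero
// mean in condition r contributes to the point mass at zero.
// [[Rcpp::export(name = ".mash_posterior_cpp")]]
Rcpp::List mash_posterior_cpp(const arma::mat& Bhat, const arma::mat& Shat,
                              const arma::mat& V, const arma::cube& U,
                              const arma::vec& pi_w, const arma::mat& loglik) {
  const int J = Bhat.n_rows, R = Bhat.n_cols, M = U.n_slices;
  mat post_mean(J, R, fill::zeros), post_m2(J, R, fill::zeros);
  mat neg_prob(J, R, fill::zeros), zero_prob(J, R, fill::zeros);
  vec logpi = log(pi_w + 1e-300);

  for (int j = 0; j < J; ++j) {
    vec lw = loglik.row(j).t() + logpi;
    double mx = lw.max();
    vec gamma = exp(lw - mx);
    gamma /= accu(gamma);

    vec se = Shat.row(j).t();
    mat Sj = V % (se * se.t());
    vec b = Bhat.row(j).t();

    for (int m = 0; m < M; ++m) {
      double g = gamma(m);
      if (g < 1e-15) continue;
      const mat& Um = U.slice(m);
      if (norm(Um, "fro") == 0.0) {        // null: point mass at 0
        zero_prob.row(j) += g;
        continue;
      }
      mat Sigma = Sj + Um;
      mat A;
      if (!solve(A, Sigma, Um)) {          // A = Sigma^{-1} U
        Sigma.diag() += 1e-10;
        A = solve(Sigma, Um);
      }
      vec mu = A.t() * b;                  // U Sigma^{-1} b
      mat pc = Um - Um * A;                // U - U Sigma^{-1} U
      for (int r = 0; r < R; ++r) {
        double m1 = mu(r), v = std::max(pc(r, r), 0.0);
        post_mean(j, r) += g * m1;
        post_m2(j, r) += g * (v + m1 * m1);
        if (v > 0) {
          neg_prob(j, r) += g * R::pnorm(0.0, m1, std::sqrt(v), 1, 0);
        } else if (m1 < 0) {
          neg_prob(j, r) += g;
        } else if (m1 == 0) {
          zero_prob(j, r) += g;
        }
      }
    }
  }
  mat post_var = post_m2 - post_mean % post_mean;
  post_var.elem(find(post_var < 0)).zeros();
  return Rcpp::List::create(
    Rcpp::Named("post_mean") = post_mean,
    Rcpp::Named("post_sd") = sqrt(post_var),
    Rcpp::Named("neg_prob") = neg_prob,
    Rcpp::Named("zero_prob") = zero_prob);
}
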