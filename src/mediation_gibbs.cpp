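// Blocked Gibbs sampler for the multilevel (1-1-1) mediation model:
//   M_ij = dM_j + a_j X_ij + eM,  eM ~ N(0, sig2m)
//   Y_ij = dY_j + c'_j X_ij + b_j M_ij + eY,  eY ~ N(0, sig2y)
//   u_j = (dM_j, a_j, dY_j, c'_j, b_j) ~ MVN(mu, Sigma)
// Priors: mu ~ N(0, tau0^-1 I) (diffuse), Sigma ~ inverse-Wishart(nu0,
// Lambda0), sig2 ~ inverse-gamma(a0, b0). All conditionals are conjugate.
// Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// draw from Wishart(df, S) via Bartlett decomposition, S = scale matrix
static mat rwishart(double df, const mat& S) {
  int p = S.n_rows;
  mat L = chol(S, "lower");
  mat A(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(rng = true)]]
Rcpp::List mediation_gibbs_chain(
    const arma::ivec& subject,   // 0-based subject index per observation
    const arma::vec& x,
    const arma::vec& m,
    const arma::vec& y,
    int n_subjects,
    int iter,
    int warmup,
    const arma::vec& lambda0_diag, // IW scale matrix diagonal (5)
    double nu0,
    double tau0,                 // prior precision of mu
    double a0, double b0,        // IG prior on residual variances
    const arma::vec& mu_init) {
  const int p = 5;
  const int N = x.n_elem;
  const int J = n_subjects;

  // per-subject sufficient statistics
  std::vector<mat> xtx_m(J, mat(2, 2, fill::zeros));
  std::vector<vec> xty_m(J, vec(2, fill::zeros));
  std::vector<mat> xtx_y(J, mat(3, 3, fill::zeros));
  std::vector<vec> xty_y(J, vec(3, fill::zeros));
  for (int i = 0; i < N; ++i) {
    int j = subject(i);
    vec dm = {1.0, x(i)};
    vec dy = {1.0, x(i), m(i)};
    xtx_m[j] += dm * dm.t();
    xty_m[j] += dm * m(i);
    xtx_y[j] += dy * dy.t();
    xty_y[j] += dy * y(i);
  }

  mat lambda0 = diagmat(lambda0_diag);
  mat u(J, p, fill::zeros);
  vec mu = mu_init;
  for (int j = 0; j < J; ++j) u.row(j) = mu.t();
  mat sigma = diagmat(lambda0_diag);
  double sig2m = 1.0, sig2y = 1.0;
  {
    // residual-scale init from data variance
    sig2m = var(m) + 1e-6;
    sig2y = var(y) + 1e-6;
  }

  int keep = iter - warmup;
  mat draws(keep, 10); // mu(5), sigma_ab, sig2m, sig2y, ab, c
  mat u_sum(J, p, fill::zeros);
  vec abj_sum(J, fill::zeros);

  for (int it = 0; it < iter; ++it) {
    mat sigma_inv = inv_sympd(sigma);

    // subject coefficient vectors
    for (int j = 0; j < J; ++j) {
      mat A = sigma_inv;
      A.submat(0, 0, 1, 1) += xtx_m[j] / sig2m;
      A.submat(2, 2, 4, 4) += xtx_y[j] / sig2y;
      vec rhs = sigma_inv * mu;
      rhs.subvec(0, 1) += xty_m[j] / sig2m;
      rhs.subvec(2, 4) += xty_y[j] / sig2y;
      mat L = chol(A, "lower");
      vec mean = solve(trimatu(L.t()), solve(trimatl(L), rhs));
      vec z = rnorm_vec(p);
      u.row(j) = (mean + solve(trimatu(L.t()), z)).t();
    }

    // residual variances
    double rss_m = 0.0, rss_y = 0.0;
    for (int i = 0; i < N; ++i) {
      int j = subject(i);
      double rm = m(i) - u(j, 0) - u(j, 1) * x(i);
      double ry = y(i) - u(j, 2) - u(j, 3) * x(i) - u(j, 4) * m(i);
      rss_m += rm * rm;
      rss_y += ry * ry;
    }
    sig2m = 1.0 / R::rgamma(a0 + N / 2.0, 1.0 / (b0 + rss_m / 2.0));
    sig2y = 1.0 / R::rgamma(a0 + N / 2.0, 1.0 / (b0 + rss_y / 2.0));

    // group means
    {
      mat P = J * sigma_inv + tau0 * eye(p, p);
      vec rhs = sigma_inv * sum(u, 0).t();
      mat L = chol(P, "lower");
      vec mean = solve(trimatu(L.t()), solve(trimatl(L), rhs));
      vec z = rnorm_vec(p);
      mu = mean + solve(trimatu(L.t()), z);
    }

    // random-effect covariance
    {
      mat S = lambda0;
      for (int j = 0; j < J; ++j) {
        vec d = u.row(j).t() - mu;
        S += d * d.t();
      }
      mat W = rwishart(nu0 + J, inv_sympd(S));
      sigma = inv_sympd(W);
    }

    if (it >= warmup) {
      int k = it - warmup;
      double sab = sigma(1, 4);
      double ab = mu(1) * mu(4) + sab;
      draws(k, 0) = mu(0);
      draws(k, 1) = mu(1);
      draws(k, 2) = mu(2);
      draws(k, 3) = mu(3);
      draws(k, 4) = mu(4);
      draws(k, 5) = sab;
      draws(k, 6) = sig2m;
      draws(k, 7) = sig2y;
      draws(k, 8) = ab;
      draws(k, 9) = mu(3) + ab; // total effect c = c' + ab
      u_sum += u;
      for (int j = 0; j < J; ++j) abj_sum(j) += u(j, 1) * u(j, 4);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("u_mean") = u_sum / keep,
    Rcpp::Named("abj_mean") = abj_sum / keep);
}
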