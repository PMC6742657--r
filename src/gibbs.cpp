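// Confidence-weighted Bayesian elastic-net Gibbs sampler for the
// peptide-level protein model. The elastic net uses a Gaussian
// scale-mixture representation: conditionally on latent tau_j and the
// ridge penalty lambda2, each penalized coefficient has prior
//   beta_j | tau_j, lambda2 ~ N(0, 1 / (1/tau_j + lambda2)),
// with gamma hyperpriors on lambda1^2 and lambda2. The prior is
// deliberately NOT scaled by sigma2: with many genuinely large
// coefficients (peptide ionization effects span log2 units) a
// sigma2-scaled penalty feeds the penalty quadratic form back into the
// sigma2 conditional at the same order as the residual sum of squares,
// and the chain contracts to a degenerate mode where everything is
// shrunk and sigma2 absorbs the signal. Unscaled, sigma2 | rest is a
// plain inverse gamma on the weighted residuals and no such feedback
// exists. Unpenalized columns (the intercept) get a flat prior.
//
// Observation weights are recomputed every iteration from the current
// standardized residuals and the per-observation identification
// confidence qc = 1 - 10^(-score/10):
//   w_i = qc_i + (1 - qc_i) / (1 + (r_i / c)^2),
// so a high-confidence observation keeps weight ~1 however large its
// residual, while low-confidence outliers are down-weighted.
//
// All randomness goes through R's RNG so set.seed() in R gives
// bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Inverse-Gaussian(mu, lambda) sampler (Michael, Schucany & Haas).
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_enet")]]
List gibbs_enet(const arma::vec& y,
                const arma::mat& X,
                const arma::vec& qc,
                const arma::uvec& penalize,
                double weight_c,
                int iterations,
                int burn_in,
                double a1, double r1,   // gamma hyperprior on lambda1^2
                double a2, double r2,   // gamma hyperprior on lambda2
                double lambda1_sq_fixed,  // <= 0 -> sample
                double lambda2_fixed,     // <= 0 -> sample
                bool use_weights) {
  const int n = X.n_rows, p = X.n_cols;
  const int keep = iterations - burn_in;
  if (keep <= 0) stop("iterations must exceed burn_in");

  arma::uvec pen_idx = arma::find(penalize == 1);
  const int ppen = pen_idx.n_elem;

  // init from a ridge-stabilised solve
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  arma::vec beta = arma::solve(XtX + 1e-6 * arma::eye(p, p), Xty);
  arma::vec resid = y - X * beta;
  double sigma2 = arma::dot(resid, resid) / std::max(n - p, 1);
  if (sigma2 < 1e-12) sigma2 = 1e-12;

  double lambda1_sq = (lambda1_sq_fixed > 0.0) ? lambda1_sq_fixed : 0.5;
  double lambda2    = (lambda2_fixed    > 0.0) ? lambda2_fixed    : 0.5;
  // latent scales start at the ridge solution's own magnitudes
  arma::vec tau(ppen, arma::fill::ones);
  for (int j = 0; j < ppen; ++j) {
    double bj = beta(pen_idx(j));
    tau(j) = std::max(bj * bj, 1e-4);
  }
  arma::vec w(n, arma::fill::ones);

  arma::mat beta_draws(keep, p);
  arma::vec sigma2_draws(keep);
  arma::vec lambda1_sq_draws(keep), lambda2_draws(keep);
  arma::vec w_mean(n, arma::fill::zeros), w_min(n);
  w_min.fill(1.0);

  RNGScope scope;

  for (int it = 0; it < iterations; ++it) {
    // observation weights from current standardized residuals
    resid = y - X * beta;
    if (use_weights) {
      double sig = std::sqrt(sigma2);
      for (int i = 0; i < n; ++i) {
        double r = resid(i) / sig;
        double rc = r / weight_c;
        w(i) = qc(i) + (1.0 - qc(i)) / (1.0 + rc * rc);
      }
    }

    // prior precision for penalized columns (unscaled by sigma2)
    arma::vec dpen(p, arma::fill::zeros);
    for (int j = 0; j < ppen; ++j)
      dpen(pen_idx(j)) = 1.0 / tau(j) + lambda2;

    // beta | rest ~ N(A^{-1} X'Wy, sigma2 A^{-1}), A = X'WX + sigma2 D
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    A.diag() += sigma2 * dpen;
    arma::vec b = Xw.t() * y;
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), b));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    beta = mu + std::sqrt(sigma2) * arma::solve(arma::trimatu(L.t()), z);

    // 1/tau_j | rest ~ InvGauss(sqrt(lambda1^2 / beta_j^2), lambda1^2)
    for (int j = 0; j < ppen; ++j) {
      double bj = beta(pen_idx(j));
      double b2 = bj * bj;
      if (b2 < 1e-20) b2 = 1e-20;
      double m = std::sqrt(lambda1_sq / b2);
      if (m > 1e8) m = 1e8;
      double inv_tau = rinvgauss1(m, lambda1_sq);
      tau(j) = 1.0 / std::max(inv_tau, 1e-12);
    }

    // sigma2 | rest ~ InvGamma(n/2, weighted RSS / 2)
    resid = y - X * beta;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += w(i) * resid(i) * resid(i);
    sigma2 = 0.5 * rss / R::rgamma(0.5 * n, 1.0);
    if (sigma2 < 1e-12) sigma2 = 1e-12;

    // hyperparameters
    if (lambda1_sq_fixed <= 0.0) {
      double rate1 = r1 + 0.5 * arma::accu(tau);
      lambda1_sq = R::rgamma(ppen + a1, 1.0 / rate1);
      if (lambda1_sq < 1e-12) lambda1_sq = 1e-12;
    }
    if (lambda2_fixed <= 0.0) {
      double ssb = 0.0;
      for (int j = 0; j < ppen; ++j) {
        double bj = beta(pen_idx(j));
        ssb += bj * bj;
      }
      double rate2 = r2 + 0.5 * ssb;
      lambda2 = R::rgamma(0.5 * ppen + a2, 1.0 / rate2);
      if (lambda2 < 1e-12) lambda2 = 1e-12;
    }

    if (it >= burn_in) {
      int k = it - burn_in;
      beta_draws.row(k) = beta.t();
      sigma2_draws(k) = sigma2;
      lambda1_sq_draws(k) = lambda1_sq;
      lambda2_draws(k) = lambda2;
      w_mean += w;
      for (int i = 0; i < n; ++i) if (w(i) < w_min(i)) w_min(i) = w(i);
    }
  }
  w_mean /= keep;

  return List::create(_["beta"] = beta_draws,
                      _["sigma2"] = sigma2_draws,
                      _["lambda1_sq"] = lambda1_sq_draws,
                      _["lambda2"] = lambda2_draws,
                      _["w_mean"] = w_mean,
                      _["w_min"] = w_min);
}
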