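#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One-sided truncated standard-normal-shifted draw: z ~ N(mu, 1) truncated
// to (0, inf) when positive, (-inf, 0] otherwise. Inverse-CDF sampling.
static inline double rtnorm01(double mu, bool positive) {
  double u;
  if (positive) {
    double p0 = R::pnorm(0.0, mu, 1.0, 1, 0); // P(z <= 0)
    u = R::runif(p0, 1.0);
  } else {
    double p0 = R::pnorm(0.0, mu, 1.0, 1, 0);
    u = R::runif(0.0, p0);
  }
  // guard against u hitting 0/1 in the extreme tails
  u = std::min(std::max(u, 1e-15), 1.0 - 1e-15);
  return R::qnorm(u, mu, 1.0, 1, 0);
}

// Gibbs sampler for the symmetric binary-probit social relations model:
//   z_d = x_d' beta + a_{i(d)} + a_{j(d)} + eps_d,  eps ~ N(0,1)
//   y_d = 1{z_d > 0},  a_i ~ N(0, sigma_a^2)
// Priors: beta ~ N(0, prior_var * I), sigma_a^2 ~ InvGamma(ig_shape, ig_rate).
// Actor effects are recentred each sweep (their mean is absorbed into the
// intercept, assumed to be column 0 of X) for identifiability.
// [[Rcpp::export]]
List srm_gibbs_cpp(const arma::ivec& y, const arma::mat& X,
                   const arma::ivec& ia, const arma::ivec& ib, int n_actors,
                   int n_iter, int burn_in, double prior_var,
                   double ig_shape, double ig_rate) {
  int n = y.n_elem, p = X.n_cols;
  int n_keep = n_iter - burn_in;

  arma::mat XtX = X.t() * X;
  arma::mat prec0 = XtX + arma::eye(p, p) / prior_var;
  arma::mat R = arma::chol(prec0); // upper triangular, prec0 = R'R

  // per-actor dyad lists
  std::vector<std::vector<int>> mine(n_actors);
  std::vector<std::vector<int>> other(n_actors);
  for (int d = 0; d < n; ++d) {
    mine[ia[d]].push_back(d);  other[ia[d]].push_back(ib[d]);
    mine[ib[d]].push_back(d);  other[ib[d]].push_back(ia[d]);
  }

  arma::vec beta(p, arma::fill::zeros);
  arma::vec a(n_actors, arma::fill::zeros);
  arma::vec z(n, arma::fill::zeros);
  double sigma2_a = 1.0;

  arma::mat beta_draws(n_keep, p);
  arma::vec sig_draws(n_keep);
  arma::mat a_draws(n_keep, n_actors);

  arma::vec xb = X * beta;
  for (int it = 0; it < n_iter; ++it) {
    // latent utilities
    for (int d = 0; d < n; ++d) {
      double mu = xb[d] + a[ia[d]] + a[ib[d]];
      z[d] = rtnorm01(mu, y[d] == 1);
    }
    // regression coefficients
    arma::vec zstar(n);
    for (int d = 0; d < n; ++d) zstar[d] = z[d] - a[ia[d]] - a[ib[d]];
    arma::vec mu_b = arma::solve(prec0, X.t() * zstar);
    arma::vec eps(p);
    for (int k = 0; k < p; ++k) eps[k] = R::norm_rand();
    beta = mu_b + arma::solve(arma::trimatu(R), eps);
    xb = X * beta;
    // actor effects, sequentially (each conditional depends on the others)
    for (int i = 0; i < n_actors; ++i) {
      double s = 0.0; int ni = mine[i].size();
      for (int q = 0; q < ni; ++q) {
        int d = mine[i][q];
        s += z[d] - xb[d] - a[other[i][q]];
      }
      double prec = ni + 1.0 / sigma2_a;
      a[i] = s / prec + R::norm_rand() / std::sqrt(prec);
    }
    // recentre: shift mean of a into the intercept
    double abar = arma::mean(a);
    a -= abar;
    beta[0] += 2.0 * abar; // a enters twice per dyad
    xb = X * beta;
    // actor-effect variance
    double ssa = arma::dot(a, a);
    double shape = ig_shape + 0.5 * n_actors;
    double rate = ig_rate + 0.5 * ssa;
    sigma2_a = 1.0 / R::rgamma(shape, 1.0 / rate);
    if (it >= burn_in) {
      beta_draws.row(it - burn_in) = beta.t();
      sig_draws[it - burn_in] = sigma2_a;
      a_draws.row(it - burn_in) = a.t();
    }
  }
  return List::create(_["beta"] = beta_draws, _["sigma2_a"] = sig_draws,
                      _["actor"] = a_draws);
}
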