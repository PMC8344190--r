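// Spike-slab (Bayes C) Gibbs sampler with feature blocks.
//
// Each block (e.g. SNPs, taxa) has its own inclusion probability pi and slab
// variance. Missing phenotypes are handled by data augmentation. Per kept
// iteration the sampler records the variance shares of each block's fitted
// values (heritability / microbiability draws), the absolute between-block
// covariance share, per-feature inclusion indicators, and the linear
// predictor for prediction of masked records.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double rinvchisq(double df, double ss) {
  // draw sigma2 = ss / chi2_df
  return ss / R::rchisq(df);
}

// [[Rcpp::export(.bayesc_gibbs)]]
List bayesc_gibbs(arma::vec y, const arma::uvec& miss_idx, const List& blocks,
                  const arma::vec& pi0, const arma::vec& p0,
                  double df_b, const arma::vec& S_b,
                  double df_e, double S_e, double var_y_ref,
                  int niter, int burnin, int thin) {
  const int n = y.n_elem;
  const int nb = blocks.size();

  std::vector<arma::mat> X(nb);
  std::vector<arma::vec> beta(nb), xtx(nb);
  std::vector<arma::uvec> delta(nb);
  std::vector<arma::vec> incl(nb);
  arma::vec sigma2_b(nb), pi(nb);

  for (int b = 0; b < nb; ++b) {
    X[b] = as<arma::mat>(blocks[b]);
    const int p = X[b].n_cols;
    beta[b] = arma::zeros(p);
    delta[b] = arma::zeros<arma::uvec>(p);
    incl[b] = arma::zeros(p);
    xtx[b] = arma::sum(arma::square(X[b]), 0).t();
    pi(b) = pi0(b);
    // slab variance sized so pi0 * p features explain their share a priori
    sigma2_b(b) = df_b * S_b(b) / (df_b + 2.0);
  }
  double sigma2_e = df_e * S_e / (df_e + 2.0);
  double mu = arma::mean(y);
  arma::vec e = y - mu;

  const int nkeep = (niter - burnin) / thin;
  arma::mat share_tr(nkeep, nb, arma::fill::zeros);
  arma::vec abscov_tr(nkeep, arma::fill::zeros);
  arma::vec s2e_tr(nkeep, arma::fill::zeros);
  arma::mat s2b_tr(nkeep, nb, arma::fill::zeros);
  arma::vec yhat_sum(n, arma::fill::zeros);
  int kept = 0;

  for (int it = 1; it <= niter; ++it) {
    // intercept (flat prior)
    e += mu;
    mu = arma::mean(e) + R::norm_rand() * std::sqrt(sigma2_e / n);
    e -= mu;

    for (int b = 0; b < nb; ++b) {
      const int p = X[b].n_cols;
      const double lambda = sigma2_e / sigma2_b(b);
      const double logpi = std::log(pi(b)) - std::log1p(-pi(b));
      for (int j = 0; j < p; ++j) {
        const double bj = beta[b](j);
        const double c = xtx[b](j);
        double rhs = arma::dot(X[b].col(j), e) + c * bj;
        const double C = c + lambda;
        const double logodds = logpi + 0.5 * std::log(lambda / C) +
          rhs * rhs / (2.0 * sigma2_e * C);
        double bnew = 0.0;
        if (std::log(R::unif_rand()) < -std::log1p(std::exp(-logodds))) {
          bnew = rhs / C + R::norm_rand() * std::sqrt(sigma2_e / C);
          delta[b](j) = 1;
        } else {
          delta[b](j) = 0;
        }
        if (bnew != bj) {
          e += X[b].col(j) * (bj - bnew);
          beta[b](j) = bnew;
        }
      }
      // slab variance and inclusion probability
      const arma::uvec in = arma::find(delta[b] == 1);
      const int m = in.n_elem;
      double ss = 0.0;
      for (arma::uword i = 0; i < in.n_elem; ++i) ss += beta[b](in(i)) * beta[b](in(i));
      sigma2_b(b) = rinvchisq(df_b + m, ss + df_b * S_b(b));
      if (sigma2_b(b) < 1e-10) sigma2_b(b) = 1e-10;
      const double a0 = pi0(b) * p0(b), b0 = (1.0 - pi0(b)) * p0(b);
      pi(b) = R::rbeta(a0 + m, b0 + (p - m));
      if (pi(b) < 1e-8) pi(b) = 1e-8;
      if (pi(b) > 1.0 - 1e-8) pi(b) = 1.0 - 1e-8;
    }

    // residual variance
    sigma2_e = rinvchisq(df_e + n, arma::dot(e, e) + df_e * S_e);
    if (!std::isfinite(sigma2_e)) stop("non-finite residual variance in Bayes C chain");

    // data augmentation for masked phenotypes
    for (arma::uword i = 0; i < miss_idx.n_elem; ++i) {
      const arma::uword id = miss_idx(i);
      const double fitted = y(id) - e(id);
      e(id) = R::norm_rand() * std::sqrt(sigma2_e);
      y(id) = fitted + e(id);
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      std::vector<arma::vec> val(nb);
      for (int b = 0; b < nb; ++b) {
        const arma::uvec in = arma::find(beta[b] != 0.0);
        val[b] = arma::zeros(n);
        if (in.n_elem > 0) val[b] = X[b].cols(in) * beta[b](in);
        share_tr(kept, b) = arma::var(val[b]) / var_y_ref;
        incl[b] += arma::conv_to<arma::vec>::from(delta[b]);
      }
      if (nb == 2) {
        abscov_tr(kept) = std::abs(arma::as_scalar(arma::cov(val[0], val[1]))) / var_y_ref;
      }
      s2e_tr(kept) = sigma2_e;
      for (int b = 0; b < nb; ++b) s2b_tr(kept, b) = sigma2_b(b);
      arma::vec fitted = mu + val[0];
      for (int b = 1; b < nb; ++b) fitted += val[b];
      yhat_sum += fitted;
      ++kept;
    }
  }

  List incl_out(nb);
  for (int b = 0; b < nb; ++b) incl_out[b] = incl[b] / std::max(kept, 1);

  return List::create(
    _["share_trace"] = share_tr,
    _["abscov_trace"] = abscov_tr,
    _["sigma2_e_trace"] = s2e_tr,
    _["sigma2_b_trace"] = s2b_tr,
    _["inclusion"] = incl_out,
    _["yhat"] = yhat_sum / std::max(kept, 1),
    _["kept"] = kept);
}
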