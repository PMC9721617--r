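// Adaptive Metropolis-within-Gibbs sampler for the joint two-session
// hierarchical model:
//
//   latent_i ~ MVN(m_i, Sigma),  m_i = (mu_base, mu_delta + X_i beta)
//   Sigma = diag(sigma) R diag(sigma),  R = L L'
//   mu ~ N(0, 1), sigma ~ HalfNormal(0, 1), L ~ LKJ-Cholesky(2),
//   beta ~ N(0, 1.5)
//   choices | latent_i ~ sequential softmax likelihood of the choice model
//
// Subject latents are updated coordinate-wise by adaptive random-walk
// Metropolis; (mu, beta) jointly by a conjugate Gibbs draw (Gaussian linear
// model given the latents); log sigma and the unconstrained correlation
// coordinates (tanh / Cholesky transform with its Jacobian) coordinate-wise
// by adaptive random-walk Metropolis. Randomness comes from R's RNG, so
// set.seed() on the R side makes chains reproducible.

#include <RcppArmadillo.h>
#include "agents.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// Build the Cholesky factor of a correlation matrix from unconstrained y
// (z = tanh(y), row-filled); returns log |Jacobian| of y -> L.
static double build_corr_chol(const arma::vec& y, int K, arma::mat& L) {
  double logjac = 0.0;
  int idx = 0;
  L.zeros(K, K);
  L(0, 0) = 1.0;
  for (int i = 1; i < K; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      const double z = std::tanh(y(idx));
      const double rem = 1.0 - sumsq;
      const double lij = z * std::sqrt(rem);
      logjac += std::log1p(-z * z) + 0.5 * std::log(rem);
      L(i, j) = lij;
      sumsq += lij * lij;
      ++idx;
    }
    L(i, i) = std::sqrt(std::max(1.0 - sumsq, 1e-12));
  }
  return logjac;
}

// log LKJ(eta) density of a correlation Cholesky factor (unnormalized).
static double lkj_chol_logpdf(const arma::mat& L, double eta) {
  const int K = L.n_rows;
  double s = 0.0;
  for (int i = 1; i < K; ++i)
    s += (K - (i + 1) + 2.0 * eta - 2.0) * std::log(L(i, i));
  return s;
}

static double mvn_logdens(const arma::vec& x, const arma::vec& m,
                          const arma::mat& Lsig) {
  arma::vec z = arma::solve(arma::trimatl(Lsig), x - m);
  double ld = arma::sum(arma::log(Lsig.diag()));
  return -0.5 * arma::dot(z, z) - ld - 0.5 * x.n_elem * LOG2PI;
}

struct HierData {
  int model, p, K;
  std::vector<int> kinds;
  const int* fs; const int* act; const int* pl; const double* r;
  arma::imat idx;       // n x 4: start1, len1, start2, len2 (0-based)
  arma::mat X;          // n x n_g drug/serum dummies
  int tm[2][2];
};

// Likelihood of one subject session under latent vector lat.
static double subj_sess_ll(const HierData& d, const arma::vec& lat, int i,
                           int sess) {
  const int start = d.idx(i, 2 * sess), len = d.idx(i, 2 * sess + 1);
  if (len == 0) return 0.0;
  std::vector<double> pv(d.p);
  for (int j = 0; j < d.p; ++j) {
    double x = (sess == 0) ? lat(j) : lat(j) + lat(d.p + j);
    pv[j] = (d.kinds[j] == 0) ? R::pnorm(x, 0.0, 1.0, 1, 0)
          : (d.kinds[j] == 1) ? std::exp(x) : x;
  }
  return twostep::session_ll(d.model, pv.data(), d.fs + start, d.act + start,
                             d.pl + start, d.r + start, len, d.tm);
}

// [[Rcpp::export]]
List fit_hier_chain_cpp(int model, int p, IntegerVector kinds_in,
                        IntegerVector fs, IntegerVector act, IntegerVector pl,
                        NumericVector r, IntegerMatrix idx_in,
                        NumericMatrix X_in, IntegerMatrix tmap, int n_iter,
                        int n_warmup, int sweeps, int hyper_rounds,
                        double init_jitter) {
  HierData d;
  d.model = model;
  d.p = p;
  d.K = 2 * p;
  d.kinds.assign(kinds_in.begin(), kinds_in.end());
  d.fs = fs.begin(); d.act = act.begin(); d.pl = pl.begin(); d.r = r.begin();
  d.idx = arma::imat(idx_in.nrow(), 4);
  for (int i = 0; i < idx_in.nrow(); ++i)
    for (int j = 0; j < 4; ++j) d.idx(i, j) = idx_in(i, j);
  d.X = as<arma::mat>(X_in);
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a) d.tm[s][a] = tmap(s, a) - 1;

  const int n = d.idx.n_rows, K = d.K, ng = d.X.n_cols;
  const int ny = K * (K - 1) / 2;
  const int q = K + ng * p;  // (mu, beta) dimension
  const int S = n_iter - n_warmup;

  // --- state ---
  arma::mat lat(K, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) lat(k, i) = init_jitter * norm_rand();
  arma::vec mu(K, arma::fill::zeros);
  arma::mat beta(p, ng, arma::fill::zeros);  // beta(j, g): effect on delta_j
  arma::vec lsig(K);
  lsig.fill(std::log(0.5));
  arma::vec y(ny, arma::fill::zeros);

  arma::mat L(K, K);
  double logjac = build_corr_chol(y, K, L);
  arma::vec sig = arma::exp(lsig);
  arma::mat Lsig = arma::diagmat(sig) * L;

  // subject prior means
  arma::mat m(K, n);
  auto refresh_means = [&]() {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) {
        m(j, i) = mu(j);
        double add = 0.0;
        for (int g = 0; g < ng; ++g) add += d.X(i, g) * beta(j, g);
        m(p + j, i) = mu(p + j) + add;
      }
    }
  };
  refresh_means();

  // caches
  arma::vec lp_prior(n), ll1(n), ll2(n);
  for (int i = 0; i < n; ++i) {
    lp_prior(i) = mvn_logdens(lat.col(i), m.col(i), Lsig);
    ll1(i) = subj_sess_ll(d, lat.col(i), i, 0);
    ll2(i) = subj_sess_ll(d, lat.col(i), i, 1);
  }

  // adaptive step sizes
  arma::mat step_lat(K, n);
  step_lat.fill(std::log(0.2));
  arma::vec step_sig(K), step_y(ny), step_ns(K);
  step_sig.fill(std::log(0.3));
  step_y.fill(std::log(0.3));
  step_ns.fill(std::log(0.3));
  long acc_lat = 0, try_lat = 0, acc_hyp = 0, try_hyp = 0;

  // prior precisions for the Gibbs block
  arma::vec prior_prec(q);
  for (int j = 0; j < K; ++j) prior_prec(j) = 1.0;           // mu ~ N(0,1)
  for (int j = K; j < q; ++j) prior_prec(j) = 1.0 / 2.25;    // beta ~ N(0,1.5)

  // draws
  arma::mat dr_mu(S, K), dr_sig(S, K), dr_beta(S, p * ng), dr_y(S, ny),
      dr_corr(S, ny), dr_lat(S, n * K);
  arma::vec dr_lp(S);

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool warm = iter < n_warmup;
    const double gam = warm ? 1.0 / std::sqrt(10.0 + iter) : 0.0;

    // ---- subject latents, coordinate-wise RWM ----
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) {
          arma::vec prop = lat.col(i);
          prop(k) += std::exp(step_lat(k, i)) * norm_rand();
          const double lpp = mvn_logdens(prop, m.col(i), Lsig);
          double l1 = ll1(i), l2;
          if (k < p) l1 = subj_sess_ll(d, prop, i, 0);
          l2 = subj_sess_ll(d, prop, i, 1);
          const double la =
              (lpp + l1 + l2) - (lp_prior(i) + ll1(i) + ll2(i));
          double a = std::min(1.0, std::exp(la));
          if (!std::isfinite(la)) a = 0.0;
          ++try_lat;
          if (unif_rand() < a) {
            lat.col(i) = prop;
            lp_prior(i) = lpp;
            ll1(i) = l1;
            ll2(i) = l2;
            ++acc_lat;
          }
          if (warm) step_lat(k, i) += gam * (a - 0.44);
        }
      }
    }

    // ---- (mu, beta): conjugate Gibbs draw ----
    {
      arma::mat Omega = Lsig * Lsig.t();
      Omega = arma::inv_sympd(Omega);
      arma::mat P = arma::diagmat(prior_prec);
      arma::vec b(q, arma::fill::zeros);
      arma::mat A(K, q);
      for (int i = 0; i < n; ++i) {
        A.zeros();
        for (int k = 0; k < K; ++k) A(k, k) = 1.0;
        for (int g = 0; g < ng; ++g)
          for (int j = 0; j < p; ++j) A(p + j, K + g * p + j) = d.X(i, g);
        arma::mat OA = Omega * A;
        P += A.t() * OA;
        b += OA.t() * lat.col(i);
      }
      arma::mat Pchol = arma::chol(P, "lower");
      arma::vec mean = arma::solve(arma::trimatu(Pchol.t()),
                                   arma::solve(arma::trimatl(Pchol), b));
      arma::vec zdraw(q);
      for (int j = 0; j < q; ++j) zdraw(j) = norm_rand();
      arma::vec theta = mean + arma::solve(arma::trimatu(Pchol.t()), zdraw);
      mu = theta.subvec(0, K - 1);
      for (int g = 0; g < ng; ++g)
        beta.col(g) = theta.subvec(K + g * p, K + (g + 1) * p - 1);
      refresh_means();
      for (int i = 0; i < n; ++i)
        lp_prior(i) = mvn_logdens(lat.col(i), m.col(i), Lsig);
    }

    // ---- log sigma and correlation, coordinate-wise RWM ----
    // cheap relative to the subject sweeps, so several rounds per iteration
    // improve hyper-parameter mixing
    for (int round = 0; round < hyper_rounds; ++round) {
    for (int j = 0; j < K; ++j) {
      arma::vec lsig_p = lsig;
      lsig_p(j) += std::exp(step_sig(j)) * norm_rand();
      arma::vec sig_p = arma::exp(lsig_p);
      arma::mat Lsig_p = arma::diagmat(sig_p) * L;
      double lp_new = 0.0, lp_old = 0.0;
      arma::vec lp_prior_new(n);
      for (int i = 0; i < n; ++i) {
        lp_prior_new(i) = mvn_logdens(lat.col(i), m.col(i), Lsig_p);
        lp_new += lp_prior_new(i);
        lp_old += lp_prior(i);
      }
      // HalfNormal(0,1) prior + log-space Jacobian
      lp_new += -0.5 * sig_p(j) * sig_p(j) + lsig_p(j);
      lp_old += -0.5 * sig(j) * sig(j) + lsig(j);
      const double la = lp_new - lp_old;
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++try_hyp;
      if (unif_rand() < a) {
        lsig = lsig_p;
        sig = sig_p;
        Lsig = Lsig_p;
        lp_prior = lp_prior_new;
        ++acc_hyp;
      }
      if (warm) step_sig(j) += gam * (a - 0.44);
    }

    // ---- non-centered scale move ----
    // rescale sigma_k together with the subjects' k-th latent deviations
    // from their prior means, keeping standardized residuals fixed: the
    // residual prior cancels, leaving the sigma prior and the likelihood
    if (round == 0)
    for (int k = 0; k < K; ++k) {
      const double delta = std::exp(step_ns(k)) * norm_rand();
      const double scale = std::exp(delta);
      const double signew = sig(k) * scale;
      double la = (-0.5 * signew * signew + std::log(signew)) -
                  (-0.5 * sig(k) * sig(k) + std::log(sig(k)));
      arma::mat lat_p = lat;
      for (int i = 0; i < n; ++i)
        lat_p(k, i) = m(k, i) + scale * (lat(k, i) - m(k, i));
      arma::vec l1n(n), l2n(n);
      for (int i = 0; i < n; ++i) {
        if (k < p) {
          l1n(i) = subj_sess_ll(d, lat_p.col(i), i, 0);
        } else l1n(i) = ll1(i);
        l2n(i) = subj_sess_ll(d, lat_p.col(i), i, 1);
        la += (l1n(i) + l2n(i)) - (ll1(i) + ll2(i));
      }
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++try_hyp;
      if (unif_rand() < a) {
        lat = lat_p;
        lsig(k) += delta;
        sig(k) = signew;
        Lsig = arma::diagmat(sig) * L;
        ll1 = l1n;
        ll2 = l2n;
        for (int i = 0; i < n; ++i)
          lp_prior(i) = mvn_logdens(lat.col(i), m.col(i), Lsig);
        ++acc_hyp;
      }
      if (warm) step_ns(k) += gam * (a - 0.44);
    }

    // ---- correlation coordinates, coordinate-wise RWM ----
    for (int l = 0; l < ny; ++l) {
      arma::vec y_p = y;
      y_p(l) += std::exp(step_y(l)) * norm_rand();
      arma::mat L_p(K, K);
      const double logjac_p = build_corr_chol(y_p, K, L_p);
      arma::mat Lsig_p = arma::diagmat(sig) * L_p;
      double lp_new = lkj_chol_logpdf(L_p, 2.0) + logjac_p;
      double lp_old = lkj_chol_logpdf(L, 2.0) + logjac;
      arma::vec lp_prior_new(n);
      for (int i = 0; i < n; ++i) {
        lp_prior_new(i) = mvn_logdens(lat.col(i), m.col(i), Lsig_p);
        lp_new += lp_prior_new(i);
        lp_old += lp_prior(i);
      }
      const double la = lp_new - lp_old;
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++try_hyp;
      if (unif_rand() < a) {
        y = y_p;
        L = L_p;
        logjac = logjac_p;
        Lsig = Lsig_p;
        lp_prior = lp_prior_new;
        ++acc_hyp;
      }
      if (warm) step_y(l) += gam * (a - 0.44);
    }
    }

    // ---- store ----
    if (!warm) {
      const int s = iter - n_warmup;
      for (int k = 0; k < K; ++k) {
        dr_mu(s, k) = mu(k);
        dr_sig(s, k) = sig(k);
      }
      for (int g = 0; g < ng; ++g)
        for (int j = 0; j < p; ++j) dr_beta(s, g * p + j) = beta(j, g);
      arma::mat R = L * L.t();
      int c = 0;
      for (int i2 = 1; i2 < K; ++i2)
        for (int j2 = 0; j2 < i2; ++j2) {
          dr_corr(s, c) = R(i2, j2);
          dr_y(s, c) = y(c);
          ++c;
        }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) dr_lat(s, i * K + k) = lat(k, i);
      double lp = arma::sum(lp_prior) + arma::sum(ll1) + arma::sum(ll2);
      lp += -0.5 * arma::dot(mu, mu);
      for (int g = 0; g < ng; ++g)
        lp += -0.5 * arma::dot(beta.col(g), beta.col(g)) / 2.25;
      lp += arma::sum(-0.5 * sig % sig);
      lp += lkj_chol_logpdf(L, 2.0);
      dr_lp(s) = lp;
    }
  }

  return List::create(
      _["mu"] = wrap(dr_mu), _["sigma"] = wrap(dr_sig),
      _["beta"] = wrap(dr_beta), _["corr"] = wrap(dr_corr),
      _["latents"] = wrap(dr_lat), _["lp"] = wrap(dr_lp),
      _["accept_latents"] = double(acc_lat) / std::max(1L, try_lat),
      _["accept_hyper"] = double(acc_hyp) / std::max(1L, try_hyp));
}
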