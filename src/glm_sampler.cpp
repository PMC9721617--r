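// Adaptive Metropolis-within-Gibbs sampler for the hierarchical Bernoulli-
// logit regression of stay behaviour:
//
//   stay ~ Bernoulli(inv_logit(F theta + W b_subject))
//   b_i ~ MVN(0, Sigma_b), Sigma_b = diag(sigma) R diag(sigma)
//   theta_j ~ N(0, 3) (slopes) / Student-t(3, 0, 10) (intercept)
//   sigma ~ HalfCauchy(0, 2), R ~ LKJ(2)
//
// Population coefficients, subject random effects, log sigma and the
// unconstrained correlation coordinates are all updated coordinate-wise by
// adaptive random-walk Metropolis; the row-level linear predictor is cached
// and updated incrementally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI_G = std::log(2.0 * M_PI);

static double build_corr_chol_g(const arma::vec& y, int K, arma::mat& L) {
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

static double lkj_chol_logpdf_g(const arma::mat& L, double eta) {
  const int K = L.n_rows;
  double s = 0.0;
  for (int i = 1; i < K; ++i)
    s += (K - (i + 1) + 2.0 * eta - 2.0) * std::log(L(i, i));
  return s;
}

static double mvn_logdens_g(const arma::vec& x, const arma::mat& Lsig) {
  arma::vec z = arma::solve(arma::trimatl(Lsig), x);
  double ld = arma::sum(arma::log(Lsig.diag()));
  return -0.5 * arma::dot(z, z) - ld - 0.5 * x.n_elem * LOG2PI_G;
}

static inline double log1pexp_s(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli-logit log-likelihood of rows [start, end)
static double ll_range(const int* yv, const double* eta, int start, int end) {
  double ll = 0.0;
  for (int i = start; i < end; ++i)
    ll += yv[i] * eta[i] - log1pexp_s(eta[i]);
  return ll;
}

// priors: [0] slope SD (normal), [1] intercept scale, [2] intercept df
// (Student-t), [3] sigma scale (half-Cauchy), [4] LKJ shape
static double theta_prior(double x, bool intercept, const double* pr) {
  if (intercept) {
    const double nu = pr[2], s = pr[1];
    return -0.5 * (nu + 1.0) * std::log1p(x * x / (nu * s * s));
  }
  return -0.5 * x * x / (pr[0] * pr[0]);
}

// rows must be grouped by subject; bounds: (n_subj + 1) row offsets.
// [[Rcpp::export]]
List fit_stay_glm_cpp(IntegerVector yv, NumericMatrix F_in, NumericMatrix W_in,
                      IntegerVector bounds, int intercept_col,
                      NumericVector priors, int n_iter, int n_warmup,
                      int sweeps, int theta_rounds, IntegerVector partner_re,
                      IntegerMatrix member) {
  const double* pr = priors.begin();
  const double sig_scale2 = priors[3] * priors[3];
  const double lkj_eta = priors[4];
  const arma::mat F = as<arma::mat>(F_in);
  const arma::mat W = as<arma::mat>(W_in);
  const int N = F.n_rows, qf = F.n_cols, K = W.n_cols;
  const int n = bounds.size() - 1;
  const int ny = K * (K - 1) / 2;
  const int S = n_iter - n_warmup;
  const int* yp = yv.begin();

  arma::vec theta(qf, arma::fill::zeros);
  arma::mat b(K, n, arma::fill::zeros);
  arma::vec lsig(K);
  lsig.fill(std::log(0.5));
  arma::vec ycor(ny, arma::fill::zeros);

  arma::mat L(K, K);
  double logjac = build_corr_chol_g(ycor, K, L);
  arma::vec sig = arma::exp(lsig);
  arma::mat Lsig = arma::diagmat(sig) * L;

  arma::vec eta(N, arma::fill::zeros);  // F theta + W b = 0 at init
  arma::vec ll_subj(n), lp_b(n);
  for (int i = 0; i < n; ++i) {
    ll_subj(i) = ll_range(yp, eta.memptr(), bounds[i], bounds[i + 1]);
    lp_b(i) = mvn_logdens_g(b.col(i), Lsig);
  }

  // row -> subject map and per-column nonzero rows (drug-dummy interaction
  // columns are zero outside one arm; skipping zero rows makes the
  // coefficient updates cheap)
  std::vector<int> subj_of(N);
  for (int i = 0; i < n; ++i)
    for (int row = bounds[i]; row < bounds[i + 1]; ++row) subj_of[row] = i;
  std::vector< std::vector<int> > nz(qf);
  for (int j = 0; j < qf; ++j)
    for (int i = 0; i < N; ++i)
      if (F(i, j) != 0.0) nz[j].push_back(i);
  arma::vec dll_subj(n);

  arma::vec step_t(qf), step_sig(K), step_y(ny), step_r(qf), step_ns(K);
  arma::mat step_b(K, n);
  step_t.fill(std::log(0.1));
  step_r.fill(std::log(0.2));
  step_ns.fill(std::log(0.4));
  step_b.fill(std::log(0.3));
  step_sig.fill(std::log(0.3));
  step_y.fill(std::log(0.3));
  long acc = 0, tries = 0;

  arma::mat dr_theta(S, qf), dr_sig(S, K), dr_corr(S, ny), dr_b(S, n * K);
  arma::vec dr_lp(S);

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool warm = iter < n_warmup;
    const double gam = warm ? 1.0 / std::sqrt(10.0 + iter) : 0.0;

    for (int sw = 0; sw < sweeps; ++sw) {
      // ---- population coefficients ----
      for (int round = 0; round < theta_rounds; ++round) {
      for (int j = 0; j < qf; ++j) {
        const double delta = std::exp(step_t(j)) * norm_rand();
        const double tnew = theta(j) + delta;
        dll_subj.zeros();
        double dll = 0.0;
        for (size_t t = 0; t < nz[j].size(); ++t) {
          const int row = nz[j][t];
          const double e = eta(row) + F(row, j) * delta;
          const double contrib = (yp[row] * e - log1pexp_s(e)) -
                                 (yp[row] * eta(row) - log1pexp_s(eta(row)));
          dll += contrib;
          dll_subj(subj_of[row]) += contrib;
        }
        const double la = dll + theta_prior(tnew, j == intercept_col, pr) -
                          theta_prior(theta(j), j == intercept_col, pr);
        double a = std::min(1.0, std::exp(la));
        if (!std::isfinite(la)) a = 0.0;
        ++tries;
        if (unif_rand() < a) {
          theta(j) = tnew;
          for (size_t t = 0; t < nz[j].size(); ++t) {
            const int row = nz[j][t];
            eta(row) += F(row, j) * delta;
          }
          ll_subj += dll_subj;
          ++acc;
        }
        if (warm) step_t(j) += gam * (a - 0.44);
      }
      }

      // ---- subject random effects ----
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) {
          const double delta = std::exp(step_b(k, i)) * norm_rand();
          arma::vec bprop = b.col(i);
          bprop(k) += delta;
          double ll_new = 0.0;
          for (int row = bounds[i]; row < bounds[i + 1]; ++row) {
            const double e = eta(row) + W(row, k) * delta;
            ll_new += yp[row] * e - log1pexp_s(e);
          }
          const double lpb_new = mvn_logdens_g(bprop, Lsig);
          const double la = ll_new + lpb_new - ll_subj(i) - lp_b(i);
          double a = std::min(1.0, std::exp(la));
          if (!std::isfinite(la)) a = 0.0;
          ++tries;
          if (unif_rand() < a) {
            b.col(i) = bprop;
            for (int row = bounds[i]; row < bounds[i + 1]; ++row)
              eta(row) += W(row, k) * delta;
            ll_subj(i) = ll_new;
            lp_b(i) = lpb_new;
            ++acc;
          }
          if (warm) step_b(k, i) += gam * (a - 0.44);
        }
      }

      // ---- recentering (ancillarity-sufficiency) moves ----
      // shift a population coefficient and its partner random effects in
      // opposite directions within the coefficient's arm; the linear
      // predictor is unchanged, so only prior terms enter the ratio
      for (int j = 0; j < qf; ++j) {
        const int k = partner_re[j];
        if (k < 0) continue;
        const double delta = std::exp(step_r(j)) * norm_rand();
        const double tnew = theta(j) + delta;
        double la = theta_prior(tnew, j == intercept_col, pr) -
                    theta_prior(theta(j), j == intercept_col, pr);
        arma::vec lp_b_new = lp_b;
        for (int i = 0; i < n; ++i) {
          if (!member(i, j)) continue;
          arma::vec bprop = b.col(i);
          bprop(k) -= delta;
          lp_b_new(i) = mvn_logdens_g(bprop, Lsig);
          la += lp_b_new(i) - lp_b(i);
        }
        double a = std::min(1.0, std::exp(la));
        if (!std::isfinite(la)) a = 0.0;
        ++tries;
        if (unif_rand() < a) {
          theta(j) = tnew;
          for (int i = 0; i < n; ++i)
            if (member(i, j)) b(k, i) -= delta;
          lp_b = lp_b_new;
          ++acc;
        }
        if (warm) step_r(j) += gam * (a - 0.44);
      }
    }

    // ---- hyper-parameters ----
    for (int j = 0; j < K; ++j) {
      arma::vec lsig_p = lsig;
      lsig_p(j) += std::exp(step_sig(j)) * norm_rand();
      arma::vec sig_p = arma::exp(lsig_p);
      arma::mat Lsig_p = arma::diagmat(sig_p) * L;
      double lp_new = -std::log1p(sig_p(j) * sig_p(j) / sig_scale2) + lsig_p(j);
      double lp_old = -std::log1p(sig(j) * sig(j) / sig_scale2) + lsig(j);
      arma::vec lp_b_new(n);
      for (int i = 0; i < n; ++i) {
        lp_b_new(i) = mvn_logdens_g(b.col(i), Lsig_p);
        lp_new += lp_b_new(i);
        lp_old += lp_b(i);
      }
      const double la = lp_new - lp_old;
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++tries;
      if (unif_rand() < a) {
        lsig = lsig_p; sig = sig_p; Lsig = Lsig_p; lp_b = lp_b_new;
        ++acc;
      }
      if (warm) step_sig(j) += gam * (a - 0.44);
    }

    // ---- non-centered scale moves ----
    // rescale sigma_k together with the k-th random-effect coordinate,
    // keeping the standardized residuals fixed; the N(0, I) prior of the
    // residuals cancels, leaving the sigma prior and the likelihood
    for (int k = 0; k < K; ++k) {
      const double delta = std::exp(step_ns(k)) * norm_rand();
      const double scale = std::exp(delta);
      const double signew = sig(k) * scale;
      double la = (-std::log1p(signew * signew / sig_scale2) +
                   std::log(signew)) -
                  (-std::log1p(sig(k) * sig(k) / sig_scale2) +
                   std::log(sig(k)));
      arma::vec ll_new(n);
      for (int i = 0; i < n; ++i) {
        const double shift = b(k, i) * (scale - 1.0);
        double lli = 0.0;
        for (int row = bounds[i]; row < bounds[i + 1]; ++row) {
          const double e = eta(row) + W(row, k) * shift;
          lli += yp[row] * e - log1pexp_s(e);
        }
        ll_new(i) = lli;
        la += lli - ll_subj(i);
      }
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++tries;
      if (unif_rand() < a) {
        for (int i = 0; i < n; ++i) {
          const double shift = b(k, i) * (scale - 1.0);
          for (int row = bounds[i]; row < bounds[i + 1]; ++row)
            eta(row) += W(row, k) * shift;
          b(k, i) *= scale;
        }
        lsig(k) += delta;
        sig(k) = signew;
        Lsig = arma::diagmat(sig) * L;
        ll_subj = ll_new;
        for (int i = 0; i < n; ++i) lp_b(i) = mvn_logdens_g(b.col(i), Lsig);
        ++acc;
      }
      if (warm) step_ns(k) += gam * (a - 0.44);
    }

    for (int l = 0; l < ny; ++l) {
      arma::vec y_p = ycor;
      y_p(l) += std::exp(step_y(l)) * norm_rand();
      arma::mat L_p(K, K);
      const double logjac_p = build_corr_chol_g(y_p, K, L_p);
      arma::mat Lsig_p = arma::diagmat(sig) * L_p;
      double lp_new = lkj_chol_logpdf_g(L_p, lkj_eta) + logjac_p;
      double lp_old = lkj_chol_logpdf_g(L, lkj_eta) + logjac;
      arma::vec lp_b_new(n);
      for (int i = 0; i < n; ++i) {
        lp_b_new(i) = mvn_logdens_g(b.col(i), Lsig_p);
        lp_new += lp_b_new(i);
        lp_old += lp_b(i);
      }
      const double la = lp_new - lp_old;
      double a = std::min(1.0, std::exp(la));
      if (!std::isfinite(la)) a = 0.0;
      ++tries;
      if (unif_rand() < a) {
        ycor = y_p; L = L_p; logjac = logjac_p; Lsig = Lsig_p; lp_b = lp_b_new;
        ++acc;
      }
      if (warm) step_y(l) += gam * (a - 0.44);
    }

    if (!warm) {
      const int s = iter - n_warmup;
      for (int j = 0; j < qf; ++j) dr_theta(s, j) = theta(j);
      for (int k = 0; k < K; ++k) dr_sig(s, k) = sig(k);
      arma::mat R = L * L.t();
      int c = 0;
      for (int i2 = 1; i2 < K; ++i2)
        for (int j2 = 0; j2 < i2; ++j2) dr_corr(s, c++) = R(i2, j2);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) dr_b(s, i * K + k) = b(k, i);
      double lp = arma::sum(ll_subj) + arma::sum(lp_b) +
                  lkj_chol_logpdf_g(L, lkj_eta);
      for (int j = 0; j < qf; ++j)
        lp += theta_prior(theta(j), j == intercept_col, pr);
      for (int k = 0; k < K; ++k)
        lp += -std::log1p(sig(k) * sig(k) / sig_scale2);
      dr_lp(s) = lp;
    }
  }

  return List::create(
      _["theta"] = wrap(dr_theta), _["sigma"] = wrap(dr_sig),
      _["corr"] = wrap(dr_corr), _["b"] = wrap(dr_b), _["lp"] = wrap(dr_lp),
      _["accept"] = double(acc) / std::max(1L, tries));
}
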