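#include <Rcpp.h>
#include "agents.h"

using namespace Rcpp;

static void fill_tm(const IntegerMatrix& tmap, int tm[2][2]) {
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a) tm[s][a] = tmap(s, a) - 1;
}

// [[Rcpp::export]]
double session_loglik_cpp(int model, NumericVector pv, IntegerVector fs,
                          IntegerVector act, IntegerVector pl,
                          NumericVector r, IntegerMatrix tmap) {
  int tm[2][2];
  fill_tm(tmap, tm);
  return twostep::session_ll(model, pv.begin(), fs.begin(), act.begin(),
                             pl.begin(), r.begin(), fs.size(), tm);
}

// [[Rcpp::export]]
NumericVector session_loglik_pointwise_cpp(int model, NumericVector pv,
                                           IntegerVector fs, IntegerVector act,
                                           IntegerVector pl, NumericVector r,
                                           IntegerMatrix tmap) {
  int tm[2][2];
  fill_tm(tmap, tm);
  NumericVector out(fs.size());
  twostep::session_ll(model, pv.begin(), fs.begin(), act.begin(), pl.begin(),
                      r.begin(), fs.size(), tm, out.begin());
  return out;
}

// Per-draw, per-trial log-likelihoods over a whole cohort.
// latents: S x (n_subj * 2p) draws of subject latent vectors, subject-major.
// kinds: 0 = unit_interval (probit), 1 = positive (log), 2 = unbounded.
// idx: n_subj x 4 (0-based start1, len1, start2, len2 into the trial arrays).
// [[Rcpp::export]]
NumericMatrix cohort_pointwise_ll_cpp(int model, int p, IntegerVector kinds,
                                      NumericMatrix latents, IntegerVector fs,
                                      IntegerVector act, IntegerVector pl,
                                      NumericVector r, IntegerMatrix idx,
                                      IntegerMatrix tmap) {
  int tm[2][2];
  fill_tm(tmap, tm);
  const int S = latents.nrow(), n = idx.nrow(), N = fs.size();
  NumericMatrix out(S, N);
  std::vector<double> pv(p), buf;
  std::vector<double> lat(2 * p);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 2 * p; ++k) lat[k] = latents(s, i * 2 * p + k);
      for (int sess = 0; sess < 2; ++sess) {
        const int start = idx(i, 2 * sess), len = idx(i, 2 * sess + 1);
        if (len == 0) continue;
        for (int j = 0; j < p; ++j) {
          double x = (sess == 0) ? lat[j] : lat[j] + lat[p + j];
          pv[j] = (kinds[j] == 0) ? R::pnorm(x, 0.0, 1.0, 1, 0)
                : (kinds[j] == 1) ? std::exp(x) : x;
        }
        buf.resize(len);
        twostep::session_ll(model, pv.data(), fs.begin() + start,
                            act.begin() + start, pl.begin() + start,
                            r.begin() + start, len, tm, buf.data());
        for (int t = 0; t < len; ++t) out(s, start + t) = buf[t];
      }
    }
  }
  return out;
}

// Posterior predictive accuracy per subject: for each draw and trial the
// predicted choice is the argmax of the mixed values (ties credited 0.5),
// compared with the observed choice, averaged over draws and trials.
// [[Rcpp::export]]
NumericVector pp_accuracy_cpp(int model, int p, IntegerVector kinds,
                              NumericMatrix latents, IntegerVector fs,
                              IntegerVector act, IntegerVector pl,
                              NumericVector r, IntegerMatrix idx,
                              IntegerMatrix tmap) {
  int tm[2][2];
  fill_tm(tmap, tm);
  const int S = latents.nrow(), n = idx.nrow();
  NumericVector out(n);
  std::vector<double> pv(p);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    int nt = idx(i, 1) + idx(i, 3);
    if (nt == 0) { out[i] = NA_REAL; continue; }
    std::vector<double> lat(2 * p);
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < 2 * p; ++k) lat[k] = latents(s, i * 2 * p + k);
      for (int sess = 0; sess < 2; ++sess) {
        const int start = idx(i, 2 * sess), len = idx(i, 2 * sess + 1);
        if (len == 0) continue;
        for (int j = 0; j < p; ++j) {
          double x = (sess == 0) ? lat[j] : lat[j] + lat[p + j];
          pv[j] = (kinds[j] == 0) ? R::pnorm(x, 0.0, 1.0, 1, 0)
                : (kinds[j] == 1) ? std::exp(x) : x;
        }
        double acc = 0.0;
        twostep::session_ll(model, pv.data(), fs.begin() + start,
                            act.begin() + start, pl.begin() + start,
                            r.begin() + start, len, tm, 0, &acc);
        tot += acc * len;
      }
    }
    out[i] = tot / (double(S) * nt);
  }
  return out;
}
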