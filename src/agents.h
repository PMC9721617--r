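#ifndef TWOSTEP_AGENTS_H
#define TWOSTEP_AGENTS_H

#include <cmath>

// Model codes: 1 = M1, 2 = M1_sticky, 3 = M2, 4 = M3.
// Parameter layouts (native space):
//   M1:        omega, gamma, eta
//   M1_sticky: omega, gamma, eta, rho, pi
//   M2:        omega, eta, alpha1, alpha2, lambda
//   M3:        omega, eta, alpha, lambda

namespace twostep {

struct VState {
  double qmf[2][2];
  double q2[2];
  int prev_action;  // 0-based, -1 = none
  int prev_stim;    // 0-based (2*s + a), -1 = none
  void reset() {
    qmf[0][0] = qmf[0][1] = qmf[1][0] = qmf[1][1] = 0.0;
    q2[0] = q2[1] = 0.0;
    prev_action = -1;
    prev_stim = -1;
  }
};

inline double eta_of(int model, const double* pv) {
  return (model <= 2) ? pv[2] : pv[1];
}

// Mixed action values for the two actions of first-stage state s (0-based).
// tm[s][a] is the 0-based planet reached.
inline void mixed_q(int model, const double* pv, const VState& st, int s,
                    const int tm[2][2], double q[2]) {
  const double omega = pv[0];
  for (int a = 0; a < 2; ++a) {
    q[a] = omega * st.q2[tm[s][a]] + (1.0 - omega) * st.qmf[s][a];
  }
  if (model == 2) {
    const double rho = pv[3], pi = pv[4];
    if (st.prev_action >= 0) q[st.prev_action] += rho;
    if (st.prev_stim >= 0) {
      for (int a = 0; a < 2; ++a)
        if (2 * s + a == st.prev_stim) q[a] += pi;
    }
  }
}

// log P(observed action) under the stable two-option softmax.
inline double log_softmax_choice(double eta, const double q[2], int a_obs) {
  const double z0 = eta * q[0], z1 = eta * q[1];
  const double m = (z0 > z1) ? z0 : z1;
  const double lse = m + std::log(std::exp(z0 - m) + std::exp(z1 - m));
  return eta * q[a_obs] - lse;
}

// Value update after observing (s, a, planet, r); all indices 0-based.
inline void value_update(int model, const double* pv, VState& st, int s,
                         int a, int planet, double r) {
  if (model <= 2) {
    const double keep = 1.0 - pv[1];  // 1 - gamma
    for (int ss = 0; ss < 2; ++ss)
      for (int aa = 0; aa < 2; ++aa) st.qmf[ss][aa] *= keep;
    st.qmf[s][a] = r;
    st.q2[planet] = r;  // model-based transfer to both first-stage states
  } else {
    double a1, a2, lam;
    if (model == 3) { a1 = pv[2]; a2 = pv[3]; lam = pv[4]; }
    else           { a1 = pv[2]; a2 = pv[2]; lam = pv[3]; }
    const double d1 = st.q2[planet] - st.qmf[s][a];
    st.qmf[s][a] += a1 * d1;
    const double d2 = r - st.q2[planet];
    st.q2[planet] += a2 * d2;
    st.qmf[s][a] += lam * a1 * d2;
  }
  st.prev_action = a;
  st.prev_stim = 2 * s + a;
}

// Total log-likelihood of one session; inputs are 1-based R labels.
inline double session_ll(int model, const double* pv, const int* fs,
                         const int* act, const int* pl, const double* r,
                         int n, const int tm[2][2], double* pointwise = 0,
                         double* acc = 0) {
  VState st;
  st.reset();
  const double eta = eta_of(model, pv);
  double ll = 0.0, q[2];
  double hits = 0.0;
  for (int t = 0; t < n; ++t) {
    const int s = fs[t] - 1, a = act[t] - 1, p = pl[t] - 1;
    mixed_q(model, pv, st, s, tm, q);
    const double lp = log_softmax_choice(eta, q, a);
    ll += lp;
    if (pointwise) pointwise[t] = lp;
    if (acc) {
      // modal predicted choice = argmax of choice probability; exact
      // probability ties (including eta = 0) credited 0.5
      const double za = eta * q[a], zb = eta * q[1 - a];
      if (za == zb) hits += 0.5;
      else hits += ((za > zb) ? 1.0 : 0.0);
    }
    value_update(model, pv, st, s, a, p, r[t]);
  }
  if (acc) *acc = (n > 0) ? hits / n : 0.5;
  return ll;
}

}  // namespace twostep

#endif
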