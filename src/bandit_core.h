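#ifndef BANDIT_CORE_H
#define BANDIT_CORE_H
#include <Rcpp.h>
#include <cmath>

// Shared trial-loop core: likelihood + forward-mode gradient and the
// plain latent-trace loop, used by both the exported likelihood API
// (bandit.cpp) and the NUTS sampler (nuts.cpp).

static const double PROB_FLOOR = 1e-12;

// Softmax over total values V = Qr + Qp with max-subtraction, then lapse mix.
static inline void policy_probs(const double *Qr, const double *Qp,
                                double xi, bool has_lapse,
                                double *p, double *pl) {
  double V[4], m = -INFINITY;
  for (int i = 0; i < 4; ++i) { V[i] = Qr[i] + Qp[i]; if (V[i] > m) m = V[i]; }
  double Z = 0.0;
  for (int i = 0; i < 4; ++i) { p[i] = std::exp(V[i] - m); Z += p[i]; }
  for (int i = 0; i < 4; ++i) {
    p[i] /= Z;
    pl[i] = has_lapse ? p[i] * (1.0 - xi) + xi / 4.0 : p[i];
  }
}

// Trial loop for one subject with forward-mode derivative propagation.
// Accumulates log-likelihood and its gradient wrt the six canonical
// parameters on the constrained scale. `reset` marks trials at which the
// Q-state is re-initialized (always the first trial; optionally run starts).
static double subject_loglik_grad(const double *th,
                                  const int *choice, const double *win,
                                  const double *loss, const int *reset,
                                  int n_trials, bool has_decay, bool has_lapse,
                                  double *grad) {
  const double R = th[0], P = th[1], lrr = th[2], lrp = th[3],
               d = th[4], xi = th[5];
  double Qr[4], Qp[4], dQr[4][6], dQp[4][6];
  double ll = 0.0;
  for (int k = 0; k < 6; ++k) grad[k] = 0.0;

  for (int t = 0; t < n_trials; ++t) {
    if (reset[t]) {
      for (int i = 0; i < 4; ++i) {
        Qr[i] = Qp[i] = 0.0;
        for (int k = 0; k < 6; ++k) dQr[i][k] = dQp[i][k] = 0.0;
      }
    }
    if (has_decay) {
      const double keep = 1.0 - d;
      for (int i = 0; i < 4; ++i) {
        for (int k = 0; k < 6; ++k) { dQr[i][k] *= keep; dQp[i][k] *= keep; }
        dQr[i][4] -= Qr[i];  // derivative wrt d uses pre-decay value
        dQp[i][4] -= Qp[i];
        Qr[i] *= keep; Qp[i] *= keep;
      }
    }
    double p[4], pl[4];
    policy_probs(Qr, Qp, xi, has_lapse, p, pl);
    const int c = choice[t];
    const double plc = pl[c] > PROB_FLOOR ? pl[c] : PROB_FLOOR;
    ll += std::log(plc);
    const double coef = pl[c] > PROB_FLOOR ? 1.0 / pl[c] : 0.0;
    const double lapse_keep = has_lapse ? (1.0 - xi) : 1.0;
    for (int i = 0; i < 4; ++i) {
      const double dV = coef * lapse_keep * p[c] * ((i == c ? 1.0 : 0.0) - p[i]);
      if (dV != 0.0)
        for (int k = 0; k < 6; ++k) grad[k] += dV * (dQr[i][k] + dQp[i][k]);
    }
    if (has_lapse) grad[5] += coef * (0.25 - p[c]);

    // prediction errors against the sensitivity-scaled outcome for the
    // chosen cue, then delta-rule update
    const double er = R * win[t]  - Qr[c];   // reward prediction error
    const double ep = P * loss[t] - Qp[c];   // punishment prediction error
    for (int k = 0; k < 6; ++k) dQr[c][k] *= (1.0 - lrr);
    dQr[c][0] += lrr * win[t];
    dQr[c][2] += er;
    Qr[c] += lrr * er;
    for (int k = 0; k < 6; ++k) dQp[c][k] *= (1.0 - lrp);
    dQp[c][1] += lrp * loss[t];
    dQp[c][3] += ep;
    Qp[c] += lrp * ep;
  }
  return ll;
}

// Plain trial loop (no gradients) writing per-trial log-lik; optionally the
// full latent trace. Returns total log-likelihood.
static double subject_trace(const double *th,
                            const int *choice, const double *win,
                            const double *loss, const int *reset,
                            int n_trials, bool has_decay, bool has_lapse,
                            double *ll_out,
                            double *delta_r, double *delta_p,
                            double *probs, double *qr_out, double *qp_out) {
  const double R = th[0], P = th[1], lrr = th[2], lrp = th[3],
               d = th[4], xi = th[5];
  double Qr[4], Qp[4];
  double total = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    if (reset[t]) for (int i = 0; i < 4; ++i) Qr[i] = Qp[i] = 0.0;
    if (has_decay) {
      const double keep = 1.0 - d;
      for (int i = 0; i < 4; ++i) { Qr[i] *= keep; Qp[i] *= keep; }
    }
    double p[4], pl[4];
    policy_probs(Qr, Qp, xi, has_lapse, p, pl);
    const int c = choice[t];
    const double plc = pl[c] > PROB_FLOOR ? pl[c] : PROB_FLOOR;
    const double lt = std::log(plc);
    total += lt;
    if (ll_out) ll_out[t] = lt;
    if (probs) for (int i = 0; i < 4; ++i) probs[t + (size_t)n_trials * i] = pl[i];
    if (qr_out) for (int i = 0; i < 4; ++i) {
      qr_out[t + (size_t)n_trials * i] = Qr[i];
      qp_out[t + (size_t)n_trials * i] = Qp[i];
    }
    const double dr = R * win[t]  - Qr[c];
    const double dp = P * loss[t] - Qp[c];
    if (delta_r) { delta_r[t] = dr; delta_p[t] = dp; }
    Qr[c] += lrr * dr;
    Qp[c] += lrp * dp;
  }
  return total;
}


#endif
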