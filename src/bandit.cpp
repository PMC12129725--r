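#include <Rcpp.h>
using namespace Rcpp;

// Canonical parameter order used throughout the package:
//   0: R   reward sensitivity        (scales reward prediction errors)
//   1: P   punishment sensitivity    (scales punishment prediction errors)
//   2: lr_r reward learning rate     (= alpha + beta in coupled models)
//   3: lr_p punishment learning rate (= alpha - beta in coupled models)
//   4: d   decay (forgetting) rate   (active in models 1 and 3)
//   5: xi  lapse probability         (active in models 1-4)
// Inactive parameters are passed as their neutral value (d = 0, xi = 0).

#include "bandit_core.h"

// [[Rcpp::export]]
List cpp_cohort_loglik_grad(NumericMatrix theta, IntegerVector choice,
                            NumericVector win, NumericVector loss,
                            IntegerVector subj_start, IntegerVector reset,
                            bool has_decay, bool has_lapse) {
  const int J = theta.nrow();
  NumericMatrix grad(J, 6);
  double total = 0.0;
  double th[6], g[6];
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < 6; ++k) th[k] = theta(j, k);
    const int a = subj_start[j], b = subj_start[j + 1];
    total += subject_loglik_grad(th, &choice[a], &win[a], &loss[a], &reset[a],
                                 b - a, has_decay, has_lapse, g);
    for (int k = 0; k < 6; ++k) grad(j, k) = g[k];
  }
  return List::create(_["loglik"] = total, _["grad"] = grad);
}

// [[Rcpp::export]]
List cpp_subject_trace(NumericVector theta, IntegerVector choice,
                       NumericVector win, NumericVector loss,
                       IntegerVector reset, bool has_decay, bool has_lapse) {
  const int n = choice.size();
  NumericVector ll(n), dr(n), dp(n);
  NumericMatrix probs(n, 4), qr(n, 4), qp(n, 4);
  double th[6];
  for (int k = 0; k < 6; ++k) th[k] = theta[k];
  double total = subject_trace(th, &choice[0], &win[0], &loss[0], &reset[0], n,
                               has_decay, has_lapse,
                               &ll[0], &dr[0], &dp[0],
                               &probs(0, 0), &qr(0, 0), &qp(0, 0));
  return List::create(_["loglik"] = ll, _["total"] = total,
                      _["delta_r"] = dr, _["delta_p"] = dp,
                      _["choice_probs"] = probs,
                      _["q_reward"] = qr, _["q_punish"] = qp);
}

// Pointwise log-likelihood over posterior draws: theta_draws is S x (J*6)
// with subject-major column blocks (columns 6*(j-1)+k). Output S x T_total.
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_loglik(NumericMatrix theta_draws,
                                   IntegerVector choice, NumericVector win,
                                   NumericVector loss,
                                   IntegerVector subj_start,
                                   IntegerVector reset,
                                   bool has_decay, bool has_lapse) {
  const int S = theta_draws.nrow();
  const int J = subj_start.size() - 1;
  const int T = choice.size();
  NumericMatrix out(S, T);
  double th[6];
  for (int s = 0; s < S; ++s) {
    std::vector<double> row(T);
    for (int j = 0; j < J; ++j) {
      for (int k = 0; k < 6; ++k) th[k] = theta_draws(s, 6 * j + k);
      const int a = subj_start[j], b = subj_start[j + 1];
      subject_trace(th, &choice[a], &win[a], &loss[a], &reset[a], b - a,
                    has_decay, has_lapse, &row[a],
                    nullptr, nullptr, nullptr, nullptr, nullptr);
    }
    for (int t = 0; t < T; ++t) out(s, t) = row[t];
  }
  return out;
}
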