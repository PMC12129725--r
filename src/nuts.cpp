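#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fast path for fit_bandit(): the hierarchical log posterior (non-centered,
// probit-transformed) and a No-U-Turn sampler over it, all in C++. Mirrors
// the R driver in R/hmc.R; uses R's RNG so set.seed() governs determinism.

#include "bandit_core.h"

struct HierModel {
  const int *choice; const double *win; const double *loss;
  const int *reset; const int *subj_start;
  int J, K;
  std::vector<int> act;     // 0-based indices into the canonical 6-vector
  std::vector<double> ub;   // upper bound per active parameter
  bool has_decay, has_lapse, prior_only, centered;
  double mu_sc2, sd_sc2;

  int dim() const { return 2 * K + J * K; }

  // Log posterior and gradient; returns lp. Subject block holds either
  // raw unconstrained parameters x[j,k] (centered; preferable when each
  // subject carries many trials) or standardized effects z[j,k] with
  // x = mu + sigma * z (non-centered).
  double lp_grad(const double *par, double *grad) const {
    const double *mu = par;
    const double *s = par + K;
    const double *zx = par + 2 * K;         // J x K, column-major
    std::vector<double> sigma(K);
    for (int k = 0; k < K; ++k) sigma[k] = std::exp(s[k]);

    double lp = 0.0;
    for (int i = 0; i < dim(); ++i) grad[i] = 0.0;

    double th[6], g6[6];
    std::vector<double> x(K);
    for (int j = 0; j < J; ++j) {
      for (int k = 0; k < 6; ++k) th[k] = 0.0;
      for (int k = 0; k < K; ++k) {
        x[k] = centered ? zx[k * J + j]
                        : mu[k] + sigma[k] * zx[k * J + j];
        th[act[k]] = R::pnorm(x[k], 0.0, 1.0, 1, 0) * ub[k];
      }
      if (!prior_only) {
        const int a = subj_start[j], b = subj_start[j + 1];
        lp += subject_loglik_grad(th, choice + a, win + a, loss + a,
                                  reset + a, b - a, has_decay, has_lapse,
                                  g6);
        for (int k = 0; k < K; ++k) {
          const double gx = g6[act[k]] * ub[k] *
            R::dnorm(x[k], 0.0, 1.0, 0);
          if (centered) {
            grad[2 * K + k * J + j] += gx;                // d/d x
          } else {
            grad[k] += gx;                                // d/d mu
            grad[K + k] += gx * zx[k * J + j] * sigma[k]; // d/d s
            grad[2 * K + k * J + j] += gx * sigma[k];     // d/d z
          }
        }
      }
      if (centered) {
        for (int k = 0; k < K; ++k) {
          const double r = (x[k] - mu[k]) / sigma[k];
          lp += -0.5 * r * r - s[k];
          grad[2 * K + k * J + j] += -r / sigma[k];
          grad[k] += r / sigma[k];
          grad[K + k] += r * r - 1.0;
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      lp += -0.5 * mu[k] * mu[k] / mu_sc2
            - 0.5 * sigma[k] * sigma[k] / sd_sc2 + s[k];
      grad[k] += -mu[k] / mu_sc2;
      grad[K + k] += -sigma[k] * sigma[k] / sd_sc2 + 1.0;
    }
    if (!centered) {
      for (int j = 0; j < J * K; ++j) {
        lp += -0.5 * zx[j] * zx[j];
        grad[2 * K + j] += -zx[j];
      }
    }
    return lp;
  }
};

struct State {
  std::vector<double> q, p, grad;
  double lp;
};

static bool leapfrog_cpp(const HierModel &mod, State &st, double eps,
                         const std::vector<double> &inv_mass) {
  const int d = mod.dim();
  for (int i = 0; i < d; ++i) st.p[i] += 0.5 * eps * st.grad[i];
  for (int i = 0; i < d; ++i) st.q[i] += eps * st.p[i] * inv_mass[i];
  st.lp = mod.lp_grad(st.q.data(), st.grad.data());
  if (!std::isfinite(st.lp)) return false;
  for (int i = 0; i < d; ++i) {
    if (!std::isfinite(st.grad[i])) return false;
    st.p[i] += 0.5 * eps * st.grad[i];
  }
  return true;
}

static double kinetic_cpp(const std::vector<double> &p,
                          const std::vector<double> &inv_mass) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += p[i] * p[i] * inv_mass[i];
  return 0.5 * k;
}

struct Tree {
  State minus_, plus_, prop;
  long n;
  bool s, divergent;
  double alpha;
  long n_alpha;
};

static void build_tree_cpp(const HierModel &mod, const State &from,
                           double log_u, int v, int depth, double eps,
                           const std::vector<double> &inv_mass,
                           double joint0, Tree &out) {
  if (depth == 0) {
    State st = from;
    if (!leapfrog_cpp(mod, st, v * eps, inv_mass)) {
      // keep endpoints well-defined even on a failed step
      out.minus_ = from; out.plus_ = from; out.prop = from;
      out.n = 0; out.s = false; out.divergent = true;
      out.alpha = 0.0; out.n_alpha = 1;
      return;
    }
    double joint = st.lp - kinetic_cpp(st.p, inv_mass);
    bool div = (joint0 - joint) > 1000.0;
    out.minus_ = st; out.plus_ = st; out.prop = st;
    out.n = (log_u <= joint) ? 1 : 0;
    out.s = !div;
    out.divergent = div;
    double a = joint - joint0;
    out.alpha = a > 0 ? 1.0 : std::exp(a);
    out.n_alpha = 1;
  } else {
    build_tree_cpp(mod, from, log_u, v, depth - 1, eps, inv_mass, joint0,
                   out);
    if (!out.s) return;
    Tree t2;
    if (v == -1) {
      build_tree_cpp(mod, out.minus_, log_u, v, depth - 1, eps, inv_mass,
                     joint0, t2);
      if (t2.s) out.minus_ = t2.minus_;
    } else {
      build_tree_cpp(mod, out.plus_, log_u, v, depth - 1, eps, inv_mass,
                     joint0, t2);
      if (t2.s) out.plus_ = t2.plus_;
    }
    if (t2.s && t2.n > 0 &&
        unif_rand() < (double)t2.n / std::max(out.n + t2.n, 1L))
      out.prop = t2.prop;
    out.n += t2.n;
    out.alpha += t2.alpha;
    out.n_alpha += t2.n_alpha;
    out.divergent = out.divergent || t2.divergent;
    if (!t2.s) { out.s = false; return; }
    double dot_m = 0.0, dot_p = 0.0;
    const int d = mod.dim();
    for (int i = 0; i < d; ++i) {
      double dq = out.plus_.q[i] - out.minus_.q[i];
      dot_m += dq * out.minus_.p[i] * inv_mass[i];
      dot_p += dq * out.plus_.p[i] * inv_mass[i];
    }
    out.s = (dot_m >= 0.0) && (dot_p >= 0.0);
  }
}

struct DualAvg {
  double mu, log_eps_bar, H_bar, eps, eps_bar;
  long m;
  void init(double eps0) {
    mu = std::log(10.0 * eps0);
    log_eps_bar = std::log(eps0);
    H_bar = 0.0; m = 0; eps = eps0; eps_bar = eps0;
  }
  void update(double h) {
    m += 1;
    double frac = 1.0 / (m + 10.0);
    H_bar = (1.0 - frac) * H_bar + frac * h;
    double log_eps = mu - std::sqrt((double)m) / 0.05 * H_bar;
    double w = std::pow((double)m, -0.75);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
    eps = std::exp(log_eps);
    eps_bar = std::exp(log_eps_bar);
  }
};

static double find_step_cpp(const HierModel &mod, const State &cur,
                            double eps, const std::vector<double> &inv_mass) {
  const int d = mod.dim();
  State st = cur;
  st.p.resize(d);
  for (int i = 0; i < d; ++i) st.p[i] = norm_rand() / std::sqrt(inv_mass[i]);
  const State st0 = st;
  double H0 = -st.lp + kinetic_cpp(st.p, inv_mass);
  auto attempt = [&](double e) -> double {
    State s2 = st0;
    if (!leapfrog_cpp(mod, s2, e, inv_mass)) return -INFINITY;
    return -(-s2.lp + kinetic_cpp(s2.p, inv_mass)) + H0;
  };
  double a = attempt(eps);
  int dir = (std::isfinite(a) && a > std::log(0.5)) ? 1 : -1;
  for (int i = 0; i < 20; ++i) {
    double eps2 = eps * std::pow(2.0, dir);
    double a2 = attempt(eps2);
    bool ok = std::isfinite(a2) && a2 > std::log(0.5);
    if ((dir == 1 && !ok) || (dir == -1 && ok)) break;
    eps = eps2;
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_nuts_chain(NumericVector init, IntegerVector choice,
                    NumericVector win, NumericVector loss,
                    IntegerVector subj_start, IntegerVector reset,
                    IntegerVector act0, NumericVector ub,
                    bool has_decay, bool has_lapse, bool prior_only,
                    bool centered, double mu_scale, double sd_scale,
                    int warmup, int iter, double target_accept,
                    int max_depth, NumericVector inv_mass0,
                    IntegerVector win_ends_in, double min_step) {
  RNGScope rng;
  HierModel mod;
  mod.choice = &choice[0]; mod.win = &win[0]; mod.loss = &loss[0];
  mod.reset = &reset[0]; mod.subj_start = &subj_start[0];
  mod.J = subj_start.size() - 1;
  mod.K = act0.size();
  mod.act.assign(act0.begin(), act0.end());
  mod.ub.assign(ub.begin(), ub.end());
  mod.has_decay = has_decay; mod.has_lapse = has_lapse;
  mod.prior_only = prior_only; mod.centered = centered;
  mod.mu_sc2 = mu_scale * mu_scale;
  mod.sd_sc2 = sd_scale * sd_scale;

  const int d = mod.dim();
  if (init.size() != d) stop("init has wrong length");
  State cur;
  cur.q.assign(init.begin(), init.end());
  cur.p.assign(d, 0.0);
  cur.grad.assign(d, 0.0);
  cur.lp = mod.lp_grad(cur.q.data(), cur.grad.data());
  if (!std::isfinite(cur.lp)) stop("non-finite log posterior at init");

  std::vector<double> inv_mass(inv_mass0.begin(), inv_mass0.end());
  double eps = find_step_cpp(mod, cur, 0.1, inv_mass);
  DualAvg da; da.init(eps);

  std::vector<int> win_ends(win_ends_in.begin(), win_ends_in.end());
  size_t win_idx = 0;
  std::vector<std::vector<double>> win_buf;

  NumericMatrix draws(iter, d);
  NumericVector lps(iter);
  int div_sampling = 0;
  double accept_sum = 0.0;
  double depth_sum = 0.0;

  for (int m = 1; m <= warmup + iter; ++m) {
    for (int i = 0; i < d; ++i)
      cur.p[i] = norm_rand() / std::sqrt(inv_mass[i]);
    double joint0 = cur.lp - kinetic_cpp(cur.p, inv_mass);
    double log_u = joint0 - exp_rand();

    State minus_ = cur, plus_ = cur;
    State prop = cur;
    long n = 1;
    bool s = true, divergent = false;
    int depth = 0;
    double alpha = 0.0;
    long n_alpha = 0;
    Tree sub;
    while (s && depth < max_depth) {
      int v = (unif_rand() < 0.5) ? -1 : 1;
      if (v == -1) {
        build_tree_cpp(mod, minus_, log_u, v, depth, eps, inv_mass, joint0,
                       sub);
        if (sub.s || sub.n > 0) minus_ = sub.minus_;
      } else {
        build_tree_cpp(mod, plus_, log_u, v, depth, eps, inv_mass, joint0,
                       sub);
        if (sub.s || sub.n > 0) plus_ = sub.plus_;
      }
      alpha += sub.alpha;
      n_alpha += sub.n_alpha;
      divergent = divergent || sub.divergent;
      if (sub.s) {
        if (sub.n > 0 && unif_rand() < (double)sub.n / n) prop = sub.prop;
        n += sub.n;
        double dot_m = 0.0, dot_p = 0.0;
        for (int i = 0; i < d; ++i) {
          double dq = plus_.q[i] - minus_.q[i];
          dot_m += dq * minus_.p[i] * inv_mass[i];
          dot_p += dq * plus_.p[i] * inv_mass[i];
        }
        s = (dot_m >= 0.0) && (dot_p >= 0.0);
      } else s = false;
      ++depth;
    }
    cur.q = prop.q; cur.grad = prop.grad; cur.lp = prop.lp;
    double a_stat = n_alpha > 0 ? alpha / n_alpha : 0.0;

    if (m <= warmup) {
      da.update(target_accept - a_stat);
      // floor prevents the step-size death spiral against likelihood
      // cliffs: oversized steps only cost rejected (divergent) subtrees
      eps = std::max(da.eps, min_step);
      if (win_idx < win_ends.size()) {
        win_buf.push_back(cur.q);
        if (m == win_ends[win_idx]) {
          if (win_buf.size() >= 10) {
            size_t nw = win_buf.size();
            for (int i = 0; i < d; ++i) {
              double mean = 0.0;
              for (size_t r = 0; r < nw; ++r) mean += win_buf[r][i];
              mean /= nw;
              double v2 = 0.0;
              for (size_t r = 0; r < nw; ++r) {
                double dv = win_buf[r][i] - mean;
                v2 += dv * dv;
              }
              v2 /= (nw - 1);
              double est = (v2 * nw + 1e-3 * 5.0) / (nw + 5.0);
              inv_mass[i] = std::max(est, 0.05 * inv_mass[i]);
            }
            // restart dual averaging around the current step size; a
            // fresh probe here can crater eps if q sits near a cliff
            da.init(eps);
          }
          win_buf.clear();
          ++win_idx;
        }
      }
      if (m == warmup) eps = std::max(da.eps_bar, min_step);
    } else {
      int r = m - warmup - 1;
      for (int i = 0; i < d; ++i) draws(r, i) = cur.q[i];
      lps[r] = cur.lp;
      if (divergent) ++div_sampling;
      accept_sum += a_stat;
      depth_sum += depth;
    }
  }
  return List::create(_["draws"] = draws, _["lp"] = lps,
                      _["divergences"] = div_sampling,
                      _["accept_rate"] = accept_sum / iter,
                      _["step_size"] = eps,
                      _["mean_tree_depth"] = depth_sum / iter);
}
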