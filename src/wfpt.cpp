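// Wiener first-passage-time (WFPT) density wrappers and a discretised
// simulator. The density of (choice, rt) for a unit-variance Wiener process
// with drift v between absorbing boundaries 0 and a, started at beta * a,
// is evaluated by the series kernel in wfpt_density.h. Time is in seconds;
// the diffusion coefficient is fixed at 1.

#include <Rcpp.h>
#include "wfpt_density.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".wfpt_log_density_cpp")]]
NumericVector wfpt_log_density_cpp(NumericVector rt, IntegerVector upper,
                                   NumericVector v, NumericVector a,
                                   NumericVector tau, NumericVector beta) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = dlens::wfpt_logd(rt[i], upper[i],
                              v[i % v.size()], a[i % a.size()],
                              tau[i % tau.size()], beta[i % beta.size()]);
  }
  return out;
}

// One Euler step with Brownian-bridge boundary-crossing correction:
// even when both endpoints stay inside (0, a), the continuous path may have
// touched a boundary within the step; accepting those crossings with the
// bridge probabilities exp(-2(a-x0)(a-x1)/dt) and exp(-2 x0 x1 / dt)
// removes the leading O(sqrt(dt)) discretisation bias of the naive scheme.
// Returns -1 (no absorption), 0 (lower) or 1 (upper), updating x.
static inline int euler_step(double &x, double v, double a,
                             double dt, double sdt) {
  double x0 = x;
  x += v * dt + sdt * norm_rand();
  if (x >= a) return 1;
  if (x <= 0.0) return 0;
  double p_up = std::exp(-2.0 * (a - x0) * (a - x) / dt);
  double p_lo = std::exp(-2.0 * x0 * x / dt);
  if (p_up + p_lo > 1e-12) {
    double u = unif_rand();
    if (u < p_up) return 1;
    if (u < p_up + p_lo) return 0;
  }
  return -1;
}

// Euler-Maruyama first-passage simulator. Returns a 2-column matrix:
// column 1 choice (1 = upper boundary), column 2 rt in seconds.
// [[Rcpp::export(name = ".wfpt_simulate_cpp")]]
NumericMatrix wfpt_simulate_cpp(int n, double v, double a, double tau,
                                double beta, double dt, double max_time) {
  NumericMatrix out(n, 2);
  double sdt = std::sqrt(dt);
  int max_steps = (int)(max_time / dt);
  for (int i = 0; i < n; ++i) {
    double x = beta * a;
    int step = 0;
    int choice;
    while (true) {
      choice = euler_step(x, v, a, dt, sdt);
      ++step;
      if (choice >= 0) break;
      if (step >= max_steps) { choice = (x >= a / 2.0) ? 1 : 0; break; }
    }
    out(i, 0) = choice;
    out(i, 1) = tau + step * dt;
  }
  return out;
}

// Simulate one session: per-trial Wiener parameters are supplied as vectors.
// [[Rcpp::export(name = ".simulate_session_cpp")]]
NumericMatrix simulate_session_cpp(NumericVector v, NumericVector a,
                                   NumericVector tau, double beta,
                                   double dt, double max_time) {
  int T = v.size();
  NumericMatrix out(T, 2);
  double sdt = std::sqrt(dt);
  int max_steps = (int)(max_time / dt);
  for (int t = 0; t < T; ++t) {
    double x = beta * a[t];
    int step = 0;
    int choice;
    while (true) {
      choice = euler_step(x, v[t], a[t], dt, sdt);
      ++step;
      if (choice >= 0) break;
      if (step >= max_steps) { choice = (x >= a[t] / 2.0) ? 1 : 0; break; }
    }
    out(t, 0) = choice;
    out(t, 1) = tau[t] + step * dt;
  }
  return out;
}
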