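// Bootstrap particle filter for the two-level diffusion model.
//
// Latent state per trial: (b_v, a, tau0). Transitions are independent Gaussian
// random walks; a and tau0 are kept inside their supports by reflection at
// a_min / tau0_min. Observation density is the WFPT density with
// v_t = v0 + b_v,t * validity_t and tau_t = tau0_t + b_tau * n_cues,t.
// Resampling is systematic, triggered when ESS < N/2. The log marginal
// likelihood estimate is exact (no Monte Carlo variability) when all walk
// scales are zero and the initial distribution is degenerate.

#include <Rcpp.h>
#include "wfpt_density.h"
#include <algorithm>
#include <numeric>
using namespace Rcpp;

static inline double reflect_lower(double x, double lo) {
  double y = x;
  // two passes are enough for any realistic innovation scale
  for (int i = 0; i < 50 && y < lo; ++i) y = 2.0 * lo - y;
  return y;
}

// truncated-normal draw (lower bound), rejection with reflection fallback
static double rtnorm_lower(double mu, double sd, double lo) {
  if (sd <= 0.0) return std::max(mu, lo);
  for (int i = 0; i < 100; ++i) {
    double x = mu + sd * norm_rand();
    if (x >= lo) return x;
  }
  return reflect_lower(mu + sd * norm_rand(), lo);
}

// weighted quantile on a copy (sorts by value, accumulates weights)
static double wquantile(std::vector<double> x, std::vector<double> w, double p) {
  int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int i, int j) { return x[i] < x[j]; });
  double cum = 0.0;
  for (int k = 0; k < n; ++k) {
    cum += w[idx[k]];
    if (cum >= p) return x[idx[k]];
  }
  return x[idx[n - 1]];
}

// [[Rcpp::export(name = ".particle_filter_cpp")]]
List particle_filter_cpp(NumericVector validity, IntegerVector ncues,
                         IntegerVector upper, NumericVector rt,
                         double v0, double b_tau, double beta,
                         double sigma_v, double sigma_a, double sigma_tau,
                         NumericVector init_mu, NumericVector init_sd,
                         double a_min, double tau0_min,
                         int n_particles, bool summaries) {
  int T = rt.size();
  int N = n_particles;

  std::vector<double> bv(N), aa(N), t0(N), W(N, 1.0 / N), lw(N), u(N);
  // state history + ancestry for the sampled backward path
  std::vector<double> h_bv((size_t)T * N), h_aa((size_t)T * N), h_t0((size_t)T * N);
  std::vector<int> anc((size_t)T * N);

  for (int i = 0; i < N; ++i) {
    bv[i] = init_sd[0] > 0.0 ? init_mu[0] + init_sd[0] * norm_rand() : init_mu[0];
    aa[i] = rtnorm_lower(init_mu[1], init_sd[1], a_min);
    t0[i] = rtnorm_lower(init_mu[2], init_sd[2], tau0_min);
  }

  double loglik = 0.0;
  bool degenerate = false;
  NumericVector ess_out(T);
  NumericMatrix fmean, fq05, fmed, fq95;
  if (summaries) {
    fmean = NumericMatrix(T, 3);
    fq05 = NumericMatrix(T, 3);
    fmed = NumericMatrix(T, 3);
    fq95 = NumericMatrix(T, 3);
  }

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      for (int i = 0; i < N; ++i) {
        if (sigma_v > 0.0) bv[i] += sigma_v * norm_rand();
        if (sigma_a > 0.0) aa[i] = reflect_lower(aa[i] + sigma_a * norm_rand(), a_min);
        if (sigma_tau > 0.0) t0[i] = reflect_lower(t0[i] + sigma_tau * norm_rand(), tau0_min);
      }
    }
    for (int i = 0; i < N; ++i) {
      h_bv[(size_t)t * N + i] = bv[i];
      h_aa[(size_t)t * N + i] = aa[i];
      h_t0[(size_t)t * N + i] = t0[i];
    }

    double m = -HUGE_VAL;
    for (int i = 0; i < N; ++i) {
      double v = v0 + bv[i] * validity[t];
      double tau = t0[i] + b_tau * ncues[t];
      lw[i] = dlens::wfpt_logd(rt[t], upper[t], v, aa[i], tau, beta);
      if (lw[i] > m) m = lw[i];
    }

    if (m <= dlens::LOG_FLOOR) {
      // total weight collapse: flag, charge the floor, keep weights as-is
      degenerate = true;
      loglik += dlens::LOG_FLOOR;
      ess_out[t] = 1.0 / std::inner_product(W.begin(), W.end(), W.begin(), 0.0);
      for (int i = 0; i < N; ++i) anc[(size_t)t * N + i] = i;
    } else {
      double S = 0.0;
      for (int i = 0; i < N; ++i) {
        u[i] = W[i] * std::exp(lw[i] - m);
        S += u[i];
      }
      loglik += m + std::log(S);
      double sq = 0.0;
      for (int i = 0; i < N; ++i) {
        W[i] = u[i] / S;
        sq += W[i] * W[i];
      }
      double ess = 1.0 / sq;
      ess_out[t] = ess;

      if (summaries) {
        double mb = 0.0, ma = 0.0, mt = 0.0;
        for (int i = 0; i < N; ++i) {
          mb += W[i] * bv[i]; ma += W[i] * aa[i]; mt += W[i] * t0[i];
        }
        fmean(t, 0) = mb; fmean(t, 1) = ma; fmean(t, 2) = mt;
        fq05(t, 0) = wquantile(bv, W, 0.05);
        fq05(t, 1) = wquantile(aa, W, 0.05);
        fq05(t, 2) = wquantile(t0, W, 0.05);
        fmed(t, 0) = wquantile(bv, W, 0.5);
        fmed(t, 1) = wquantile(aa, W, 0.5);
        fmed(t, 2) = wquantile(t0, W, 0.5);
        fq95(t, 0) = wquantile(bv, W, 0.95);
        fq95(t, 1) = wquantile(aa, W, 0.95);
        fq95(t, 2) = wquantile(t0, W, 0.95);
      }

      if (ess < N / 2.0) {
        // systematic resampling
        std::vector<double> nbv(N), naa(N), nt0(N);
        double u0 = unif_rand() / N;
        double cum = W[0];
        int j = 0;
        for (int i = 0; i < N; ++i) {
          double target = u0 + (double)i / N;
          while (cum < target && j < N - 1) { ++j; cum += W[j]; }
          nbv[i] = bv[j]; naa[i] = aa[j]; nt0[i] = t0[j];
          anc[(size_t)t * N + i] = j;
        }
        bv = nbv; aa = naa; t0 = nt0;
        std::fill(W.begin(), W.end(), 1.0 / N);
      } else {
        for (int i = 0; i < N; ++i) anc[(size_t)t * N + i] = i;
      }
    }
  }

  // sample one ancestral path from the final weights
  NumericMatrix path(T, 3);
  {
    double uu = unif_rand();
    double cum = 0.0;
    int j = N - 1;
    for (int i = 0; i < N; ++i) {
      cum += W[i];
      if (cum >= uu) { j = i; break; }
    }
    for (int t = T - 1; t >= 0; --t) {
      j = anc[(size_t)t * N + j];
      path(t, 0) = h_bv[(size_t)t * N + j];
      path(t, 1) = h_aa[(size_t)t * N + j];
      path(t, 2) = h_t0[(size_t)t * N + j];
    }
  }

  List out = List::create(
    _["loglik"] = loglik,
    _["ess"] = ess_out,
    _["degenerate"] = degenerate,
    _["path"] = path);
  if (summaries) {
    out["filtered_mean"] = fmean;
    out["filtered_q05"] = fq05;
    out["filtered_median"] = fmed;
    out["filtered_q95"] = fq95;
  }
  return out;
}
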