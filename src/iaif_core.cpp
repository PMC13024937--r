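#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-style RNG: splitmix64 keyed by (seed, plan index, step index).
// Every (plan, step) Monte-Carlo block owns an independent, replayable
// stream, so re-scoring the remainder of a plan with the planning-time seed
// reproduces the planning-time draws bit-exactly.
// ---------------------------------------------------------------------------

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1): 53-bit mantissa shifted off zero
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // standard normal via Box-Muller (cosine branch only; platform-stable)
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

static uint64_t stream_key(double seed, int plan, int step) {
  uint64_t k = static_cast<uint64_t>(seed);
  k ^= 0x9E3779B97F4A7C15ULL + (static_cast<uint64_t>(plan + 1) << 32);
  k ^= 0xBF58476D1CE4E5B9ULL * static_cast<uint64_t>(step + 1);
  // one mixing round to decorrelate nearby keys
  SplitMix m(k);
  return m.next();
}

// ---------------------------------------------------------------------------
// Unscented transform of the cursor block (position, velocity) through the
// damped second-order lag, with the damping parameter appended as a third,
// uncertain sigma dimension.  Euler step:
//   pos' = pos + dt * vel;  vel' = vel + dt * (-d * vel + a)
// ---------------------------------------------------------------------------

struct UkfOut {
  double m0, m1;         // predicted mean
  double p00, p01, p11;  // predicted covariance (symmetric)
};

static UkfOut ukf_cursor_step(double m0, double m1,
                              double p00, double p01, double p11,
                              double a, double dt,
                              double d_mean, double d_var,
                              double alpha, double beta, double kappa) {
  const int n = 3;
  double lambda = alpha * alpha * (n + kappa) - n;
  double c = n + lambda;
  if (c <= 0) stop("invalid sigma-point scaling (n + lambda <= 0)");
  double s = std::sqrt(c);

  // Cholesky of blockdiag([[p00,p01],[p01,p11]], d_var), robust to zero rows
  double l00 = p00 > 0 ? std::sqrt(p00) : 0.0;
  double l10 = l00 > 0 ? p01 / l00 : 0.0;
  double l11s = p11 - l10 * l10;
  double l11 = l11s > 0 ? std::sqrt(l11s) : 0.0;
  double l22 = d_var > 0 ? std::sqrt(d_var) : 0.0;

  double X[7][3];  // sigma points (pos, vel, d)
  X[0][0] = m0; X[0][1] = m1; X[0][2] = d_mean;
  // columns of L scaled by s
  double cols[3][3] = { { l00, l10, 0.0 }, { 0.0, l11, 0.0 }, { 0.0, 0.0, l22 } };
  for (int i = 0; i < 3; ++i) {
    for (int k = 0; k < 3; ++k) {
      X[1 + i][k]     = X[0][k] + s * cols[i][k];
      X[4 + i][k]     = X[0][k] - s * cols[i][k];
    }
  }

  double wm0 = lambda / c, wmi = 1.0 / (2.0 * c);
  double wc0 = wm0 + (1.0 - alpha * alpha + beta);

  double Y[7][2];
  for (int i = 0; i < 7; ++i) {
    double pos = X[i][0], vel = X[i][1], d = X[i][2];
    Y[i][0] = pos + dt * vel;
    Y[i][1] = vel + dt * (-d * vel + a);
  }

  UkfOut out;
  out.m0 = wm0 * Y[0][0]; out.m1 = wm0 * Y[0][1];
  for (int i = 1; i < 7; ++i) { out.m0 += wmi * Y[i][0]; out.m1 += wmi * Y[i][1]; }

  double q00 = 0, q01 = 0, q11 = 0;
  for (int i = 0; i < 7; ++i) {
    double w = (i == 0) ? wc0 : wmi;
    double d0 = Y[i][0] - out.m0, d1 = Y[i][1] - out.m1;
    q00 += w * d0 * d0; q01 += w * d0 * d1; q11 += w * d1 * d1;
  }
  out.p00 = q00; out.p01 = q01; out.p11 = q11;
  return out;
}

// [[Rcpp::export(name = ".cpp_ukf_cursor")]]
NumericVector cpp_ukf_cursor(NumericVector mean, NumericVector cov,
                             double action, double dt,
                             double d_mean, double d_var,
                             double alpha, double beta, double kappa) {
  UkfOut o = ukf_cursor_step(mean[0], mean[1], cov[0], cov[1], cov[2],
                             action, dt, d_mean, d_var, alpha, beta, kappa);
  return NumericVector::create(o.m0, o.m1, o.p00, o.p01, o.p11);
}

// [[Rcpp::export(name = ".cpp_rollout_cursor")]]
NumericMatrix cpp_rollout_cursor(NumericVector mean, NumericVector cov,
                                 NumericVector actions, double dt,
                                 double d_mean, double d_var,
                                 double alpha, double beta, double kappa) {
  int N = actions.size();
  NumericMatrix out(N, 5);  // m0 m1 p00 p01 p11 per step
  double m0 = mean[0], m1 = mean[1], p00 = cov[0], p01 = cov[1], p11 = cov[2];
  for (int i = 0; i < N; ++i) {
    UkfOut o = ukf_cursor_step(m0, m1, p00, p01, p11, actions[i], dt,
                               d_mean, d_var, alpha, beta, kappa);
    m0 = o.m0; m1 = o.m1; p00 = o.p00; p01 = o.p01; p11 = o.p11;
    out(i, 0) = m0; out(i, 1) = m1; out(i, 2) = p00; out(i, 3) = p01; out(i, 4) = p11;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo pragmatic value of a predicted belief: draw hidden states from
// the (mean-field) belief, emit observations, score them under the factorised
// preference (Gaussian over the cursor-position channel around the believed
// target centre, Bernoulli over the in-target flag).
// ---------------------------------------------------------------------------

static double pragmatic_mc(double cm0, double cp00,
                           double tp_m, double tp_v, double tw_m, double tw_v,
                           double obs_var_cursor,
                           double pref_center, double pref_var,
                           double log_p_in, double log_p_out, double log_floor,
                           int m, SplitMix &rng) {
  double sd_s1 = cp00 > 0 ? std::sqrt(cp00) : 0.0;
  double sd_s3 = tp_v > 0 ? std::sqrt(tp_v) : 0.0;
  double sd_s4 = tw_v > 0 ? std::sqrt(tw_v) : 0.0;
  double sd_o1 = obs_var_cursor > 0 ? std::sqrt(obs_var_cursor) : 0.0;
  double lc = -0.5 * std::log(2.0 * M_PI * pref_var);
  double acc = 0.0;
  for (int q = 0; q < m; ++q) {
    double s1 = cm0 + sd_s1 * rng.norm();
    double s3 = tp_m + sd_s3 * rng.norm();
    double s4 = tw_m + sd_s4 * rng.norm();
    double o1 = s1 + sd_o1 * rng.norm();
    bool inside = std::fabs(s1 - s3) <= s4;
    double dz = o1 - pref_center;
    double lp = (inside ? log_p_in : log_p_out) + lc - 0.5 * dz * dz / pref_var;
    if (lp < log_floor) lp = log_floor;
    acc += lp;
  }
  return -acc / m;  // pragmatic value: negative expected log-preference
}

// Evaluate K plans: roll each out through the UKF and score step-wise EFE
// (information gain excluded; pragmatic value only).  step_offset shifts the
// per-step stream key so truncated re-scoring can replay planning streams.
// [[Rcpp::export(name = ".cpp_eval_plans")]]
List cpp_eval_plans(NumericMatrix plans,            // K x N actions
                    NumericVector cursor_mean, NumericVector cursor_cov,
                    double tp_m, double tp_v, double tw_m, double tw_v,
                    double dt, double d_mean, double d_var,
                    double alpha, double beta, double kappa,
                    double obs_var_cursor,
                    double pref_center, double pref_var,
                    double log_p_in, double log_p_out, double log_floor,
                    int m, double seed, int step_offset, int plan_offset) {
  int K = plans.nrow(), N = plans.ncol();
  NumericMatrix efe(K, N);
  for (int j = 0; j < K; ++j) {
    double m0 = cursor_mean[0], m1 = cursor_mean[1];
    double p00 = cursor_cov[0], p01 = cursor_cov[1], p11 = cursor_cov[2];
    for (int i = 0; i < N; ++i) {
      UkfOut o = ukf_cursor_step(m0, m1, p00, p01, p11, plans(j, i), dt,
                                 d_mean, d_var, alpha, beta, kappa);
      m0 = o.m0; m1 = o.m1; p00 = o.p00; p01 = o.p01; p11 = o.p11;
      SplitMix rng(stream_key(seed, j + plan_offset, i + step_offset));
      efe(j, i) = pragmatic_mc(m0, p00, tp_m, tp_v, tw_m, tw_v,
                               obs_var_cursor, pref_center, pref_var,
                               log_p_in, log_p_out, log_floor, m, rng);
    }
  }
  NumericVector mean_efe(K);
  for (int j = 0; j < K; ++j) {
    double s = 0; for (int i = 0; i < N; ++i) s += efe(j, i);
    mean_efe[j] = s / N;
  }
  return List::create(_["stepwise"] = efe, _["mean"] = mean_efe);
}
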