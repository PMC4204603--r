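#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simplified f-I curve; series fill at the removable singularity.
static inline double h_rate(double x, double a, double b, double d) {
  double y = a * x - b;
  double u = d * y;
  if (std::fabs(u) < 1e-6) return (1.0 + 0.5 * u + u * u / 12.0) / d;
  return y / (1.0 - std::exp(-u));
}

// Euler-Maruyama integration of one decision trial.
//
// Time in ms, currents in nA, rates in Hz. The gating drift uses
// dS/dt = -S/tau_S + (1-S) * gamma * H(x) * 1e-3 (H in Hz -> per ms).
// Noise currents are OU processes initialised at their stationary law.
// Uses R's RNG: seed with set.seed() before the call.
//
// Returns choice (0 undecided / 1 target / 2 distractor), decision time
// (ms from stimulus onset, NA if undecided), baseline rate (mean over the
// last 1000 ms of the pre-stimulus epoch, pooled over populations), the
// gating state at stimulus onset, and optionally per-bin max-rate
// envelopes (whole trial) and per-bin mean-rate traces.
// [[Rcpp::export]]
List sim_trial_cpp(List par, double I0, double sigma, double coh,
                   double dt, double t_prestim, double t_stim,
                   double theta, int sustain,
                   double env_bin, double trace_bin,
                   bool keep_env, bool keep_traces, bool stop_at_choice,
                   double S1_init, double S2_init) {
  const double a = par["a"], b = par["b"], d = par["d"];
  const double gamma = par["gamma"], tauS = par["tau_S"],
               tauN = par["tau_noise"];
  const double Js = par["J_self"], Jc = par["J_cross"], Jx = par["J_ext"];
  const double mu0 = par["mu0"];

  const int n_pre  = (int) std::lround(t_prestim / dt);
  const int n_stim = (int) std::lround(t_stim / dt);
  const int n_tot  = n_pre + n_stim;
  const double stim1 = Jx * mu0 * (1.0 + coh / 100.0);
  const double stim2 = Jx * mu0 * (1.0 - coh / 100.0);
  const double noise_amp = sigma * std::sqrt(2.0 * dt / tauN);

  const int steps_per_env   = keep_env ? (int) std::lround(env_bin / dt) : 0;
  const int steps_per_trace = keep_traces ? (int) std::lround(trace_bin / dt) : 0;
  const int n_env   = keep_env ? n_tot / steps_per_env : 0;
  const int n_trace = keep_traces ? n_tot / steps_per_trace : 0;

  NumericVector env1(n_env), env2(n_env), tr1(n_trace), tr2(n_trace);
  if (keep_env) { env1.fill(R_NegInf); env2.fill(R_NegInf); }

  // circular buffers for the sustained (windowed-min) rate
  const int kwin = std::max(sustain, 1);
  std::vector<double> buf1(kwin, 0.0), buf2(kwin, 0.0);

  double S1 = S1_init, S2 = S2_init;
  double In1 = sigma * norm_rand(), In2 = sigma * norm_rand();

  const int base_from = n_pre - (int) std::lround(1000.0 / dt);
  double base_sum = 0.0; int base_n = 0;

  int choice = 0, run1 = 0, run2 = 0;
  double dtime = NA_REAL;
  double S1_onset = NA_REAL, S2_onset = NA_REAL;

  for (int k = 0; k < n_tot; ++k) {
    const bool on = k >= n_pre;
    if (k == n_pre) { S1_onset = S1; S2_onset = S2; }

    const double x1 = Js * S1 - Jc * S2 + I0 + (on ? stim1 : 0.0) + In1;
    const double x2 = Js * S2 - Jc * S1 + I0 + (on ? stim2 : 0.0) + In2;
    const double r1 = h_rate(x1, a, b, d);
    const double r2 = h_rate(x2, a, b, d);

    if (!std::isfinite(r1) || !std::isfinite(r2))
      stop("non-finite firing rate at step %d: numerical blow-up", k);

    if (k >= base_from && k < n_pre) { base_sum += 0.5 * (r1 + r2); ++base_n; }

    if (keep_env) {
      // envelope of the sustained rate: min over the trailing detection
      // window, so threshold re-detection reproduces the sustained rule
      buf1[k % kwin] = r1; buf2[k % kwin] = r2;
      const int nfill = std::min(k + 1, kwin);
      double m1 = buf1[0], m2 = buf2[0];
      for (int j = 1; j < nfill; ++j) {
        if (buf1[j] < m1) m1 = buf1[j];
        if (buf2[j] < m2) m2 = buf2[j];
      }
      const int ib = k / steps_per_env;
      if (m1 > env1[ib]) env1[ib] = m1;
      if (m2 > env2[ib]) env2[ib] = m2;
    }
    if (keep_traces) {
      const int ib = k / steps_per_trace;
      tr1[ib] += r1; tr2[ib] += r2;
    }

    if (on && choice == 0) {
      run1 = (r1 >= theta) ? run1 + 1 : 0;
      run2 = (r2 >= theta) ? run2 + 1 : 0;
      if (run1 >= sustain || run2 >= sustain) {
        // timestamp the first step of the sustained crossing
        dtime = (k - n_pre - (sustain - 1)) * dt + dt;
        choice = (run1 >= sustain) ? 1 : 2;
        if (run1 >= sustain && run2 >= sustain) choice = (r1 >= r2) ? 1 : 2;
        if (stop_at_choice && !keep_env && !keep_traces) break;
      }
    }

    // Euler step; clip S to its invariant interval [0,1]
    const double f1 = -S1 / tauS + (1.0 - S1) * gamma * r1 * 1e-3;
    const double f2 = -S2 / tauS + (1.0 - S2) * gamma * r2 * 1e-3;
    S1 += dt * f1; S2 += dt * f2;
    if (S1 < 0.0) S1 = 0.0; else if (S1 > 1.0) S1 = 1.0;
    if (S2 < 0.0) S2 = 0.0; else if (S2 > 1.0) S2 = 1.0;

    In1 += dt * (-In1 / tauN) + noise_amp * norm_rand();
    In2 += dt * (-In2 / tauN) + noise_amp * norm_rand();
  }

  if (keep_traces) {
    for (int i = 0; i < n_trace; ++i) {
      tr1[i] /= steps_per_trace; tr2[i] /= steps_per_trace;
    }
  }

  return List::create(
    _["choice"] = choice,
    _["decision_time"] = dtime,
    _["baseline_rate"] = base_sum / std::max(base_n, 1),
    _["S_onset"] = NumericVector::create(S1_onset, S2_onset),
    _["env_target"] = keep_env ? env1 : NumericVector(0),
    _["env_distractor"] = keep_env ? env2 : NumericVector(0),
    _["trace_target"] = keep_traces ? tr1 : NumericVector(0),
    _["trace_distractor"] = keep_traces ? tr2 : NumericVector(0));
}
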