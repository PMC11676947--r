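#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cell parameter vector layout (shared with R/cell-params.R, keep in sync):
// 0 cm, 1 gL, 2 EL, 3 Vt, 4 Delta, 5 a, 6 b, 7 tau_w,
// 8 Qe, 9 Qi, 10 tau_e, 11 tau_i, 12 Ee, 13 Ei,
// 14 V_spike, 15 V_reset, 16 t_refrac
enum ParIdx { CM, GL, ELp, VT, DELTA, Aa, Bb, TAUW, QE, QI, TAUE, TAUI,
              EE, EI, VSPIKE, VRESET, TREFRAC };

// One forward-Euler AdEx update. v/w/Ge/Gi/refrac are updated in place.
// Returns true if the cell spiked this step.
static inline bool adex_update(const double* p, double dt,
                               double& v, double& w, double& Ge, double& Gi,
                               double& refrac, int n_exc, int n_inh,
                               double I_ext, double decay_e, double decay_i) {
  Ge = Ge * decay_e + p[QE] * n_exc;
  Gi = Gi * decay_i + p[QI] * n_inh;
  if (refrac > 0.0) {
    // voltage clamped at reset; adaptation and conductances keep evolving
    w += dt * ((p[Aa] * (v - p[ELp]) - w) / p[TAUW]);
    refrac -= dt;
    return false;
  }
  double Isyn = Ge * (p[EE] - v) + Gi * (p[EI] - v);
  double veff = v < p[VSPIKE] ? v : p[VSPIKE]; // clip exponential argument
  double dv = (p[GL] * (p[ELp] - v)
               + p[GL] * p[DELTA] * std::exp((veff - p[VT]) / p[DELTA])
               - w + Isyn + I_ext) / p[CM];
  double wnew = w + dt * ((p[Aa] * (v - p[ELp]) - w) / p[TAUW]);
  v += dt * dv;
  w = wnew;
  if (v > p[VSPIKE]) {
    v = p[VRESET];
    w += p[Bb];
    refrac = p[TREFRAC];
    return true;
  }
  return false;
}

// Single-cell simulation with prescribed synaptic event counts per step and
// an external current waveform. Deterministic: all randomness is drawn on the
// R side (event counts, OU currents).
// [[Rcpp::export]]
List adex_cell_sim_cpp(NumericVector par, IntegerVector exc_counts,
                       IntegerVector inh_counts, NumericVector I_ext,
                       double dt, double v0, double w0, bool record_trace) {
  const int n = exc_counts.size();
  if (inh_counts.size() != n || I_ext.size() != n)
    stop("input schedules must have equal length");
  const double* p = REAL(par);
  double decay_e = std::exp(-dt / p[TAUE]);
  double decay_i = std::exp(-dt / p[TAUI]);

  double v = v0, w = w0, Ge = 0.0, Gi = 0.0, refrac = 0.0;
  std::vector<double> spikes;
  NumericVector vt, wt;
  if (record_trace) { vt = NumericVector(n + 1); wt = NumericVector(n + 1);
                      vt[0] = v; wt[0] = w; }

  for (int i = 0; i < n; ++i) {
    bool sp = adex_update(p, dt, v, w, Ge, Gi, refrac,
                          exc_counts[i], inh_counts[i], I_ext[i],
                          decay_e, decay_i);
    if (sp) spikes.push_back((i + 1) * dt);
    if (record_trace) { vt[i + 1] = v; wt[i + 1] = w; }
    if (!std::isfinite(v) || !std::isfinite(w))
      stop("non-finite state (%s) at t = %.3f ms",
           std::isfinite(v) ? "w" : "v", (i + 1) * dt);
  }

  List out = List::create(_["spikes"] = wrap(spikes),
                          _["n_steps"] = n, _["dt"] = dt);
  if (record_trace) { out["v"] = vt; out["w"] = wt; }
  return out;
}

// Deliver one presynaptic spike along a CSR adjacency to target conductances.
static inline void deliver(const int* ptr, const int* tgt, int src,
                           std::vector<double>& G, double q) {
  for (int k = ptr[src]; k < ptr[src + 1]; ++k) G[tgt[k]] += q;
}

// Full TC-RE network simulation. Populations indexed 0..N_tc-1 (TC) and
// N_tc..N_tc+N_re-1 (RE). Cortical (P) and sensory (S) drives are pools of
// inhomogeneous-Poisson sources with fixed adjacency; an optional single
// common Poisson source projects to every cell (dynamic-clamp style input);
// optional independent OU membrane currents per cell.
// Uses R's RNG stream (reproducible under set.seed on the caller side).
// [[Rcpp::export]]
List adex_network_sim_cpp(NumericVector par_tc, NumericVector par_re,
                          int N_tc, int N_re,
                          IntegerVector tc2re_ptr, IntegerVector tc2re_tgt,
                          IntegerVector re2tc_ptr, IntegerVector re2tc_tgt,
                          IntegerVector re2re_ptr, IntegerVector re2re_tgt,
                          IntegerVector p2tc_ptr, IntegerVector p2tc_tgt,
                          IntegerVector p2re_ptr, IntegerVector p2re_tgt,
                          IntegerVector s2tc_ptr, IntegerVector s2tc_tgt,
                          int N_P, int N_S,
                          NumericVector P_rate, NumericVector S_rate,
                          NumericVector q_proj,
                          NumericVector common_rate, double common_q_tc,
                          double common_q_re,
                          NumericVector ou_mean, NumericVector ou_sigma,
                          NumericVector ou_tau,
                          double dt, NumericVector v_init,
                          IntegerVector record_idx, int record_stride) {
  const int n_steps = P_rate.size();
  if (S_rate.size() != n_steps) stop("P and S schedules must have equal length");
  const int N = N_tc + N_re;
  const double *ptc = REAL(par_tc), *pre = REAL(par_re);
  const double q_tc2re = q_proj[0], q_re2tc = q_proj[1], q_re2re = q_proj[2],
               q_p2tc = q_proj[3], q_p2re = q_proj[4], q_s2tc = q_proj[5];
  const bool has_common = common_rate.size() > 0;
  if (has_common && common_rate.size() != n_steps)
    stop("common-drive schedule must match duration");

  std::vector<double> v(v_init.begin(), v_init.end()), w(N, 0.0),
      Ge(N, 0.0), Gi(N, 0.0), refrac(N, 0.0);
  const double dec_e_tc = std::exp(-dt / ptc[TAUE]), dec_i_tc = std::exp(-dt / ptc[TAUI]);
  const double dec_e_re = std::exp(-dt / pre[TAUE]), dec_i_re = std::exp(-dt / pre[TAUI]);

  // OU membrane currents (pA), exact discretisation, stationary start
  const bool has_ou = ou_sigma[0] > 0.0 || ou_sigma[1] > 0.0;
  std::vector<double> Iou(N, 0.0);
  double ou_a[2] = {0, 0}, ou_s[2] = {0, 0};
  if (has_ou) {
    for (int k = 0; k < 2; ++k) {
      ou_a[k] = std::exp(-dt / ou_tau[k]);
      ou_s[k] = ou_sigma[k] * std::sqrt(1.0 - ou_a[k] * ou_a[k]);
    }
    for (int i = 0; i < N; ++i) {
      int k = i < N_tc ? 0 : 1;
      Iou[i] = ou_mean[k] + ou_sigma[k] * norm_rand();
    }
  }

  std::vector<int> sp_id; std::vector<double> sp_t;
  std::vector<int> exc_cnt(N, 0), inh_cnt(N, 0);

  const int n_rec = record_idx.size();
  int n_rec_steps = n_rec > 0 ? (n_steps / record_stride + 1) : 0;
  NumericMatrix v_rec(n_rec_steps, n_rec);
  if (n_rec > 0) for (int j = 0; j < n_rec; ++j) v_rec(0, j) = v[record_idx[j]];
  int rec_row = 1;

  // scratch: conductance increments are applied via counts (drives share the
  // projection-specific quantal size, so accumulate as weighted increments)
  std::vector<double> dGe(N, 0.0), dGi(N, 0.0);

  for (int i = 0; i < n_steps; ++i) {
    std::fill(dGe.begin(), dGe.end(), 0.0);
    std::fill(dGi.begin(), dGi.end(), 0.0);

    // external drive events for this step (Poisson superposition over pool)
    double lamP = N_P * P_rate[i] * dt * 1e-3; // rate Hz, dt ms
    int nP = lamP > 0 ? (int)R::rpois(lamP) : 0;
    for (int k = 0; k < nP; ++k) {
      int src = (int)(unif_rand() * N_P); if (src >= N_P) src = N_P - 1;
      for (int e = p2tc_ptr[src]; e < p2tc_ptr[src + 1]; ++e) dGe[p2tc_tgt[e]] += q_p2tc;
      for (int e = p2re_ptr[src]; e < p2re_ptr[src + 1]; ++e) dGe[N_tc + p2re_tgt[e]] += q_p2re;
    }
    double lamS = N_S * S_rate[i] * dt * 1e-3;
    int nS = lamS > 0 ? (int)R::rpois(lamS) : 0;
    for (int k = 0; k < nS; ++k) {
      int src = (int)(unif_rand() * N_S); if (src >= N_S) src = N_S - 1;
      for (int e = s2tc_ptr[src]; e < s2tc_ptr[src + 1]; ++e) dGe[s2tc_tgt[e]] += q_s2tc;
    }
    if (has_common && common_rate[i] > 0) {
      int nC = (int)R::rpois(common_rate[i] * dt * 1e-3);
      if (nC > 0) {
        for (int c = 0; c < N_tc; ++c) dGe[c] += nC * common_q_tc;
        for (int c = N_tc; c < N; ++c) dGe[c] += nC * common_q_re;
      }
    }

    // advance all cells, collect spikes
    size_t first_new = sp_t.size();
    for (int c = 0; c < N; ++c) {
      const bool is_tc = c < N_tc;
      const double* p = is_tc ? ptc : pre;
      double dec_e = is_tc ? dec_e_tc : dec_e_re, dec_i = is_tc ? dec_i_tc : dec_i_re;
      Ge[c] = Ge[c] * dec_e + dGe[c];
      Gi[c] = Gi[c] * dec_i + dGi[c];
      double I = 0.0;
      if (has_ou) {
        int k = is_tc ? 0 : 1;
        Iou[c] = ou_mean[k] + (Iou[c] - ou_mean[k]) * ou_a[k] + ou_s[k] * norm_rand();
        I = Iou[c];
      }
      bool sp;
      if (refrac[c] > 0.0) {
        w[c] += dt * ((p[Aa] * (v[c] - p[ELp]) - w[c]) / p[TAUW]);
        refrac[c] -= dt;
        sp = false;
      } else {
        double Isyn = Ge[c] * (p[EE] - v[c]) + Gi[c] * (p[EI] - v[c]);
        double veff = v[c] < p[VSPIKE] ? v[c] : p[VSPIKE];
        double dv = (p[GL] * (p[ELp] - v[c])
                     + p[GL] * p[DELTA] * std::exp((veff - p[VT]) / p[DELTA])
                     - w[c] + Isyn + I) / p[CM];
        double wnew = w[c] + dt * ((p[Aa] * (v[c] - p[ELp]) - w[c]) / p[TAUW]);
        v[c] += dt * dv;
        w[c] = wnew;
        sp = v[c] > p[VSPIKE];
        if (sp) { v[c] = p[VRESET]; w[c] += p[Bb]; refrac[c] = p[TREFRAC]; }
      }
      if (!std::isfinite(v[c]) || !std::isfinite(w[c]))
        stop("numerical blow-up in neuron %d at t = %.3f ms", c + 1, (i + 1) * dt);
      if (sp) {
        sp_id.push_back(c + 1);
        sp_t.push_back((i + 1) * dt);
      }
    }

    // recurrent propagation: spikes of this step reach targets next step
    for (size_t s = first_new; s < sp_t.size(); ++s) {
      int c = sp_id[s] - 1;
      if (c < N_tc) {
        for (int e = tc2re_ptr[c]; e < tc2re_ptr[c + 1]; ++e)
          Ge[N_tc + tc2re_tgt[e]] += q_tc2re;
      } else {
        int r = c - N_tc;
        for (int e = re2tc_ptr[r]; e < re2tc_ptr[r + 1]; ++e)
          Gi[re2tc_tgt[e]] += q_re2tc;
        for (int e = re2re_ptr[r]; e < re2re_ptr[r + 1]; ++e)
          Gi[N_tc + re2re_tgt[e]] += q_re2re;
      }
    }

    if (n_rec > 0 && ((i + 1) % record_stride == 0) && rec_row < n_rec_steps) {
      for (int j = 0; j < n_rec; ++j) v_rec(rec_row, j) = v[record_idx[j]];
      ++rec_row;
    }
  }

  List out = List::create(_["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
                          _["n_steps"] = n_steps, _["dt"] = dt);
  if (n_rec > 0) {
    out["v_rec"] = v_rec;
    out["record_stride"] = record_stride;
  }
  return out;
}
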