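#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Subthreshold shotnoise moments and the semi-analytic transfer function,
// shared by the mean-field integrator. Units: mV, ms, nS, pA, pF internally;
// rates in Hz (converted to 1/s where the shotnoise formulas require it).

struct Chan { double K, nu, Q, tau, E; }; // tau in ms, nu in Hz

struct Moments { double muV, sigmaV, tauV_ms, muG; };

static Moments shot_moments(const std::vector<Chan>& ch,
                            double gL, double EL, double cm, double w,
                            const std::vector<double>& stat_g,
                            const std::vector<double>& stat_E,
                            double tau_fallback_ms) {
  double muG = gL, numer = gL * EL - w;
  for (const Chan& c : ch) {
    double mg = c.nu * c.K * (c.tau * 1e-3) * c.Q; // Eq: muG_x = nu K tau Q
    muG += mg;
    numer += mg * c.E;
  }
  for (size_t s = 0; s < stat_g.size(); ++s) {
    muG += stat_g[s];
    numer += stat_g[s] * stat_E[s];
  }
  double muV = numer / muG;
  double tau_m_s = (cm / muG) * 1e-3;
  double num_t = 0.0, den_t = 0.0;
  for (const Chan& c : ch) {
    if (c.nu <= 0.0 || c.K <= 0.0) continue;
    double U = c.Q / muG * (c.E - muV); // effective synaptic drive (mV)
    double contrib = c.K * c.nu * U * U * (c.tau * 1e-3) * (c.tau * 1e-3);
    num_t += contrib;
    den_t += contrib / (tau_m_s + c.tau * 1e-3);
  }
  Moments m;
  m.muG = muG;
  m.muV = muV;
  if (num_t > 0.0) {
    m.sigmaV = std::sqrt(0.5 * den_t); // sigmaV^2 = sum contrib / (2 (tau_m+tau))
    m.tauV_ms = (num_t / den_t) * 1e3;
  } else {
    m.sigmaV = 0.0;
    m.tauV_ms = tau_m_s * 1e3 + tau_fallback_ms;
  }
  return m;
}

// effective threshold: second-order polynomial in normalised (muV, sigmaV, tauVN)
static double v_thr_eff(const double* P, const double* nrm,
                        double muV, double sigmaV, double tauVN) {
  double x0 = (muV - nrm[0]) / nrm[1];
  double x1 = (sigmaV - nrm[2]) / nrm[3];
  double x2 = (tauVN - nrm[4]) / nrm[5];
  return P[0] + P[1] * x0 + P[2] * x1 + P[3] * x2
       + P[4] * x0 * x0 + P[5] * x0 * x1 + P[6] * x0 * x2
       + P[7] * x1 * x1 + P[8] * x1 * x2 + P[9] * x2 * x2;
}

static double rate_from_moments(const Moments& m, double gL, double cm,
                                const double* P, const double* nrm) {
  double tauVN = m.tauV_ms * gL / cm;
  double vthr = v_thr_eff(P, nrm, m.muV, m.sigmaV, tauVN);
  double tauV_s = m.tauV_ms * 1e-3;
  if (m.sigmaV < 1e-9) return m.muV > vthr ? 1.0 / tauV_s : 0.0;
  return 0.5 / tauV_s * std::erfc((vthr - m.muV) / (M_SQRT2 * m.sigmaV));
}

// Configuration unpacked once from the R side.
struct MFCfg {
  std::vector<double> par_e, par_i, coef_e, coef_i, nrm;
  double K_ie, K_ei, K_ii, K_pe, K_pi, K_se;
  double N_e, N_i, T_ms, fd_min, fd_rel, c_clamp;
  double com_K, com_Q; // optional single common Poisson source (K, Q); rate is time-varying
};

enum ParIdx { CM, GL, ELp, VT, DELTA, Aa, Bb, TAUW, QE, QI, TAUE, TAUI,
              EE, EI, VSPIKE, VRESET, TREFRAC };

static MFCfg unpack_cfg(const List& cfg) {
  MFCfg c;
  c.par_e = as<std::vector<double>>(cfg["par_e"]);
  c.par_i = as<std::vector<double>>(cfg["par_i"]);
  c.coef_e = as<std::vector<double>>(cfg["coef_e"]);
  c.coef_i = as<std::vector<double>>(cfg["coef_i"]);
  c.nrm = as<std::vector<double>>(cfg["norm"]);
  c.K_ie = cfg["K_ie"]; c.K_ei = cfg["K_ei"]; c.K_ii = cfg["K_ii"];
  c.K_pe = cfg["K_pe"]; c.K_pi = cfg["K_pi"]; c.K_se = cfg["K_se"];
  c.N_e = cfg["N_e"]; c.N_i = cfg["N_i"]; c.T_ms = cfg["T_ms"];
  c.fd_min = cfg["fd_min"]; c.fd_rel = cfg["fd_rel"];
  c.c_clamp = cfg["c_clamp"];
  c.com_K = cfg["com_K"]; c.com_Q = cfg["com_Q"];
  return c;
}

// Transfer function F_mu(nu_e, nu_i) for population pop (0 = TC, 1 = RE)
// given external drives and static noise conductances. Also returns moments.
static Moments pop_moments(const MFCfg& c, int pop, double nu_e, double nu_i,
                           double w, double P, double S, double com_rate,
                           double nge, double ngi) {
  const std::vector<double>& p = pop == 0 ? c.par_e : c.par_i;
  std::vector<Chan> ch;
  ch.reserve(4);
  if (pop == 0) {
    if (c.K_pe > 0) ch.push_back({c.K_pe, P, p[QE], p[TAUE], p[EE]});
    if (c.K_se > 0) ch.push_back({c.K_se, S, p[QE], p[TAUE], p[EE]});
    ch.push_back({c.K_ie, nu_i, p[QI], p[TAUI], p[EI]});
  } else {
    if (c.K_pi > 0) ch.push_back({c.K_pi, P, p[QE], p[TAUE], p[EE]});
    ch.push_back({c.K_ei, nu_e, p[QE], p[TAUE], p[EE]});
    ch.push_back({c.K_ii, nu_i, p[QI], p[TAUI], p[EI]});
  }
  if (c.com_K > 0 && com_rate > 0)
    ch.push_back({c.com_K, com_rate, c.com_Q, p[TAUE], p[EE]});
  std::vector<double> sg, sE;
  if (nge > 0) { sg.push_back(nge); sE.push_back(p[EE]); }
  if (ngi > 0) { sg.push_back(ngi); sE.push_back(p[EI]); }
  double tau_fb = std::max(p[TAUE], p[TAUI]);
  return shot_moments(ch, p[GL], p[ELp], p[CM], w, sg, sE, tau_fb);
}

static double pop_rate(const MFCfg& c, int pop, double nu_e, double nu_i,
                       double w, double P, double S, double com_rate,
                       double nge, double ngi, Moments* mom = nullptr) {
  Moments m = pop_moments(c, pop, nu_e, nu_i, w, P, S, com_rate, nge, ngi);
  if (mom) *mom = m;
  const std::vector<double>& p = pop == 0 ? c.par_e : c.par_i;
  const std::vector<double>& cf = pop == 0 ? c.coef_e : c.coef_i;
  return rate_from_moments(m, p[GL], p[CM], cf.data(), c.nrm.data());
}

// quadratic-through-3-points derivative helpers (non-uniform abscissae)
static void quad_derivs(double x0, double x1, double x2,
                        double f0, double f1, double f2, double at,
                        double& d1, double& d2) {
  double s01 = (f1 - f0) / (x1 - x0);
  double s12 = (f2 - f1) / (x2 - x1);
  double c2 = (s12 - s01) / (x2 - x0);
  // f(x) = f0 + s01 (x - x0) + c2 (x - x0)(x - x1)
  d1 = s01 + c2 * (2.0 * at - x0 - x1);
  d2 = 2.0 * c2;
}

struct Derivs {
  double dnu[2], dc[3], dw[2], F[2], muV[2], sigmaV[2];
  double dF[2][2]; // dF[mu][lambda] = dF_mu/dnu_lambda
};

static Derivs mf_rhs(const MFCfg& c, const double* st, double P, double S,
                     double com_rate, double nge, double ngi) {
  // state layout: nu_e, nu_i, c_ee, c_ei, c_ii, w_e, w_i
  double nu_e = st[0], nu_i = st[1];
  double cee = st[2], cei = st[3], cii = st[4];
  double w[2] = {st[5], st[6]};

  double he = std::max(c.fd_min, c.fd_rel * nu_e);
  double hi = std::max(c.fd_min, c.fd_rel * nu_i);
  double xe[3] = {std::max(0.0, nu_e - he), nu_e, nu_e + he};
  double xi[3] = {std::max(0.0, nu_i - hi), nu_i, nu_i + hi};
  if (xe[0] == xe[1]) { xe[1] = 0.5 * he; } // nu at 0: forward-style stencil
  if (xi[0] == xi[1]) { xi[1] = 0.5 * hi; }

  Derivs d;
  double d2F[2][3]; // [mu][ee, ei, ii]
  for (int pop = 0; pop < 2; ++pop) {
    double F[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        F[a][b] = pop_rate(c, pop, xe[a], xi[b], w[pop], P, S, com_rate, nge, ngi);
    Moments m;
    d.F[pop] = pop_rate(c, pop, nu_e, nu_i, w[pop], P, S, com_rate, nge, ngi, &m);
    d.muV[pop] = m.muV;
    d.sigmaV[pop] = m.sigmaV;
    // first and second derivatives along each axis (middle row/column)
    double de1, de2, di1, di2;
    quad_derivs(xe[0], xe[1], xe[2], F[0][1], F[1][1], F[2][1], nu_e, de1, de2);
    quad_derivs(xi[0], xi[1], xi[2], F[1][0], F[1][1], F[1][2], nu_i, di1, di2);
    d.dF[pop][0] = de1; d.dF[pop][1] = di1;
    d2F[pop][0] = de2; d2F[pop][2] = di2;
    // cross derivative from corner points
    d2F[pop][1] = (F[2][2] - F[2][0] - F[0][2] + F[0][0])
                  / ((xe[2] - xe[0]) * (xi[2] - xi[0]));
  }

  double T = c.T_ms;
  double invT_Hz = 1000.0 / T; // 1/T in Hz
  double Aee = d.F[0] * (invT_Hz - d.F[0]) / c.N_e;
  double Aii = d.F[1] * (invT_Hz - d.F[1]) / c.N_i;

  double de = d.F[0] - nu_e, di = d.F[1] - nu_i;
  d.dnu[0] = (de + 0.5 * (cee * d2F[0][0] + 2.0 * cei * d2F[0][1] + cii * d2F[0][2])) / T;
  d.dnu[1] = (di + 0.5 * (cee * d2F[1][0] + 2.0 * cei * d2F[1][1] + cii * d2F[1][2])) / T;
  d.dc[0] = (Aee + de * de
             + 2.0 * (d.dF[0][0] * cee + d.dF[0][1] * cei) - 2.0 * cee) / T;
  d.dc[1] = (de * di + d.dF[0][0] * cei + d.dF[0][1] * cii
             + d.dF[1][0] * cee + d.dF[1][1] * cei - 2.0 * cei) / T;
  d.dc[2] = (Aii + di * di
             + 2.0 * (d.dF[1][0] * cei + d.dF[1][1] * cii) - 2.0 * cii) / T;
  // adaptation (per ms): dw = -w/tau_w + b nu + a (muV - EL)/tau_w
  for (int pop = 0; pop < 2; ++pop) {
    const std::vector<double>& p = pop == 0 ? c.par_e : c.par_i;
    d.dw[pop] = -w[pop] / p[TAUW] + p[Bb] * (pop == 0 ? nu_e : nu_i) * 1e-3
                + p[Aa] * (d.muV[pop] - p[ELp]) / p[TAUW];
  }
  return d;
}

// [[Rcpp::export]]
NumericVector mf_derivs_cpp(List cfg, NumericVector state, double P, double S,
                            double com_rate, double nge, double ngi) {
  MFCfg c = unpack_cfg(cfg);
  Derivs d = mf_rhs(c, REAL(state), P, S, com_rate, nge, ngi);
  NumericVector out = NumericVector::create(
      _["nu_e"] = d.dnu[0], _["nu_i"] = d.dnu[1],
      _["c_ee"] = d.dc[0], _["c_ei"] = d.dc[1], _["c_ii"] = d.dc[2],
      _["w_e"] = d.dw[0], _["w_i"] = d.dw[1]);
  out.attr("F") = NumericVector::create(d.F[0], d.F[1]);
  out.attr("muV") = NumericVector::create(d.muV[0], d.muV[1]);
  out.attr("sigmaV") = NumericVector::create(d.sigmaV[0], d.sigmaV[1]);
  return out;
}

// Forward-Euler integration of the second-order mean-field. Drives P/S and
// the common-source rate are per-step arrays; noise conductances are
// piecewise-constant arrays indexed by floor(t / noise_bin_ms).
// [[Rcpp::export]]
List mf_integrate_cpp(List cfg, NumericVector init,
                      NumericVector P_rate, NumericVector S_rate,
                      NumericVector com_rate,
                      NumericVector noise_ge, NumericVector noise_gi,
                      double noise_bin_ms, double dt, int stride) {
  MFCfg c = unpack_cfg(cfg);
  const int n_steps = P_rate.size();
  if (S_rate.size() != n_steps) stop("drive schedules must have equal length");
  const bool has_com = com_rate.size() > 0;
  const bool has_noise = noise_ge.size() > 0;

  double st[7];
  for (int k = 0; k < 7; ++k) st[k] = init[k];

  int n_out = n_steps / stride + 1;
  NumericMatrix out(n_out, 13);
  colnames(out) = CharacterVector::create("t", "nu_e", "nu_i", "c_ee", "c_ei",
                                          "c_ii", "w_e", "w_i", "muV_e", "muV_i",
                                          "sigmaV_e", "sigmaV_i", "F_e");
  long clip_count = 0;
  int row = 0;

  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    double P = P_rate[std::min(i, n_steps - 1)];
    double S = S_rate[std::min(i, n_steps - 1)];
    double com = has_com ? com_rate[std::min(i, n_steps - 1)] : 0.0;
    double nge = 0.0, ngi = 0.0;
    if (has_noise) {
      int bin = (int)(t / noise_bin_ms);
      if (bin >= noise_ge.size()) bin = noise_ge.size() - 1;
      nge = noise_ge[bin];
      ngi = noise_gi[bin];
    }
    Derivs d = mf_rhs(c, st, P, S, com, nge, ngi);

    if (i % stride == 0 && row < n_out) {
      out(row, 0) = t;
      for (int k = 0; k < 7; ++k) out(row, 1 + k) = st[k];
      out(row, 8) = d.muV[0]; out(row, 9) = d.muV[1];
      out(row, 10) = d.sigmaV[0]; out(row, 11) = d.sigmaV[1];
      out(row, 12) = d.F[0];
      ++row;
    }
    if (i == n_steps) break;

    st[0] += dt * d.dnu[0]; st[1] += dt * d.dnu[1];
    st[2] += dt * d.dc[0]; st[3] += dt * d.dc[1]; st[4] += dt * d.dc[2];
    st[5] += dt * d.dw[0]; st[6] += dt * d.dw[1];
    if (st[0] < 0) { st[0] = 0; ++clip_count; }
    if (st[1] < 0) { st[1] = 0; ++clip_count; }
    if (st[2] < 0) { st[2] = 0; ++clip_count; }
    if (st[4] < 0) { st[4] = 0; ++clip_count; }
    if (c.c_clamp > 0) {
      // validity clamp: the second-order expansion holds for covariances on
      // the Poissonian finite-size scale nu (1/T - nu) / N; cap at a
      // multiple of it (using max(nu, F) so onset transients keep headroom)
      double invT_Hz = 1000.0 / c.T_ms;
      double re = std::min(std::max(std::max(st[0], d.F[0]), 1.0), invT_Hz);
      double ri = std::min(std::max(std::max(st[1], d.F[1]), 1.0), invT_Hz);
      double be = c.c_clamp * re * (invT_Hz - re + 1.0) / c.N_e;
      double bi = c.c_clamp * ri * (invT_Hz - ri + 1.0) / c.N_i;
      if (st[2] > be) { st[2] = be; ++clip_count; }
      if (st[4] > bi) { st[4] = bi; ++clip_count; }
      double bei = std::sqrt(be * bi);
      if (st[3] > bei) { st[3] = bei; ++clip_count; }
      if (st[3] < -bei) { st[3] = -bei; ++clip_count; }
    }
    for (int k = 0; k < 7; ++k)
      if (!std::isfinite(st[k]))
        stop("mean-field blow-up at t = %.2f ms (state component %d)", t, k + 1);
  }

  return List::create(_["trajectory"] = out, _["clips"] = clip_count,
                      _["n_steps"] = n_steps, _["dt"] = dt);
}

// Vectorised transfer-function evaluation under the mean-field input wiring
// (used for cross-checks and the firing-adaptation metric).
// [[Rcpp::export]]
NumericMatrix mf_transfer_cpp(List cfg, int pop, NumericVector nu_e,
                              NumericVector nu_i, NumericVector w,
                              double P, double S, double com_rate,
                              double nge, double ngi) {
  MFCfg c = unpack_cfg(cfg);
  int n = nu_e.size();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("rate", "muV", "sigmaV", "muG");
  for (int i = 0; i < n; ++i) {
    Moments m;
    out(i, 0) = pop_rate(c, pop - 1, nu_e[i], nu_i[i], w[i], P, S, com_rate,
                         nge, ngi, &m);
    out(i, 1) = m.muV; out(i, 2) = m.sigmaV; out(i, 3) = m.muG;
  }
  return out;
}
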