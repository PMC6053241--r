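// Exported single-cell and single-synapse operations. These run on direct
// rate-function evaluation (no lookup tables) and are the same code paths
// the network engine uses, via the shared templated derivatives.

#include <Rcpp.h>
#include "model.h"

using namespace Rcpp;
using namespace tck;

static CxParams cx_params_from_list(List p) {
  CxParams c;
  double Ssoma = as<double>(p["S_soma"]), rho = as<double>(p["rho"]);
  c.Cm = as<double>(p["C_m"]);
  c.S_soma = Ssoma; c.S_dend = rho * Ssoma;
  c.gNaS = as<double>(p["g_Na_soma"]);
  c.gKS = as<double>(p["g_K_soma"]);
  c.gNapS = as<double>(p["g_Nap_soma"]);
  c.gNaD = as<double>(p["g_Na_dend"]);
  c.gNapD = as<double>(p["g_Nap_dend"]);
  c.gKm = as<double>(p["g_Km"]);
  c.gKCa = as<double>(p["g_KCa"]);
  c.gHVA = as<double>(p["g_HVA"]);
  c.GL = as<double>(p["G_L"]);
  c.EL = as<double>(p["E_L"]);
  c.GKL = as<double>(p["G_KL"]);
  c.EK = as<double>(p["E_K"]);
  double gc = 1.0 / as<double>(p["kappa_Mohm"]);
  c.gcD = gc * 1e-3 / c.S_dend;
  c.gcS = gc * 1e-3 / c.S_soma;
  c.naM_sh = as<double>(p["na_m_mid"]) + 35.0;
  c.naH_sh = as<double>(p["na_h_mid"]) + 65.0;
  c.kv_sh = as<double>(p["kv_mid"]) - 5.0;
  c.napMax = as<double>(p["nap_max"]);
  return c;
}

static ThParams th_params_from_list(List p, bool is_tc) {
  ThParams t;
  t.Cm = as<double>(p["C_m"]); t.S = as<double>(p["S"]);
  t.gNa = as<double>(p["g_Na"]); t.gK = as<double>(p["g_K"]);
  t.gT = as<double>(p["g_T"]); t.gh = as<double>(p["g_h"]);
  t.GL = as<double>(p["G_L"]); t.EL = as<double>(p["E_L"]);
  t.GKL = as<double>(p["G_KL"]); t.EK = as<double>(p["E_K"]);
  t.Vtr = as<double>(p["V_tr"]);
  t.VtrK = as<double>(p["V_trK"]);
  t.Eh = as<double>(p["E_h"]);
  t.is_tc = is_tc;
  return t;
}

static void check_finite(const double* d, int n, const char* what) {
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(d[i]))
      stop("non-finite derivative in %s (component %d)", what, i + 1);
}

// [[Rcpp::export(name = ".cx_dendrite_rhs")]]
List cx_dendrite_rhs_cpp(NumericVector state, List params, double ach_gkl,
                         double I_syn, double I_stim, double V_S) {
  if (state.size() != NCX)
    stop("cortical state must have %d components", NCX);
  CxParams P = cx_params_from_list(params);
  DirectKin kin;
  std::vector<double> dy(NCX, 0.0);
  double vs = ISNAN(V_S) ? cx_solve_vs(P, state[0], &state[0]) : V_S;
  cx_derivs(P, kin, &state[0], vs, ach_gkl, I_syn, I_stim, dy.data());
  check_finite(dy.data(), NCX, "cortical dendrite");
  return List::create(_["dstate"] = wrap(dy), _["V_S"] = vs);
}

// [[Rcpp::export(name = ".solve_vs")]]
List solve_vs_cpp(double V_D, NumericVector soma_gating, List params,
                  double tol, int max_iter) {
  CxParams P = cx_params_from_list(params);
  // pack a 13-vector with the soma gating in slots 9..12
  std::vector<double> s(NCX, 0.0);
  s[0] = V_D;
  for (int i = 0; i < 4; ++i) s[9 + i] = soma_gating[i];
  // closed form (currents ohmic in VS at fixed gating), then a residual
  // check; a safeguarded Newton refinement covers any future nonlinear
  // channel added to the balance.
  double vs = cx_solve_vs(P, V_D, s.data());
  double res = cx_vs_residual(P, vs, V_D, s.data());
  double scale = std::fabs(P.gcS) + P.gNaS + P.gKS + P.gNapS;
  int it = 0;
  double lo = std::min(V_D, E_NA) - 200.0, hi = std::max(V_D, E_NA) + 200.0;
  while (std::fabs(res) > tol * scale && it++ < max_iter) {
    double gna = P.gNaS * s[9] * s[9] * s[9] * s[10];
    double dF = -(P.gcS + gna + P.gKS * s[11] + P.gNapS * s[12]);
    double vn = vs - res / dF;
    if (vn < lo || vn > hi) vn = 0.5 * (lo + hi);
    if (res > 0) lo = vs; else hi = vs;
    vs = vn;
    res = cx_vs_residual(P, vs, V_D, s.data());
  }
  if (!(std::fabs(res) <= tol * scale))
    stop("axosomatic equilibrium solver failed to converge at V_D = %.3f", V_D);
  return List::create(_["V_S"] = vs, _["residual"] = res,
                      _["iterations"] = it);
}

// [[Rcpp::export(name = ".thalamic_rhs")]]
List thalamic_rhs_cpp(NumericVector state, List params, bool is_tc,
                      double ach_gkl, double ha_gh, double I_syn,
                      double I_stim) {
  int nv = is_tc ? NTC : NRE;
  if (state.size() != nv) stop("thalamic state must have %d components", nv);
  ThParams P = th_params_from_list(params, is_tc);
  if (!is_tc && P.gh > 0)
    stop("the hyperpolarization-activated current is TC-only: g_h must be 0 for RE");
  DirectKin kin; kin.ha_gh = ha_gh;
  std::vector<double> dy(nv, 0.0);
  th_derivs(P, kin, &state[0], ach_gkl, I_syn, I_stim, dy.data());
  check_finite(dy.data(), nv, is_tc ? "TC cell" : "RE cell");
  return List::create(_["dstate"] = wrap(dy));
}

// Single-cell RK4 integration with step-current protocol; used for
// regime-level cell tests (rebound bursts, tonic firing).
// stim: matrix with columns t_on, t_off, amplitude (uA/cm2; cortical cells
// receive it on the dendrite). Returns voltage trace (soma / membrane) and
// spike times.
// [[Rcpp::export(name = ".single_cell_run")]]
List single_cell_run(std::string kind, List params, double ach_gkl,
                     double ha_gh, double duration, double dt,
                     NumericMatrix stim, double v0, int record_every) {
  bool cortical = kind == "PY" || kind == "IN";
  bool is_tc = kind == "TC";
  DirectKin kin; kin.ha_gh = ha_gh;
  int nv = cortical ? NCX : (is_tc ? NTC : NRE);
  std::vector<double> y(nv, 0.0), dy(nv), k1(nv), k2(nv), k3(nv), k4(nv),
      yt(nv);
  CxParams CP; ThParams TP;
  if (cortical) CP = cx_params_from_list(params);
  else TP = th_params_from_list(params, is_tc);
  // init at v0, gates at steady state
  y[0] = v0;
  if (cortical) {
    double inf, tau;
    kin.eval(G_CXNA_M, v0 - CP.naM_sh, inf, tau); y[1] = y[9] = inf;
    kin.eval(G_CXNA_H, v0 - CP.naH_sh, inf, tau); y[2] = y[10] = inf;
    kin.eval(G_CXNAP_M, v0, inf, tau); y[3] = y[12] = CP.napMax * inf;
    kin.eval(G_CXKM_N, v0, inf, tau); y[4] = inf;
    y[5] = cx_kca_m(CX_CA_INF).inf;
    kin.eval(G_CXHVA_M, v0, inf, tau); y[6] = inf;
    kin.eval(G_CXHVA_H, v0, inf, tau); y[7] = inf;
    y[8] = CX_CA_INF;
    kin.eval(G_CXK_N, v0 - CP.kv_sh, inf, tau); y[11] = inf;
  } else {
    double inf, tau, vr = v0 - TP.Vtr;
    kin.eval(G_THNA_M, vr, inf, tau); y[1] = inf;
    kin.eval(G_THNA_H, vr, inf, tau); y[2] = inf;
    kin.eval(G_THK_N, v0 - TP.VtrK, inf, tau); y[3] = inf;
    kin.eval(is_tc ? G_TCT_M : G_RET_M, v0, inf, tau); y[4] = inf;
    kin.eval(is_tc ? G_TCT_H : G_RET_H, v0, inf, tau); y[5] = inf;
    if (is_tc) {
      kin.eval(G_TCH_M, v0, inf, tau);
      y[6] = inf; y[7] = 0.0; y[8] = 0.0; y[9] = TH_CA_INF;
    } else y[6] = TH_CA_INF;
  }
  long nsteps = (long)std::llround(duration / dt);
  std::vector<double> vtrace, ttrace, spikes;
  double vprev = v0, last_spk = -1e9;
  auto inj_at = [&](double t) {
    double a = 0.0;
    for (int r = 0; r < stim.nrow(); ++r)
      if (t >= stim(r, 0) && t < stim(r, 1)) a += stim(r, 2);
    return a;
  };
  auto deriv = [&](double t, std::vector<double>& yy, std::vector<double>& dd) {
    double istim = inj_at(t);
    if (cortical) {
      double vs = cx_solve_vs(CP, yy[0], yy.data());
      cx_derivs(CP, kin, yy.data(), vs, ach_gkl, 0.0, istim, dd.data());
    } else {
      th_derivs(TP, kin, yy.data(), ach_gkl, 0.0, istim, dd.data());
    }
  };
  for (long it = 0; it < nsteps; ++it) {
    double t = it * dt;
    deriv(t, y, k1);
    for (int i = 0; i < nv; ++i) yt[i] = y[i] + dt / 2 * k1[i];
    deriv(t + dt / 2, yt, k2);
    for (int i = 0; i < nv; ++i) yt[i] = y[i] + dt / 2 * k2[i];
    deriv(t + dt / 2, yt, k3);
    for (int i = 0; i < nv; ++i) yt[i] = y[i] + dt * k3[i];
    deriv(t + dt, yt, k4);
    for (int i = 0; i < nv; ++i)
      y[i] += dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    for (int i = 1; i < nv; ++i) {
      bool is_ca = (cortical && i == 8) || (is_tc && i == 9) ||
                   (!cortical && !is_tc && i == 6);
      if (!is_ca) { if (y[i] < 0) y[i] = 0; else if (y[i] > 1) y[i] = 1; }
    }
    double v = cortical ? cx_solve_vs(CP, y[0], y.data()) : y[0];
    if (!(std::fabs(y[0]) <= 500.0))
      stop("numerical blow-up in single-cell run at t = %.2f ms", t);
    if (v >= 0 && vprev < 0 && t - last_spk > 2.0) {
      spikes.push_back(t + dt);
      last_spk = t + dt;
    }
    vprev = v;
    if (record_every > 0 && it % record_every == 0) {
      vtrace.push_back(v);
      ttrace.push_back(t + dt);
    }
  }
  return List::create(_["t"] = wrap(ttrace), _["v"] = wrap(vtrace),
                      _["spikes"] = wrap(spikes));
}

// First-order receptor kinetics / GABA-B cascade driven by a given
// presynaptic spike train. Returns the time course of the open fraction
// (or, for GABA-B, the potassium-channel activation G^4/(G^4+KD) along
// with R and G).
// [[Rcpp::export(name = ".synapse_response")]]
List synapse_response(int receptor, NumericVector spike_times,
                      double duration, double dt) {
  int ns = (int)std::llround(duration / dt);
  NumericVector out(ns), tv(ns), Rv_out(ns), Gv_out(ns);
  double O = 0.0, Rv = 0.0, Gv = 0.0;
  double al = receptor == 0 ? AMPA_ALPHA : receptor == 1 ? NMDA_ALPHA :
              GABAA_ALPHA;
  double be = receptor == 0 ? AMPA_BETA : receptor == 1 ? NMDA_BETA :
              GABAA_BETA;
  auto Tat = [&](double t) {
    for (double s : spike_times)
      if (t >= s && t < s + TDUR) return TMAX;
    return 0.0;
  };
  for (int it = 0; it < ns; ++it) {
    double t = it * dt;
    if (receptor == 3) {
      auto f = [&](double tt, double r, double g, double& dr, double& dg) {
        double T = Tat(tt);
        dr = GABAB_K1 * T * (1 - r) - GABAB_K2 * r;
        dg = GABAB_K3 * r - GABAB_K4 * g;
      };
      double r1, g1, r2, g2, r3, g3, r4, g4;
      f(t, Rv, Gv, r1, g1);
      f(t + dt / 2, Rv + dt / 2 * r1, Gv + dt / 2 * g1, r2, g2);
      f(t + dt / 2, Rv + dt / 2 * r2, Gv + dt / 2 * g2, r3, g3);
      f(t + dt, Rv + dt * r3, Gv + dt * g3, r4, g4);
      Rv += dt / 6 * (r1 + 2 * r2 + 2 * r3 + r4);
      Gv += dt / 6 * (g1 + 2 * g2 + 2 * g3 + g4);
      double g4p = Gv * Gv * Gv * Gv;
      out[it] = g4p / (g4p + GABAB_KD);
      Rv_out[it] = Rv; Gv_out[it] = Gv;
    } else {
      auto f = [&](double tt, double o) {
        return al * Tat(tt) * (1 - o) - be * o;
      };
      double o1 = f(t, O), o2 = f(t + dt / 2, O + dt / 2 * o1),
             o3 = f(t + dt / 2, O + dt / 2 * o2), o4 = f(t + dt, O + dt * o3);
      O += dt / 6 * (o1 + 2 * o2 + 2 * o3 + o4);
      if (O < 0) O = 0; if (O > 1) O = 1;
      out[it] = O;
    }
    tv[it] = t + dt;
  }
  return List::create(_["t"] = tv, _["value"] = out,
                      _["R"] = Rv_out, _["G"] = Gv_out);
}

// Peak over lags |l| <= lag_max of the energy-normalized raw
// cross-correlation sum(x[t+l] y[t]) / sqrt(sum x^2 sum y^2).
// [[Rcpp::export(name = ".xcorr_energy_peak")]]
double xcorr_energy_peak(NumericVector x, NumericVector y, int lag_max) {
  int n = x.size();
  double ex = 0, ey = 0;
  for (int i = 0; i < n; ++i) { ex += x[i] * x[i]; ey += y[i] * y[i]; }
  if (ex == 0 || ey == 0) return NA_REAL;
  double best = R_NegInf;
  for (int l = -lag_max; l <= lag_max; ++l) {
    double v = 0;
    int lo = std::max(0, -l), hi = std::min(n, n - l);
    for (int t = lo; t < hi; ++t) v += x[t + l] * y[t];
    if (v > best) best = v;
  }
  return best / std::sqrt(ex * ey);
}

// Connected-component labelling (8-connectivity) of a logical matrix.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!m(i, j) || lab(i, j)) continue;
    ++next;
    stack.push_back({i, j});
    lab(i, j) = next;
    while (!stack.empty()) {
      auto [ci, cj] = stack.back();
      stack.pop_back();
      for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ni = ci + di, nj = cj + dj;
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        if (m(ni, nj) && !lab(ni, nj)) {
          lab(ni, nj) = next;
          stack.push_back({ni, nj});
        }
      }
    }
  }
  return lab;
}
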