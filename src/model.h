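// Single-cell right-hand sides shared by the network engine and the
// exported single-cell operations. The kinetics provider `K` supplies
// (inf, tau) for each tabulated gate, so the same code runs either on
// direct rate-function evaluation (exact, used by the exported ops and
// for table construction) or on lookup tables (used by the engine).

#ifndef TCSLEEP_MODEL_H
#define TCSLEEP_MODEL_H

#include "kinetics.h"

namespace tck {

enum Gate { G_CXNA_M, G_CXNA_H, G_CXK_N, G_CXNAP_M, G_CXKM_N,
            G_CXHVA_M, G_CXHVA_H, G_THNA_M, G_THNA_H, G_THK_N,
            G_TCT_M, G_TCT_H, G_RET_M, G_RET_H, G_TCH_M, N_GATES };

// Direct evaluation of gate `g` at voltage v (ha = stage shift, h-current
// only).
inline InfTau gate_direct(int g, double v, double ha_gh) {
  switch (g) {
    case G_CXNA_M:  return cx_na_m(v);
    case G_CXNA_H:  return cx_na_h(v);
    case G_CXK_N:   return cx_k_n(v);
    case G_CXNAP_M: return cx_nap_m(v);
    case G_CXKM_N:  return cx_km_n(v);
    case G_CXHVA_M: return cx_hva_m(v);
    case G_CXHVA_H: return cx_hva_h(v);
    case G_THNA_M:  return th_na_m(v);
    case G_THNA_H:  return th_na_h(v);
    case G_THK_N:   return th_k_n(v);
    case G_TCT_M:   return tc_t_m(v);
    case G_TCT_H:   return tc_t_h(v);
    case G_RET_M:   return re_t_m(v);
    case G_RET_H:   return re_t_h(v);
    case G_TCH_M:   return tc_h_m(v, ha_gh);
  }
  return {0.0, 1.0};
}

struct DirectKin {
  double ha_gh = 0.0;
  inline void eval(int g, double v, double& inf, double& tau) const {
    InfTau it = gate_direct(g, v, ha_gh);
    inf = it.inf; tau = it.tau;
  }
};

struct TabKin {
  RateTab tab[N_GATES];
  void build(double ha_gh) {
    for (int g = 0; g < N_GATES; ++g) {
      double ha = ha_gh;
      tab[g].build([g, ha](double v) { return gate_direct(g, v, ha); });
    }
  }
  void rebuild_h(double ha_gh) {
    tab[G_TCH_M].build([ha_gh](double v) { return gate_direct(G_TCH_M, v, ha_gh); });
  }
  inline void eval(int g, double v, double& inf, double& tau) const {
    tab[g].eval(v, inf, tau);
  }
};

// ---- Cortical two-compartment cell ----
// State layout (13): 0 VD, 1 mNaD, 2 hNaD, 3 mNapD, 4 nKm, 5 mKCa,
// 6 mHVA, 7 hHVA, 8 Ca, 9 mNaS, 10 hNaS, 11 nKS, 12 mNapS.
const int NCX = 13;

struct CxParams {
  double Cm, S_soma, S_dend;
  double gNaS, gKS, gNapS;               // axosomatic, mS/cm2
  double gNaD, gNapD, gKm, gKCa, gHVA;   // dendritic
  double GL, EL, GKL, EK;
  double gcD, gcS;                       // coupling density per compartment
  double naM_sh, naH_sh, kv_sh;          // channel midpoint shifts (mV)
  double napMax;                         // persistent-Na max open fraction
};

// Axosomatic equilibrium: with the gating variables held as state, every
// axosomatic current is ohmic in VS, so the current balance
// 0 = -g(VS - VD) - INa - IK - INap has the closed-form root below.
inline double cx_solve_vs(const CxParams& p, double VD, const double* y) {
  double gna = p.gNaS * y[9] * y[9] * y[9] * y[10];
  double gk = p.gKS * y[11];
  double gnap = p.gNapS * y[12];
  double gtot = p.gcS + gna + gk + gnap;
  return (p.gcS * VD + gna * E_NA + gk * p.EK + gnap * E_NA) / gtot;
}

inline double cx_vs_residual(const CxParams& p, double VS, double VD,
                             const double* y) {
  double ina = p.gNaS * y[9] * y[9] * y[9] * y[10] * (VS - E_NA);
  double ik = p.gKS * y[11] * (VS - p.EK);
  double inap = p.gNapS * y[12] * (VS - E_NA);
  return -p.gcS * (VS - VD) - ina - ik - inap;
}

// Dendritic + soma-gating derivatives. I_syn and I_stim are densities on
// the dendritic membrane (uA/cm2); gkl_f is the stage potassium-leak
// factor. Returns dy for all 13 state variables.
template <class K>
inline void cx_derivs(const CxParams& p, const K& kin, const double* y,
                      double VS, double gkl_f, double Isyn, double Istim,
                      double* dy) {
  double VD = y[0];
  double inf, tau;
  // dendritic gates (channel midpoints shifted per cell parameters)
  kin.eval(G_CXNA_M, VD - p.naM_sh, inf, tau);  dy[1] = (inf - y[1]) / tau;
  kin.eval(G_CXNA_H, VD - p.naH_sh, inf, tau);  dy[2] = (inf - y[2]) / tau;
  kin.eval(G_CXNAP_M, VD, inf, tau);
  dy[3] = (p.napMax * inf - y[3]) / tau;
  kin.eval(G_CXKM_N, VD, inf, tau);  dy[4] = (inf - y[4]) / tau;
  InfTau kca = cx_kca_m(y[8]);       dy[5] = (kca.inf - y[5]) / kca.tau;
  kin.eval(G_CXHVA_M, VD, inf, tau); dy[6] = (inf - y[6]) / tau;
  kin.eval(G_CXHVA_H, VD, inf, tau); dy[7] = (inf - y[7]) / tau;
  // dendritic currents (densities)
  double ina = p.gNaD * y[1] * y[1] * y[1] * y[2] * (VD - E_NA);
  double inap = p.gNapD * y[3] * (VD - E_NA);
  double ikm = p.gKm * y[4] * (VD - p.EK);
  double ikca = p.gKCa * y[5] * (VD - p.EK);
  double ihva = p.gHVA * y[6] * y[6] * y[7] * (VD - E_CA_HVA);
  double il = p.GL * (VD - p.EL);
  double ikl = gkl_f * p.GKL * (VD - p.EK);
  dy[0] = (-ikl - ina - inap - ikm - ikca - ihva - il
           - p.gcD * (VD - VS) - Isyn + Istim) / p.Cm;
  dy[8] = -CX_CA_DRIVE * ihva + (CX_CA_INF - y[8]) / CX_CA_TAU;
  // axosomatic gates follow the equilibrium voltage
  kin.eval(G_CXNA_M, VS - p.naM_sh, inf, tau);  dy[9] = (inf - y[9]) / tau;
  kin.eval(G_CXNA_H, VS - p.naH_sh, inf, tau);  dy[10] = (inf - y[10]) / tau;
  kin.eval(G_CXK_N, VS - p.kv_sh, inf, tau);    dy[11] = (inf - y[11]) / tau;
  kin.eval(G_CXNAP_M, VS, inf, tau);
  dy[12] = (p.napMax * inf - y[12]) / tau;
}

// ---- Thalamic single-compartment cell ----
// TC state (10): 0 V, 1 mNa, 2 hNa, 3 nK, 4 mT, 5 hT,
//                6 O_h, 7 P1_h, 8 OL_h, 9 Ca
// RE state (7):  0 V, 1 mNa, 2 hNa, 3 nK, 4 mT, 5 hT, 6 Ca
const int NTC = 10, NRE = 7;

struct ThParams {
  double Cm, S;
  double gNa, gK, gT, gh;
  double GL, EL, GKL, EK;
  double Vtr, VtrK, Eh;        // Na / K kinetics shifts; h reversal
  bool is_tc;
};

template <class K>
inline void th_derivs(const ThParams& p, const K& kin, const double* y,
                      double gkl_f, double Isyn, double Istim, double* dy) {
  double V = y[0];
  double v2 = V - p.Vtr;
  double inf, tau;
  kin.eval(G_THNA_M, v2, inf, tau);
  dy[1] = (inf - y[1]) / tau;
  kin.eval(G_THNA_H, v2, inf, tau); dy[2] = (inf - y[2]) / tau;
  kin.eval(G_THK_N, V - p.VtrK, inf, tau); dy[3] = (inf - y[3]) / tau;
  kin.eval(p.is_tc ? G_TCT_M : G_RET_M, V, inf, tau);
  dy[4] = (inf - y[4]) / tau;
  kin.eval(p.is_tc ? G_TCT_H : G_RET_H, V, inf, tau);
  dy[5] = (inf - y[5]) / tau;
  int ica_idx = p.is_tc ? 9 : 6;
  double ca = y[ica_idx];
  double eca = nernst_ca(ca);
  double ina = p.gNa * y[1] * y[1] * y[1] * y[2] * (V - E_NA);
  double ik = p.gK * y[3] * y[3] * y[3] * y[3] * (V - p.EK);
  double it = p.gT * y[4] * y[4] * y[5] * (V - eca);
  double ih = 0.0;
  if (p.is_tc) {
    kin.eval(G_TCH_M, V, inf, tau);
    double al = inf / tau, be = (1.0 - inf) / tau;
    double O = y[6], P1 = y[7], OL = y[8];
    double ca4 = ca * ca * ca * ca;
    dy[6] = al * (1.0 - O - OL) - be * O;
    dy[7] = H_K1 * ca4 * (1.0 - P1) - H_K2 * P1;
    dy[8] = H_K3 * P1 * O - H_K4 * OL;
    ih = p.gh * (O + H_GINC * OL) * (V - p.Eh);
  }
  double il = p.GL * (V - p.EL);
  double ikl = gkl_f * p.GKL * (V - p.EK);
  dy[0] = (-ikl - ina - ik - it - ih - il - Isyn + Istim) / p.Cm;
  dy[ica_idx] = -TH_CA_DRIVE * it + (TH_CA_INF - y[ica_idx]) / TH_CA_TAU;
}

} // namespace tck
#endif
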