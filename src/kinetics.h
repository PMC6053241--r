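// Intrinsic-current gating kinetics and synaptic kinetic constants.
//
// This header is the single record of the adopted rate-function set for
// every intrinsic current of the model lineage this network belongs to
// (two-compartment cortical cells with Mainen-style channels; Traub-style
// thalamic spike currents; Destexhe/Huguenard low-threshold Ca currents;
// McCormick-style h-current; first-order transmitter kinetics with a
// G-protein cascade for GABA-B). Conductances are densities (mS/cm2),
// voltages mV, times ms, Ca in mM.
//
// Temperature scaling: cortical channel time constants are divided by
// QT = 2.3^((36-23)/10) = 2.9529; thalamic spike currents are defined at
// 36 C (factor 1); low-threshold Ca gating uses the classical
// phi_m = 5^((36-24)/10), phi_h = 3^((36-24)/10); the h-current time
// constant is already expressed at body temperature.

#ifndef TCSLEEP_KINETICS_H
#define TCSLEEP_KINETICS_H

#include <cmath>
#include <vector>

namespace tck {

const double QT     = std::pow(2.3, (36.0 - 23.0) / 10.0); // 2.9529
const double PHI_M  = std::pow(5.0, (36.0 - 24.0) / 10.0); // 6.8986
const double PHI_H  = std::pow(3.0, (36.0 - 24.0) / 10.0); // 3.7372

const double E_NA = 50.0, E_CA_HVA = 140.0, E_H = -40.0;

// Reversal potentials of the synaptic receptors (mV).
const double E_AMPA = 0.0, E_NMDA = 0.0, E_GABAA = -70.0, E_GABAB = -95.0;

// First-order transmitter kinetics: [T] = TMAX for TDUR ms after a spike.
const double TMAX = 0.5, TDUR = 0.3;
const double AMPA_ALPHA = 1.1,   AMPA_BETA = 0.19;    // /(mM ms), /ms
const double NMDA_ALPHA = 0.072, NMDA_BETA = 0.0066;
const double GABAA_ALPHA = 5.0,  GABAA_BETA = 0.18;
// GABA-B G-protein cascade (R = activated receptor, G = G protein):
//   R' = K1 [T](1-R) - K2 R;  G' = K3 R - K4 G;  act = G^4/(G^4 + KD)
const double GABAB_K1 = 0.52, GABAB_K2 = 0.0013,
             GABAB_K3 = 0.098, GABAB_K4 = 0.033, GABAB_KD = 100.0;

// NMDA voltage dependence (sigmoidal magnesium-block factor).
inline double nmda_block(double v) { return 1.0 / (1.0 + std::exp(-(v + 25.0) / 12.5)); }

// Calcium pools: dCa/dt = -DRIVE * I_Ca + (CA_INF - Ca)/TAU
// (drive from the surface-to-volume factor of a thin submembrane shell:
//  0.1 um for cortex, 1 um for thalamus).
const double CX_CA_DRIVE = 5.18e-4, CX_CA_INF = 1.0e-4, CX_CA_TAU = 200.0;
const double TH_CA_DRIVE = 5.18e-5, TH_CA_INF = 2.4e-4, TH_CA_TAU = 5.0;

inline double nernst_ca(double cai) {          // E_Ca at 36 C, [Ca]_o = 2 mM
  if (cai < 1e-6) cai = 1e-6;
  return 13.3264 * std::log(2.0 / cai);
}

// x/(1 - exp(-x/y)), stable near x = 0.
inline double trap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - r / 2.0);
  return x / (1.0 - std::exp(-r));
}

struct InfTau { double inf, tau; };

// ---- Cortical fast sodium (axosomatic and dendritic) ----
inline InfTau cx_na_m(double v) {
  double a = 0.182 * trap(v + 35.0, 9.0);
  double b = 0.124 * trap(-(v + 35.0), 9.0);
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}
inline InfTau cx_na_h(double v) {
  double a = 0.024 * trap(v + 50.0, 5.0);
  double b = 0.0091 * trap(-(v + 75.0), 5.0);
  // steep steady-state inactivation keeps the window current small above
  // -40 mV (no depolarized equilibrium in the reduced soma)
  double inf = 1.0 / (1.0 + std::exp((v + 65.0) / 5.0));
  return { inf, 1.0 / ((a + b) * QT) };
}
// ---- Cortical fast potassium (axosomatic) ----
// Half-activation near 5 mV: low enough that the rectifier beats the
// sodium window current above -40 mV (a purely high-threshold rectifier
// leaves the instantaneous-soma reduction with a spurious stable
// depolarized equilibrium), high enough to contribute no standing
// current at rest.
inline InfTau cx_k_n(double v) {
  double a = 0.02 * trap(v - 5.0, 9.0);
  double b = 0.002 * trap(-(v - 5.0), 9.0);
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}
// ---- Persistent sodium (PY only); low maximal open fraction ----
// The maximal open fraction (a cell parameter, nap_max) controls the
// regenerative depolarized plateau: placed just below the reach of the
// calcium-activated potassium conductance it turns sustained
// depolarizations into terminating Up-like plateaus rather than
// permanent latch-up.
inline InfTau cx_nap_m(double v) {
  return { 1.0 / (1.0 + std::exp(-(v + 42.0) / 5.0)), 0.2 };
}
// ---- Slow non-inactivating potassium (dendritic) ----
inline InfTau cx_km_n(double v) {
  double a = 0.001 * trap(v + 30.0, 9.0);
  double b = 0.001 * trap(-(v + 30.0), 9.0);
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}
// ---- High-threshold calcium (dendritic), m^2 h ----
inline InfTau cx_hva_m(double v) {
  double a = 0.055 * trap(v + 27.0, 3.8);
  double b = 0.94 * std::exp((-75.0 - v) / 17.0);
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}
inline InfTau cx_hva_h(double v) {
  double a = 0.000457 * std::exp((-13.0 - v) / 50.0);
  double b = 0.0065 / (std::exp((-15.0 - v) / 28.0) + 1.0);
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}
// ---- Calcium-dependent potassium (dendritic); rate from [Ca], not V ----
inline InfTau cx_kca_m(double ca) {
  double a = 0.01 * ca * 1000.0;   // Ca in mM; rate constant per uM
  double b = 0.02;
  return { a / (a + b), 1.0 / ((a + b) * QT) };
}

// ---- Thalamic fast sodium / potassium (Traub kinetics) ----
// The spike-current threshold placement V_tr is a cell parameter
// (defaults in the R-level parameter tables); kinetics are expressed in
// threshold-relative coordinates v2 = V - V_tr.
inline InfTau th_na_m(double v) {    // v already threshold-relative
  double a = 0.32 * trap(v - 13.0, 4.0);
  double b = 0.28 * trap(40.0 - v, 5.0);
  return { a / (a + b), 1.0 / (a + b) };
}
inline InfTau th_na_h(double v) {
  double a = 0.128 * std::exp((17.0 - v) / 18.0);
  double b = 4.0 / (1.0 + std::exp((40.0 - v) / 5.0));
  return { a / (a + b), 1.0 / (a + b) };
}
inline InfTau th_k_n(double v) {
  double a = 0.032 * trap(v - 15.0, 5.0);
  double b = 0.5 * std::exp((10.0 - v) / 40.0);
  return { a / (a + b), 1.0 / (a + b) };
}

// ---- Low-threshold calcium, relay cells, m^2 h ----
inline InfTau tc_t_m(double v) {
  double inf = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
  double tau = (0.612 + 1.0 / (std::exp(-(v + 131.6) / 16.7) +
                               std::exp((v + 16.8) / 18.2))) / PHI_M;
  return { inf, tau };
}
inline InfTau tc_t_h(double v) {
  double inf = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
  double tau = (v < -81.0)
    ? std::exp((v + 467.0) / 66.6) / PHI_H
    : (28.0 + std::exp(-(v + 21.88) / 10.2)) / PHI_H;
  return { inf, tau };
}
// ---- Low-threshold calcium, reticular cells, m^2 h ----
inline InfTau re_t_m(double v) {
  double inf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4));
  double tau = (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) +
                             std::exp(-(v + 102.0) / 15.0))) / PHI_M;
  return { inf, tau };
}
inline InfTau re_t_h(double v) {
  double inf = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
  double tau = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) +
                              std::exp(-(v + 407.0) / 50.0))) / PHI_H;
  return { inf, tau };
}

// ---- Hyperpolarization-activated cation current (TC only) ----
// Activation midpoint shifted by the histamine level of the stage.
// The channel carries a calcium-regulated open/locked-open scheme
// (calcium-bound protein P1 locks open channels into OL with conductance
// factor GINC): the slow negative feedback that terminates spindle
// sequences and sets their 2-20 s recurrence.
inline InfTau tc_h_m(double v, double ha_gh) {
  double inf = 1.0 / (1.0 + std::exp((v + 75.0 + ha_gh) / 5.5));
  double tau = 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) +
                                std::exp(-(v + 89.0) / 11.6));
  return { inf, tau };
}
const double H_K2 = 4.0e-4;                    // /ms, P1 unbinding
const double H_CAC = 0.002;                    // mM, half-binding Ca
const double H_K1 = H_K2 / (H_CAC * H_CAC * H_CAC * H_CAC);
const double H_K4 = 1.0e-3;                    // /ms, unlock
const double H_K3 = 0.1;                       // /ms, lock (k4 / Pc)
const double H_GINC = 2.0;                     // locked-state conductance

// ---- Lookup tables: x_inf and tau on a uniform voltage grid ----
struct RateTab {
  double v0 = -150.0, dv = 0.05;
  int n = 0;
  std::vector<double> inf, tau;
  // range covers absolute voltages and threshold-relative coordinates
  template <class F> void build(F f, double vmax = 160.0) {
    n = (int)((vmax - v0) / dv) + 1;
    inf.resize(n); tau.resize(n);
    for (int i = 0; i < n; ++i) {
      InfTau it = f(v0 + dv * i);
      inf[i] = it.inf; tau[i] = it.tau;
    }
  }
  inline void eval(double v, double& xi, double& ta) const {
    double u = (v - v0) / dv;
    if (u <= 0.0) { xi = inf[0]; ta = tau[0]; return; }
    if (u >= n - 1.0) { xi = inf[n - 1]; ta = tau[n - 1]; return; }
    int k = (int)u; double f = u - k;
    xi = inf[k] + f * (inf[k + 1] - inf[k]);
    ta = tau[k] + f * (tau[k + 1] - tau[k]);
  }
};

} // namespace tck
#endif
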