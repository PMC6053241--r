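// Network integration engine: fixed-step RK4 over the full thalamocortical
// network, with spike detection on upward zero crossings, miniature-PSP
// Poisson processes (thinning sampler), online symmetric STDP on the
// plastic projection, stage scheduling, stimulation protocols, and
// recorders (spike raster, LFP = mean pyramidal dendritic voltage, weight
// snapshots).

#include <Rcpp.h>
#include <cstring>
#include "model.h"

using namespace Rcpp;
using namespace tck;

static const double MU_MAX = 1.0 / 250.0; // mini-rate asymptote, per ms
static const double REFRACT = 2.0;        // spike-registration refractory, ms
static const double V_ABORT = 500.0;      // blow-up guard, mV

struct Proj {
  std::string name;
  int src, tgt, rec;                 // populations 0..3; receptor 0..3
  std::vector<int> pre, post;        // 0-based
  std::vector<double> w, w0, ma, ma0;
  std::vector<double> factor;        // stage factor per stage bundle
  bool mini = false, stdp = false;
  double mini_F = 30.0;
  std::vector<double> mini_factor;   // stage scaling of mini amplitudes
  int gate = -1;                     // index into engine gate list
  int mini_block = -1;               // index into engine mini blocks
  // CSR adjacency for the plastic projection
  std::vector<int> bypost_start, bypost_idx, bypre_start, bypre_idx;
  double next_mini = R_PosInf;
};

struct GateSet { int src, rec, n, off; };     // off: state offset (R,G for GABAB)
struct MiniBlock { int tgt, rec, off, n; double conv; };

struct StageBundle {
  double gkl[4];
  double ha_gh;
  double A_plus, A_minus, tau_plus, tau_minus, f_mini, bound;
};

struct Stim { int pop, idx; double t_on, t_off, amp; };

enum { AMPA = 0, NMDA = 1, GABAA = 2, GABAB = 3 };
enum { PY = 0, IN = 1, TC = 2, RE = 3 };

struct Engine {
  int n[4];
  CxParams cx[2];
  ThParams th[2];
  std::vector<Proj> projections;
  std::vector<GateSet> gates;
  std::vector<MiniBlock> minis;
  std::vector<StageBundle> stages;
  std::vector<int> sched_stage;      // per schedule segment
  std::vector<double> sched_end;     // segment end times (ms)
  std::vector<Stim> stim;
  double dt, t_total, stdp_gmax, mini_ref_amp;
  double bg_rate = 0.0, bg_amp = 0.0;   // background barrages: Hz/cell, uS
  int bg_radius = 5;                    // half-width of one barrage
  int bg_block = -1;                    // PY AMPA conductance block
  double next_bg = R_PosInf;
  int lfp_every;
  double snap_ms;
  bool plastic, minis_on;
  TabKin kin;

  int off_pop[4], nv_pop[4];         // state offsets / vars per cell
  int nstate = 0;
  std::vector<double> y, k1, k2, k3, k4, yt;
  std::vector<double> vs_now[2];     // axosomatic voltages (PY, IN)
  std::vector<double> last_spike[4];
  std::vector<double> inj[4];        // stimulation current densities
  std::vector<double> acc[4][4];     // synaptic conductance accumulators
  std::vector<double> gb_act;        // GABAB activation scratch
  int cur_stage = 0, cur_seg = 0;
  size_t stim_ptr = 0;
  std::vector<int> stim_active;

  // recorders
  std::vector<int> spk_pop, spk_idx;
  std::vector<double> spk_t;
  std::vector<double> lfp;
  std::vector<double> snap_t;
  std::vector<std::vector<double>> snaps, snaps_ma;
  std::vector<std::pair<int,int>> vrec_cells;
  std::vector<std::vector<double>> vrec;

  int state_vars(int pop) { return pop <= IN ? NCX : (pop == TC ? NTC : NRE); }

  void layout() {
    nstate = 0;
    for (int p = 0; p < 4; ++p) {
      off_pop[p] = nstate;
      nv_pop[p] = state_vars(p);
      nstate += n[p] * nv_pop[p];
    }
    for (auto& g : gates) {
      g.off = nstate;
      nstate += g.n * (g.rec == GABAB ? 2 : 1);
    }
    for (auto& m : minis) {
      m.off = nstate;
      nstate += m.n;
    }
    y.assign(nstate, 0.0);
    k1 = k2 = k3 = k4 = yt = y;
    for (int p = 0; p < 2; ++p) vs_now[p].assign(n[p], -68.0);
    for (int p = 0; p < 4; ++p) {
      last_spike[p].assign(n[p], -1e9);
      inj[p].assign(n[p], 0.0);
      for (int r = 0; r < 4; ++r) acc[p][r].assign(n[p], 0.0);
    }
  }

  double* cell(std::vector<double>& v, int pop, int i) {
    return v.data() + off_pop[pop] + i * nv_pop[pop];
  }

  void init_state(double v0[4], double jitter) {
    DirectKin dk; dk.ha_gh = stages[cur_stage].ha_gh;
    for (int p = 0; p < 4; ++p) {
      for (int i = 0; i < n[p]; ++i) {
        double* s = cell(y, p, i);
        double v = v0[p] + jitter * (2.0 * R::unif_rand() - 1.0);
        if (p <= IN) {
          const CxParams& cp = cx[p];
          s[0] = v;
          double inf, tau;
          dk.eval(G_CXNA_M, v - cp.naM_sh, inf, tau);  s[1] = inf;
          dk.eval(G_CXNA_H, v - cp.naH_sh, inf, tau);  s[2] = inf;
          dk.eval(G_CXNAP_M, v, inf, tau); s[3] = cp.napMax * inf;
          dk.eval(G_CXKM_N, v, inf, tau);  s[4] = inf;
          s[5] = cx_kca_m(CX_CA_INF).inf;
          dk.eval(G_CXHVA_M, v, inf, tau); s[6] = inf;
          dk.eval(G_CXHVA_H, v, inf, tau); s[7] = inf;
          s[8] = CX_CA_INF;
          s[9] = s[1];
          s[10] = s[2];
          dk.eval(G_CXK_N, v - cp.kv_sh, inf, tau);   s[11] = inf;
          s[12] = s[3];
          vs_now[p][i] = v;
        } else {
          s[0] = v;
          double vr = v - th[p - TC].Vtr;
          double inf, tau;
          dk.eval(G_THNA_M, vr, inf, tau); s[1] = inf;
          dk.eval(G_THNA_H, vr, inf, tau); s[2] = inf;
          dk.eval(G_THK_N, v - th[p - TC].VtrK, inf, tau); s[3] = inf;
          dk.eval(p == TC ? G_TCT_M : G_RET_M, v, inf, tau); s[4] = inf;
          dk.eval(p == TC ? G_TCT_H : G_RET_H, v, inf, tau); s[5] = inf;
          if (p == TC) {
            dk.eval(G_TCH_M, v, inf, tau);
            s[6] = inf;       // open fraction at steady state
            s[7] = 0.0;       // calcium-bound protein
            s[8] = 0.0;       // locked-open fraction
            s[9] = TH_CA_INF;
          } else s[6] = TH_CA_INF;
        }
      }
    }
  }

  // mini conductances enter the target current via the accumulators:
  // cheaper to add them at gather time. They are added directly in rhs by
  // folding into acc before the per-cell loop.
  void add_minis_to_acc(std::vector<double>& yy) {
    for (auto& m : minis)
      for (int i = 0; i < m.n; ++i)
        acc[m.tgt][m.rec][i] += yy[m.off + i];
  }

  void step(double t) {
    rhs_main(t, y, k1);
    axpy(yt, y, k1, dt / 2.0);
    rhs_main(t + dt / 2.0, yt, k2);
    axpy(yt, y, k2, dt / 2.0);
    rhs_main(t + dt / 2.0, yt, k3);
    axpy(yt, y, k3, dt);
    rhs_main(t + dt, yt, k4);
    for (int i = 0; i < nstate; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    clamp_gates();
  }

  void rhs_main(double t, std::vector<double>& yy, std::vector<double>& dy);

  void axpy(std::vector<double>& out, const std::vector<double>& a,
            const std::vector<double>& b, double h) {
    for (int i = 0; i < nstate; ++i) out[i] = a[i] + h * b[i];
  }

  void clamp_gates() {
    // gating variables live in [0,1]; clamp roundoff excursions
    for (int p = 0; p < 4; ++p) {
      int ca_idx = p <= IN ? 8 : (p == TC ? 9 : 6);
      for (int i = 0; i < n[p]; ++i) {
        double* s = cell(y, p, i);
        for (int v = 1; v < nv_pop[p]; ++v) {
          if (v == ca_idx) { if (s[v] < 0) s[v] = 0; continue; }
          if (s[v] < 0) s[v] = 0;
          else if (s[v] > 1) s[v] = 1;
        }
      }
    }
    for (auto& g : gates) {
      int nn = g.n * (g.rec == GABAB ? 2 : 1);
      for (int i = 0; i < nn; ++i) {
        double& v = y[g.off + i];
        if (v < 0) v = 0;
        else if (g.rec != GABAB && v > 1) v = 1;
      }
    }
    for (auto& m : minis)
      for (int i = 0; i < m.n; ++i)
        if (y[m.off + i] < 0) y[m.off + i] = 0;
  }

  void run();
  void sample_background(double t0, double t1);
  void detect_spikes(double t_new, std::vector<double>& vprev_cx0,
                     std::vector<double>& vprev_cx1,
                     std::vector<double>& vprev_th0,
                     std::vector<double>& vprev_th1);
  void do_stdp(int neuron, double t);
  void sample_minis(double t0, double t1);
  void advance_stim(double t);
};

void Engine::rhs_main(double t, std::vector<double>& yy,
                      std::vector<double>& dy) {
  const StageBundle& st = stages[cur_stage];
  for (int p = 0; p < 2; ++p)
    for (int i = 0; i < n[p]; ++i)
      vs_now[p][i] = cx_solve_vs(cx[p], cell(yy, p, i)[0], cell(yy, p, i));
  for (int p = 0; p < 4; ++p)
    for (int r = 0; r < 4; ++r)
      if (n[p] > 0)
        std::memset(acc[p][r].data(), 0, sizeof(double) * n[p]);
  for (auto& pr : projections) {
    double f = pr.factor[cur_stage];
    const GateSet& g = gates[pr.gate];
    double* tacc = acc[pr.tgt][pr.rec].data();
    const int* pre = pr.pre.data();
    const int* post = pr.post.data();
    const double* w = pr.w.data();
    size_t ns = pr.pre.size();
    if (pr.rec == GABAB) {
      if ((int)gb_act.size() < g.n) gb_act.assign(g.n, 0.0);
      for (int i = 0; i < g.n; ++i) {
        double G = yy[g.off + g.n + i];
        double g4 = G * G * G * G;
        gb_act[i] = g4 / (g4 + GABAB_KD);
      }
      for (size_t s = 0; s < ns; ++s)
        tacc[post[s]] += f * w[s] * gb_act[pre[s]];
    } else {
      const double* O = yy.data() + g.off;
      for (size_t s = 0; s < ns; ++s)
        tacc[post[s]] += f * w[s] * O[pre[s]];
    }
  }
  add_minis_to_acc(yy);
  for (int p = 0; p < 2; ++p) {
    const CxParams& P = cx[p];
    double sconv = 1e-3 / P.S_dend;
    for (int i = 0; i < n[p]; ++i) {
      double* s = cell(yy, p, i);
      double* d = cell(dy, p, i);
      double VD = s[0];
      double isyn = (acc[p][AMPA][i] * (VD - E_AMPA) +
                     acc[p][NMDA][i] * nmda_block(VD) * (VD - E_NMDA) +
                     acc[p][GABAA][i] * (VD - E_GABAA) +
                     acc[p][GABAB][i] * (VD - E_GABAB)) * sconv;
      cx_derivs(P, kin, s, vs_now[p][i], st.gkl[p], isyn, inj[p][i], d);
    }
  }
  for (int p = TC; p <= RE; ++p) {
    const ThParams& P = th[p - TC];
    double sconv = 1e-3 / P.S;
    for (int i = 0; i < n[p]; ++i) {
      double* s = cell(yy, p, i);
      double* d = cell(dy, p, i);
      double V = s[0];
      double isyn = (acc[p][AMPA][i] * (V - E_AMPA) +
                     acc[p][NMDA][i] * nmda_block(V) * (V - E_NMDA) +
                     acc[p][GABAA][i] * (V - E_GABAA) +
                     acc[p][GABAB][i] * (V - E_GABAB)) * sconv;
      th_derivs(P, kin, s, st.gkl[p], isyn, inj[p][i], d);
    }
  }
  for (auto& g : gates) {
    const std::vector<double>& ls = last_spike[g.src];
    if (g.rec == GABAB) {
      for (int i = 0; i < g.n; ++i) {
        double tt = t - ls[i];
        double T = (tt >= 0 && tt < TDUR) ? TMAX : 0.0;
        double Rv = yy[g.off + i], Gv = yy[g.off + g.n + i];
        dy[g.off + i] = GABAB_K1 * T * (1.0 - Rv) - GABAB_K2 * Rv;
        dy[g.off + g.n + i] = GABAB_K3 * Rv - GABAB_K4 * Gv;
      }
    } else {
      double al = g.rec == AMPA ? AMPA_ALPHA :
                  g.rec == NMDA ? NMDA_ALPHA : GABAA_ALPHA;
      double be = g.rec == AMPA ? AMPA_BETA :
                  g.rec == NMDA ? NMDA_BETA : GABAA_BETA;
      for (int i = 0; i < g.n; ++i) {
        double tt = t - ls[i];
        double T = (tt >= 0 && tt < TDUR) ? TMAX : 0.0;
        double O = yy[g.off + i];
        dy[g.off + i] = al * T * (1.0 - O) - be * O;
      }
    }
  }
  for (auto& m : minis) {
    double be = m.rec == GABAA ? GABAA_BETA : AMPA_BETA;
    for (int i = 0; i < m.n; ++i)
      dy[m.off + i] = -be * yy[m.off + i];
  }
}

void Engine::do_stdp(int j, double t) {
  for (auto& pr : projections) {
    if (!pr.stdp) continue;
    const StageBundle& st = stages[cur_stage];
    // this spike as POSTsynaptic: potentiate afferent synapses
    for (int k = pr.bypost_start[j]; k < pr.bypost_start[j + 1]; ++k) {
      int s = pr.bypost_idx[k];
      double dtau = t - last_spike[pr.src][pr.pre[s]];
      if (dtau > 0 && dtau < 1e4) {
        double F = st.A_plus * std::exp(-dtau / st.tau_plus);
        pr.w[s] = std::min(pr.w[s] + stdp_gmax * F, st.bound * pr.w0[s]);
        if (!pr.ma.empty())
          pr.ma[s] = std::min(pr.ma[s] + st.f_mini * mini_ref_amp * F,
                              st.bound * pr.ma0[s]);
      }
    }
    // this spike as PREsynaptic: depress efferent synapses
    for (int k = pr.bypre_start[j]; k < pr.bypre_start[j + 1]; ++k) {
      int s = pr.bypre_idx[k];
      double dtau = last_spike[pr.tgt][pr.post[s]] - t;
      if (dtau < 0 && dtau > -1e4) {
        double F = -st.A_minus * std::exp(dtau / st.tau_minus);
        pr.w[s] = std::max(pr.w[s] + stdp_gmax * F, 0.0);
        if (!pr.ma.empty())
          pr.ma[s] = std::max(pr.ma[s] + st.f_mini * mini_ref_amp * F, 0.0);
      }
    }
  }
}

// Sparse suprathreshold background barrages onto local groups of
// pyramidal cells (afferents from outside the simulated patch),
// delivered through the same decaying AMPA-type conductance as the
// miniature PSPs. One event excites the cells within bg_radius of a
// uniformly drawn centre; whether the stimulated group recruits its
// neighbours is then decided by the stage-dependent synaptic factors.
void Engine::sample_background(double t0, double t1) {
  if (bg_rate <= 0.0 || bg_block < 0 || n[PY] == 0) return;
  int width = 2 * bg_radius + 1;
  double lambda = bg_rate * 1e-3 * n[PY] / width;   // events/ms, population
  if (next_bg == R_PosInf) next_bg = t0 + R::exp_rand() / lambda;
  while (next_bg < t1) {
    int c = (int)(R::unif_rand() * n[PY]);
    if (c >= n[PY]) c = n[PY] - 1;
    const MiniBlock& m = minis[bg_block];
    for (int i = std::max(0, c - bg_radius);
         i <= std::min(n[PY] - 1, c + bg_radius); ++i)
      y[m.off + i] += bg_amp;
    next_bg += R::exp_rand() / lambda;
  }
}

void Engine::sample_minis(double t0, double t1) {
  for (auto& pr : projections) {
    if (!pr.mini) continue;
    size_t ns = pr.pre.size();
    if (!ns) continue;
    double lambda = ns * MU_MAX;
    if (pr.next_mini == R_PosInf)
      pr.next_mini = t0 + R::exp_rand() / lambda;
    while (pr.next_mini < t1) {
      double te = pr.next_mini;
      int s = (int)(R::unif_rand() * ns);
      if (s >= (int)ns) s = ns - 1;
      double ls = last_spike[pr.src][pr.pre[s]];
      double mu = 0.0;
      if (te > ls) mu = (2.0 / (1.0 + std::exp(-(te - ls) / pr.mini_F)) - 1.0) / 250.0;
      if (R::unif_rand() * MU_MAX < mu) {
        const MiniBlock& m = minis[pr.mini_block];
        double amp = pr.ma.empty() ? mini_ref_amp : pr.ma[s];
        double f = pr.mini_factor.empty() ? 1.0 : pr.mini_factor[cur_stage];
        y[m.off + pr.post[s]] += f * amp * m.conv;
      }
      pr.next_mini += R::exp_rand() / lambda;
    }
  }
}

void Engine::advance_stim(double t) {
  while (stim_ptr < stim.size() && stim[stim_ptr].t_on <= t) {
    const Stim& s = stim[stim_ptr];
    if (s.t_off > t) {
      inj[s.pop][s.idx] += s.amp;
      stim_active.push_back((int)stim_ptr);
    }
    ++stim_ptr;
  }
  for (size_t a = 0; a < stim_active.size();) {
    const Stim& s = stim[stim_active[a]];
    if (s.t_off <= t) {
      inj[s.pop][s.idx] -= s.amp;
      stim_active[a] = stim_active.back();
      stim_active.pop_back();
    } else ++a;
  }
}

void Engine::run() {
  long nsteps = (long)std::llround(t_total / dt);
  std::vector<double> vprev0(vs_now[0]), vprev1(vs_now[1]);
  std::vector<double> vprevT(n[TC]), vprevR(n[RE]);
  for (int i = 0; i < n[TC]; ++i) vprevT[i] = cell(y, TC, i)[0];
  for (int i = 0; i < n[RE]; ++i) vprevR[i] = cell(y, RE, i)[0];
  double next_snap = 0.0;
  std::vector<int> spk_buf_pop, spk_buf_idx;
  for (long it = 0; it < nsteps; ++it) {
    double t = it * dt;
    // stage switching
    while (cur_seg < (int)sched_end.size() - 1 && t >= sched_end[cur_seg]) {
      ++cur_seg;
      if (sched_stage[cur_seg] != cur_stage) {
        cur_stage = sched_stage[cur_seg];
        kin.rebuild_h(stages[cur_stage].ha_gh);
      }
    }
    advance_stim(t);
    // recorders
    if (lfp_every > 0 && it % lfp_every == 0) {
      double m = 0.0;
      for (int i = 0; i < n[PY]; ++i) m += cell(y, PY, i)[0];
      lfp.push_back(n[PY] ? m / n[PY] : 0.0);
      for (size_t c = 0; c < vrec_cells.size(); ++c) {
        int p = vrec_cells[c].first, i = vrec_cells[c].second;
        vrec[c].push_back(p <= IN ? vs_now[p][i] : cell(y, p, i)[0]);
      }
    }
    if (snap_ms > 0 && t >= next_snap) {
      for (auto& pr : projections)
        if (pr.stdp) {
          snap_t.push_back(t);
          snaps.push_back(pr.w);
          snaps_ma.push_back(pr.ma);
        }
      next_snap += snap_ms;
    }
    if (minis_on) sample_minis(t, t + dt);
    sample_background(t, t + dt);
    step(t);
    double t_new = t + dt;
    // spike detection on upward zero crossing
    spk_buf_pop.clear(); spk_buf_idx.clear();
    for (int p = 0; p < 2; ++p) {
      std::vector<double>& vp = p == 0 ? vprev0 : vprev1;
      for (int i = 0; i < n[p]; ++i) {
        double v = cx_solve_vs(cx[p], cell(y, p, i)[0], cell(y, p, i));
        if (v >= 0.0 && vp[i] < 0.0 && t_new - last_spike[p][i] > REFRACT) {
          spk_buf_pop.push_back(p); spk_buf_idx.push_back(i);
        }
        vp[i] = v;
        if (!(std::fabs(cell(y, p, i)[0]) <= V_ABORT))
          stop("numerical blow-up: |V| > 500 mV in population %d, neuron %d, t = %.2f ms",
               p, i + 1, t_new);
      }
    }
    for (int p = TC; p <= RE; ++p) {
      std::vector<double>& vp = p == TC ? vprevT : vprevR;
      for (int i = 0; i < n[p]; ++i) {
        double v = cell(y, p, i)[0];
        if (v >= 0.0 && vp[i] < 0.0 && t_new - last_spike[p][i] > REFRACT) {
          spk_buf_pop.push_back(p); spk_buf_idx.push_back(i);
        }
        vp[i] = v;
        if (!(std::fabs(v) <= V_ABORT))
          stop("numerical blow-up: |V| > 500 mV in population %d, neuron %d, t = %.2f ms",
               p, i + 1, t_new);
      }
    }
    // STDP first (uses pre-update last-spike times), then register
    if (plastic)
      for (size_t s = 0; s < spk_buf_pop.size(); ++s)
        if (spk_buf_pop[s] == PY) do_stdp(spk_buf_idx[s], t_new);
    for (size_t s = 0; s < spk_buf_pop.size(); ++s) {
      int p = spk_buf_pop[s], i = spk_buf_idx[s];
      last_spike[p][i] = t_new;
      spk_pop.push_back(p); spk_idx.push_back(i + 1);
      spk_t.push_back(t_new);
    }
    if (it % 50000 == 0) Rcpp::checkUserInterrupt();
  }
  // final snapshot
  if (snap_ms > 0)
    for (auto& pr : projections)
      if (pr.stdp) {
        snap_t.push_back(t_total);
        snaps.push_back(pr.w);
        snaps_ma.push_back(pr.ma);
      }
}

// ---------- R interface ----------

static CxParams cx_from_list(List p) {
  CxParams c;
  double Ssoma = as<double>(p["S_soma"]), rho = as<double>(p["rho"]);
  c.Cm = as<double>(p["C_m"]);
  c.S_soma = Ssoma;
  c.S_dend = rho * Ssoma;
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
  double gc_uS = 1.0 / as<double>(p["kappa_Mohm"]); // uS
  c.gcD = gc_uS * 1e-3 / c.S_dend;                  // mS/cm2
  c.gcS = gc_uS * 1e-3 / c.S_soma;
  c.naM_sh = as<double>(p["na_m_mid"]) + 35.0;
  c.naH_sh = as<double>(p["na_h_mid"]) + 65.0;
  c.kv_sh = as<double>(p["kv_mid"]) - 5.0;
  c.napMax = as<double>(p["nap_max"]);
  return c;
}

static ThParams th_from_list(List p, bool is_tc) {
  ThParams t;
  t.Cm = as<double>(p["C_m"]);
  t.S = as<double>(p["S"]);
  t.gNa = as<double>(p["g_Na"]);
  t.gK = as<double>(p["g_K"]);
  t.gT = as<double>(p["g_T"]);
  t.gh = as<double>(p["g_h"]);
  t.GL = as<double>(p["G_L"]);
  t.EL = as<double>(p["E_L"]);
  t.GKL = as<double>(p["G_KL"]);
  t.EK = as<double>(p["E_K"]);
  t.Vtr = as<double>(p["V_tr"]);
  t.VtrK = as<double>(p["V_trK"]);
  t.Eh = as<double>(p["E_h"]);
  t.is_tc = is_tc;
  return t;
}

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List cfg) {
  Engine E;
  List pops = cfg["pops"];
  IntegerVector nn = cfg["n"];
  for (int p = 0; p < 4; ++p) E.n[p] = nn[p];
  E.cx[0] = cx_from_list(pops["PY"]);
  E.cx[1] = cx_from_list(pops["IN"]);
  E.th[0] = th_from_list(pops["TC"], true);
  E.th[1] = th_from_list(pops["RE"], false);

  List stg = cfg["stages"];
  for (int k = 0; k < stg.size(); ++k) {
    List s = stg[k];
    StageBundle b;
    NumericVector g = s["gkl"];
    for (int p = 0; p < 4; ++p) b.gkl[p] = g[p];
    b.ha_gh = as<double>(s["ha_gh"]);
    b.A_plus = as<double>(s["A_plus"]);
    b.A_minus = as<double>(s["A_minus"]);
    b.tau_plus = as<double>(s["tau_plus"]);
    b.tau_minus = as<double>(s["tau_minus"]);
    b.f_mini = as<double>(s["f"]);
    b.bound = as<double>(s["bound"]);
    E.stages.push_back(b);
  }
  NumericMatrix sched = cfg["schedule"];
  for (int i = 0; i < sched.nrow(); ++i) {
    E.sched_stage.push_back((int)sched(i, 0));
    E.sched_end.push_back(sched(i, 1));
  }
  E.cur_stage = E.sched_stage.empty() ? 0 : E.sched_stage[0];

  // projections and shared gate sets
  List prjs = cfg["projections"];
  std::map<int, int> gate_map;
  for (int k = 0; k < prjs.size(); ++k) {
    List pl = prjs[k];
    Proj pr;
    pr.name = as<std::string>(pl["name"]);
    pr.src = as<int>(pl["src"]);
    pr.tgt = as<int>(pl["tgt"]);
    pr.rec = as<int>(pl["rec"]);
    pr.pre = as<std::vector<int>>(pl["pre"]);
    pr.post = as<std::vector<int>>(pl["post"]);
    pr.w = as<std::vector<double>>(pl["w"]);
    pr.w0 = pr.w;
    if (pl.containsElementNamed("ma") && !Rf_isNull(pl["ma"])) {
      pr.ma = as<std::vector<double>>(pl["ma"]);
      pr.ma0 = pr.ma;
    }
    pr.factor = as<std::vector<double>>(pl["factor"]);
    pr.mini = as<bool>(pl["mini"]);
    pr.stdp = as<bool>(pl["stdp"]);
    if (pl.containsElementNamed("mini_factor") && !Rf_isNull(pl["mini_factor"]))
      pr.mini_factor = as<std::vector<double>>(pl["mini_factor"]);
    int key = pr.src * 10 + pr.rec;
    if (gate_map.find(key) == gate_map.end()) {
      GateSet g; g.src = pr.src; g.rec = pr.rec; g.n = E.n[pr.src]; g.off = 0;
      gate_map[key] = (int)E.gates.size();
      E.gates.push_back(g);
    }
    pr.gate = gate_map[key];
    E.projections.push_back(pr);
  }
  // mini blocks per (tgt, rec); conversion factor (uS per mV of PSP
  // amplitude) supplied per projection
  std::map<int, int> mini_map;
  for (size_t k = 0; k < E.projections.size(); ++k) {
    Proj& pr = E.projections[k];
    if (!pr.mini) continue;
    List pl = as<List>(as<List>(cfg["projections"])[k]);
    double conv = as<double>(pl["mini_conv"]);
    int key = pr.tgt * 10 + pr.rec;
    if (mini_map.find(key) == mini_map.end()) {
      MiniBlock m;
      m.tgt = pr.tgt; m.rec = pr.rec; m.n = E.n[pr.tgt];
      m.conv = conv;
      mini_map[key] = (int)E.minis.size();
      E.minis.push_back(m);
    }
    pr.mini_block = mini_map[key];
  }
  // STDP adjacency
  for (auto& pr : E.projections) {
    if (!pr.stdp) continue;
    int npre = E.n[pr.src], npost = E.n[pr.tgt];
    pr.bypost_start.assign(npost + 1, 0);
    pr.bypre_start.assign(npre + 1, 0);
    for (size_t s = 0; s < pr.post.size(); ++s) {
      pr.bypost_start[pr.post[s] + 1]++;
      pr.bypre_start[pr.pre[s] + 1]++;
    }
    for (int i = 0; i < npost; ++i) pr.bypost_start[i + 1] += pr.bypost_start[i];
    for (int i = 0; i < npre; ++i) pr.bypre_start[i + 1] += pr.bypre_start[i];
    pr.bypost_idx.resize(pr.post.size());
    pr.bypre_idx.resize(pr.pre.size());
    std::vector<int> c1(pr.bypost_start.begin(), pr.bypost_start.end());
    std::vector<int> c2(pr.bypre_start.begin(), pr.bypre_start.end());
    for (size_t s = 0; s < pr.post.size(); ++s) {
      pr.bypost_idx[c1[pr.post[s]]++] = (int)s;
      pr.bypre_idx[c2[pr.pre[s]]++] = (int)s;
    }
  }

  NumericMatrix stim = cfg["stim"];
  for (int i = 0; i < stim.nrow(); ++i) {
    Stim s;
    s.pop = (int)stim(i, 0);
    s.idx = (int)stim(i, 1);
    s.t_on = stim(i, 2);
    s.t_off = stim(i, 3);
    s.amp = stim(i, 4);
    E.stim.push_back(s);
  }
  std::sort(E.stim.begin(), E.stim.end(),
            [](const Stim& a, const Stim& b) { return a.t_on < b.t_on; });

  E.dt = as<double>(cfg["dt"]);
  E.t_total = as<double>(cfg["t_total"]);
  E.lfp_every = as<int>(cfg["lfp_every"]);
  E.snap_ms = as<double>(cfg["snap_ms"]);
  E.stdp_gmax = as<double>(cfg["stdp_gmax"]);
  E.mini_ref_amp = as<double>(cfg["mini_ref_amp"]);
  E.plastic = as<bool>(cfg["plastic"]);
  E.minis_on = as<bool>(cfg["minis"]);
  E.bg_rate = as<double>(cfg["bg_rate"]);
  E.bg_amp = as<double>(cfg["bg_amp"]);
  E.bg_radius = as<int>(cfg["bg_radius"]);
  for (size_t b = 0; b < E.minis.size(); ++b)
    if (E.minis[b].tgt == PY && E.minis[b].rec == AMPA)
      E.bg_block = (int)b;

  if (cfg.containsElementNamed("vrec") && !Rf_isNull(cfg["vrec"])) {
    NumericMatrix vr = cfg["vrec"];
    for (int i = 0; i < vr.nrow(); ++i)
      E.vrec_cells.push_back({(int)vr(i, 0), (int)vr(i, 1)});
    E.vrec.resize(E.vrec_cells.size());
  }

  E.kin.build(E.stages[E.cur_stage].ha_gh);
  E.layout();

  NumericVector v0v = cfg["v0"];
  double v0[4] = {v0v[0], v0v[1], v0v[2], v0v[3]};
  double jitter = as<double>(cfg["v_jitter"]);

  GetRNGstate();
  E.init_state(v0, jitter);
  E.run();
  PutRNGstate();

  // assemble outputs
  int nspk = (int)E.spk_t.size();
  IntegerVector sp(nspk), si(nspk);
  NumericVector stt(nspk);
  for (int i = 0; i < nspk; ++i) {
    sp[i] = E.spk_pop[i]; si[i] = E.spk_idx[i]; stt[i] = E.spk_t[i];
  }
  NumericMatrix snapm(E.snaps.size(),
                      E.snaps.empty() ? 0 : E.snaps[0].size());
  for (size_t r = 0; r < E.snaps.size(); ++r)
    for (size_t c = 0; c < E.snaps[r].size(); ++c)
      snapm(r, c) = E.snaps[r][c];
  List wfin, mafin;
  for (auto& pr : E.projections) {
    wfin[pr.name] = wrap(pr.w);
    if (!pr.ma.empty()) mafin[pr.name] = wrap(pr.ma);
  }
  List vout;
  for (size_t c = 0; c < E.vrec.size(); ++c) vout.push_back(wrap(E.vrec[c]));
  return List::create(
    _["spike_pop"] = sp, _["spike_idx"] = si, _["spike_t"] = stt,
    _["lfp"] = wrap(E.lfp), _["lfp_dt"] = E.dt * E.lfp_every,
    _["snap_t"] = wrap(E.snap_t), _["snapshots"] = snapm,
    _["weights"] = wfin, _["mini_amps"] = mafin,
    _["vrec"] = vout);
}
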