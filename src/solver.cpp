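// Backward-Euler integrator for a branched passive/active cable with
// double-exponential synapses, somatic Gaussian current noise, step current
// injections, and an ideal somatic voltage clamp.
//
// Units: V mV, t ms, conductance mS, capacitance uF, current uA internally
// (nA at the interface, nS for synaptic conductances, pA for noise sigma).
//
// The tree must be supplied in Hines order: parent(i) < i for all non-root
// compartments, root = compartment 0. One elimination sweep from the leaves
// followed by back-substitution solves the (symmetric, diagonally dominant)
// implicit system exactly per step.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include "kinetics.h"

using namespace Rcpp;

namespace {

// Deterministic, platform-independent RNG (xorshift64*) with Box-Muller
// normals, so identical seeds give bit-identical noise everywhere.
struct NoiseRng {
  uint64_t s;
  bool have_spare;
  double spare;
  explicit NoiseRng(uint64_t seed) : have_spare(false), spare(0.0) {
    s = seed * 2654435761u + 0x9E3779B97F4A7C15ULL;
    if (s == 0) s = 0x106689D45497FDB5ULL;
    for (int i = 0; i < 8; ++i) next();  // warm up
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

// Tabulated gate updates: per gate, steady state and per-step decay factor
// exp(-dt/tau) on a uniform voltage grid, linearly interpolated.
struct GateTable {
  double vmin, vmax, dv, inv_dv;
  std::vector<double> inf, fac;
  void build(void (*rates)(double, double&, double&), double dt) {
    vmin = -150.0;
    vmax = 80.0;
    dv = 0.05;
    inv_dv = 1.0 / dv;
    int n = static_cast<int>((vmax - vmin) / dv) + 1;
    inf.resize(n);
    fac.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * dv, x, tau;
      rates(v, x, tau);
      inf[i] = x;
      fac[i] = std::exp(-dt / tau);
    }
  }
  inline void update(double v, double& state) const {
    if (v < vmin) v = vmin;
    if (v > vmax) v = vmax;
    double u = (v - vmin) * inv_dv;
    int i = static_cast<int>(u);
    if (i >= static_cast<int>(inf.size()) - 1) i = inf.size() - 2;
    double w = u - i;
    double xinf = inf[i] + w * (inf[i + 1] - inf[i]);
    double f = fac[i] + w * (fac[i + 1] - fac[i]);
    state = xinf + (state - xinf) * f;
  }
  inline double steady(double v) const {
    if (v < vmin) v = vmin;
    if (v > vmax) v = vmax;
    double u = (v - vmin) * inv_dv;
    int i = static_cast<int>(u);
    if (i >= static_cast<int>(inf.size()) - 1) i = inf.size() - 2;
    double w = u - i;
    return inf[i] + w * (inf[i + 1] - inf[i]);
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_cable")]]
List simulate_cable(IntegerVector parent,       // 0-based, -1 for root
                    NumericVector cap_uF,       // cm * area per compartment
                    NumericVector g_ax_mS,      // coupling to parent (root: 0)
                    NumericVector g_leak_mS,    // leak conductance per comp
                    NumericVector e_leak_mV,    // leak reversal per comp
                    NumericVector g_nat_mS,     // maximal conductances * area
                    NumericVector g_nap_mS,
                    NumericVector g_ka_mS,
                    NumericVector g_kdrf_mS,
                    double e_na,
                    double e_k,
                    IntegerVector syn_comp,     // per synaptic state
                    NumericVector syn_tau_r,
                    NumericVector syn_tau_d,
                    NumericVector syn_e_rev,
                    IntegerVector ev_step,      // events sorted by step
                    IntegerVector ev_state,
                    NumericVector ev_amount_nS, // weight * factor
                    IntegerVector stim_comp,    // step current injections
                    NumericVector stim_start,
                    NumericVector stim_end,
                    NumericVector stim_amp_nA,
                    bool noise_on,
                    double noise_sigma_pA,
                    double noise_seed,
                    int noise_comp,
                    bool clamp_on,
                    double clamp_vhold,
                    int clamp_comp,
                    double dt,
                    int n_steps,
                    int record_every,
                    NumericVector v0,
                    bool record_all,
                    bool record_clamp) {
  const int n = parent.size();
  const int n_syn = syn_comp.size();
  const int n_ev = ev_step.size();
  const int n_stim = stim_comp.size();

  // Static diagonal: C/dt + g_leak + sum of axial couplings (+ clamp marker).
  std::vector<double> d0(n), v(n), d(n), rhs(n);
  for (int i = 0; i < n; ++i) {
    d0[i] = cap_uF[i] / dt + g_leak_mS[i];
    v[i] = v0[i];
  }
  for (int i = 1; i < n; ++i) {
    d0[i] += g_ax_mS[i];
    d0[parent[i]] += g_ax_mS[i];
  }

  // Active-gate bookkeeping: only compartments with any nonzero gbar.
  std::vector<int> act;
  for (int i = 0; i < n; ++i)
    if (g_nat_mS[i] > 0 || g_nap_mS[i] > 0 || g_ka_mS[i] > 0 || g_kdrf_mS[i] > 0)
      act.push_back(i);
  const int n_act = act.size();

  GateTable t_m, t_h, t_s, t_p, t_a, t_b, t_n;
  if (n_act > 0) {
    t_m.build(ivlsim::nat_m, dt);
    t_h.build(ivlsim::nat_h, dt);
    t_s.build(ivlsim::nat_s, dt);
    t_p.build(ivlsim::nap_p, dt);
    t_a.build(ivlsim::ka_a, dt);
    t_b.build(ivlsim::ka_b, dt);
    t_n.build(ivlsim::kdrf_n, dt);
  }
  std::vector<double> gm(n_act), gh(n_act), gs(n_act), gp(n_act), ga(n_act),
      gb(n_act), gn(n_act);
  for (int k = 0; k < n_act; ++k) {
    double vi = v[act[k]];
    gm[k] = t_m.steady(vi);
    gh[k] = t_h.steady(vi);
    gs[k] = t_s.steady(vi);
    gp[k] = t_p.steady(vi);
    ga[k] = t_a.steady(vi);
    gb[k] = t_b.steady(vi);
    gn[k] = t_n.steady(vi);
  }

  // Synaptic double-exponential states: g = (Sd - Sr), decays precomputed.
  std::vector<double> sd(n_syn, 0.0), sr(n_syn, 0.0), fd(n_syn), fr(n_syn);
  for (int j = 0; j < n_syn; ++j) {
    fd[j] = std::exp(-dt / syn_tau_d[j]);
    fr[j] = std::exp(-dt / syn_tau_r[j]);
  }

  NoiseRng rng(static_cast<uint64_t>(noise_seed));
  const double noise_scale = noise_sigma_pA * 1e-6 / std::sqrt(dt);  // uA

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_v(n_rec);
  NumericMatrix rec_all(record_all ? n_rec : 0, record_all ? n : 0);
  NumericVector rec_ic(record_clamp ? n_rec : 0);

  // Current per compartment from membrane + axial balance at the clamped
  // node; equals the electrode current holding it at vhold.
  auto clamp_current_uA = [&](double inj_uA) {
    int c = clamp_comp;
    double vm = v[c];
    double im = g_leak_mS[c] * (vm - e_leak_mV[c]);
    for (int k = 0; k < n_act; ++k) {
      if (act[k] != c) continue;
      double m3h = gm[k] * gm[k] * gm[k] * gh[k] * gs[k];
      im += g_nat_mS[c] * m3h * (vm - e_na);
      im += g_nap_mS[c] * gp[k] * (vm - e_na);
      im += g_ka_mS[c] * ga[k] * ga[k] * gb[k] * (vm - e_k);
      im += g_kdrf_mS[c] * gn[k] * gn[k] * gn[k] * gn[k] * (vm - e_k);
    }
    for (int j = 0; j < n_syn; ++j)
      if (syn_comp[j] == c) im += (sd[j] - sr[j]) * 1e-6 * (vm - syn_e_rev[j]);
    double ax_in = 0.0;
    if (parent[c] >= 0) ax_in += g_ax_mS[c] * (v[parent[c]] - vm);
    for (int i = 1; i < n; ++i)
      if (parent[i] == c) ax_in += g_ax_mS[i] * (v[i] - vm);
    return im - ax_in - inj_uA;
  };

  int rec_i = 0;
  rec_t[0] = 0.0;
  rec_v[0] = v[0];
  if (record_all)
    for (int i = 0; i < n; ++i) rec_all(0, i) = v[i];
  if (record_clamp) rec_ic[0] = clamp_current_uA(0.0) * 1e3;
  ++rec_i;

  int ev_i = 0;
  for (int step = 0; step < n_steps; ++step) {
    // 1. deliver events scheduled at this step, then decay to t+dt
    while (ev_i < n_ev && ev_step[ev_i] <= step) {
      int j = ev_state[ev_i];
      sd[j] += ev_amount_nS[ev_i];
      sr[j] += ev_amount_nS[ev_i];
      ++ev_i;
    }
    for (int j = 0; j < n_syn; ++j) {
      sd[j] *= fd[j];
      sr[j] *= fr[j];
    }

    // 2. gate update via exponential integration at V(t)
    for (int k = 0; k < n_act; ++k) {
      double vi = v[act[k]];
      t_m.update(vi, gm[k]);
      t_h.update(vi, gh[k]);
      t_s.update(vi, gs[k]);
      t_p.update(vi, gp[k]);
      t_a.update(vi, ga[k]);
      t_b.update(vi, gb[k]);
      t_n.update(vi, gn[k]);
    }

    // 3. assemble implicit system
    for (int i = 0; i < n; ++i) {
      d[i] = d0[i];
      rhs[i] = cap_uF[i] / dt * v[i] + g_leak_mS[i] * e_leak_mV[i];
    }
    for (int k = 0; k < n_act; ++k) {
      int i = act[k];
      double m3h = gm[k] * gm[k] * gm[k] * gh[k] * gs[k];
      double gna = g_nat_mS[i] * m3h + g_nap_mS[i] * gp[k];
      double n4 = gn[k] * gn[k] * gn[k] * gn[k];
      double gk = g_ka_mS[i] * ga[k] * ga[k] * gb[k] + g_kdrf_mS[i] * n4;
      d[i] += gna + gk;
      rhs[i] += gna * e_na + gk * e_k;
    }
    for (int j = 0; j < n_syn; ++j) {
      double g = (sd[j] - sr[j]) * 1e-6;  // nS -> mS
      d[syn_comp[j]] += g;
      rhs[syn_comp[j]] += g * syn_e_rev[j];
    }
    double t_mid = (step + 0.5) * dt;
    double inj_clamp_uA = 0.0;
    for (int s = 0; s < n_stim; ++s) {
      if (t_mid >= stim_start[s] && t_mid < stim_end[s]) {
        rhs[stim_comp[s]] += stim_amp_nA[s] * 1e-3;
        if (clamp_on && stim_comp[s] == clamp_comp)
          inj_clamp_uA += stim_amp_nA[s] * 1e-3;
      }
    }
    if (noise_on) {
      double xi = noise_scale * rng.gauss();
      rhs[noise_comp] += xi;
      if (clamp_on && noise_comp == clamp_comp) inj_clamp_uA += xi;
    }

    // 4. Hines solve (exact Dirichlet handling of the clamped row)
    if (clamp_on) {
      d[clamp_comp] = 1.0;
      rhs[clamp_comp] = clamp_vhold;
    }
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      if (clamp_on && i == clamp_comp) {
        rhs[p] += g_ax_mS[i] * clamp_vhold;  // known child value
        continue;
      }
      if (clamp_on && p == clamp_comp) continue;  // fixed parent row
      double f = g_ax_mS[i] / d[i];
      d[p] -= f * g_ax_mS[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      v[i] = (clamp_on && i == clamp_comp)
                 ? clamp_vhold
                 : (rhs[i] + g_ax_mS[i] * v[parent[i]]) / d[i];

    // 5. record
    if ((step + 1) % record_every == 0) {
      rec_t[rec_i] = (step + 1) * dt;
      rec_v[rec_i] = v[0];
      if (record_all)
        for (int i = 0; i < n; ++i) rec_all(rec_i, i) = v[i];
      if (record_clamp) rec_ic[rec_i] = clamp_current_uA(inj_clamp_uA) * 1e3;
      ++rec_i;
    }
    if ((step & 1023) == 0 && !std::isfinite(v[0]))
      stop("non-finite membrane potential at t = %f ms (compartment 1)",
           step * dt);
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(v[i]))
      stop("non-finite membrane potential at t = %f ms (compartment %d)",
           n_steps * dt, i + 1);

  List out = List::create(_["time"] = rec_t, _["vm"] = rec_v);
  if (record_all) out["vm_all"] = rec_all;
  if (record_clamp) out["i_clamp"] = rec_ic;
  return out;
}
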