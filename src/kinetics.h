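#ifndef IVLSIM_KINETICS_H
#define IVLSIM_KINETICS_H

#include <cmath>

// Hodgkin-Huxley-style gating for the four active conductances of the
// reduced IS3-like model:
//
//   transient Na        g_NaT  = gbar * m^3 * h * s (E = e_na)
//   persistent Na       g_NaP  = gbar * p         (E = e_na)
//   A-type K            g_KA   = gbar * a^3 * b   (E = e_k)
//   fast delayed-rect K g_Kdrf = gbar * n^4       (E = e_k)
//
// The exact kinetics of the original reconstructed-cell models are not part
// of this package. The forms below are literature-typical fast-spiking
// interneuron kinetics (steep sigmoidal steady states in the style of
// Golomb-type FS models: near-instantaneous Na activation, slower steep Na
// inactivation well separated from activation, a high-threshold Kv3-like
// fast rectifier that engages only during the spike, and a subthreshold
// transient A-current). Voltage shifts were chosen so that, at the printed
// channel densities and the calibrated (high input resistance, hence very
// small) leak, the cell rests near the leak reversal, shows a small
// rheobase with sustained high-rate firing, and enters depolarization
// block with shrinking spikes under strong drive. They are collected in
// this single header so they can be swapped without touching the
// integrator.
//
// Each function fills the steady state (inf) and time constant (tau, ms)
// at membrane potential v (mV); gates are integrated by exact exponential
// relaxation toward inf per step, so tau may be arbitrarily small.

namespace ivlsim {

// -- transient Na activation (m): steep, nearly instantaneous ----------------
inline void nat_m(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 30.0) / 9.0));
  tau = 0.05;
}

// -- transient Na inactivation (h): slow, well below activation --------------
inline void nat_h(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 52.0) / 6.7));
  tau = 1.0 + 40.0 / (1.0 + std::exp((v + 60.0) / 12.0));
}

// -- transient Na slow inactivation (s): integrates sustained depolarization
//    and spike load over hundreds of ms; collapse of s under strong drive
//    produces depolarization block with shrinking spikes ---------------------
inline void nat_s(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 44.0) / 5.0));
  tau = 600.0;
}

// -- persistent Na activation (p): non-inactivating, subthreshold amplifier --
inline void nap_p(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 45.0) / 5.0));
  tau = 1.0;
}

// -- A-type K activation (a) -------------------------------------------------
inline void ka_a(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  tau = 2.0;
}

// -- A-type K inactivation (b): slow, removes the A-brake on sustained
//    depolarization ----------------------------------------------------------
inline void ka_b(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v + 70.0) / 6.0));
  tau = 150.0;
}

// -- fast delayed-rectifier K activation (n): Kv3-like, high threshold,
//    fast at spike voltages --------------------------------------------------
inline void kdrf_n(double v, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 12.4) / 6.8));
  tau = 0.4 + 3.0 / (1.0 + std::exp((v + 40.0) / 10.0));
}

}  // namespace ivlsim

#endif
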