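#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment conductance model, one sweep.
//
// Units: ms, mV, pA, nS, pF (so pA/pF = mV/ms and R[GOhm] = 1/g[nS]).
// Currents: leak, HCN (first-order sigmoid gate), T-type calcium
// (instantaneous m_inf^2 activation x first-order inactivation),
// exponential spike-initiation current gated by a slow sodium-availability
// variable s (gives depolarization block), and a spike-triggered adaptation
// current w. Forward Euler on V, exponential Euler on gates.

static inline double sig_up(double v, double vhalf, double k) {
  // increasing sigmoid (activation with depolarization)
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}
static inline double sig_dn(double v, double vhalf, double k) {
  // decreasing sigmoid (activation with hyperpolarization / inactivation)
  return 1.0 / (1.0 + std::exp((v - vhalf) / k));
}

// [[Rcpp::export]]
List sim_sweep_cpp(List par, double amp, double step_on, double step_off,
                   double total_dur, double fs_out, double bias,
                   double v0, int oversample, NumericVector noise) {
  const double c_pf      = par["c_pf"];
  const double g_leak    = par["g_leak_ns"];
  const double e_leak    = par["e_leak_mv"];
  const double g_h       = par["g_h_ns"];
  const double e_h       = par["e_h_mv"];
  const double h_vhalf   = par["h_vhalf_mv"];
  const double h_slope   = par["h_slope_mv"];
  const double h_taumax  = par["h_taumax_ms"];
  const double h_taumin  = par["h_taumin_ms"];
  const double g_t       = par["g_t_ns"];
  const double t_vm      = par["t_vm_mv"];
  const double t_km      = par["t_km_mv"];
  const double t_vh      = par["t_vh_mv"];
  const double t_kh      = par["t_kh_mv"];
  const double t_tau_in  = par["t_tau_inact_ms"];
  const double t_tau_rec = par["t_tau_rec_ms"];
  const double t_ktau    = par["t_ktau_mv"];
  const double t_tauvh   = par["t_tauvh_mv"];
  const double e_t       = par["e_t_mv"];
  const bool   spiking   = as<double>(par["spike_on"]) > 0.5;
  const double v_t       = par["v_t_mv"];
  const double delta_t   = par["delta_t_mv"];
  const double v_reset   = par["v_reset_mv"];
  const double t_ref     = par["t_ref_ms"];
  const double v_trig    = par["v_trigger_mv"];
  const double v_peak    = par["v_peak_mv"];
  const double s_vhalf   = par["s_vhalf_mv"];
  const double s_slope   = par["s_slope_mv"];
  const double s_tau     = par["s_tau_ms"];
  const double s_block   = par["s_block"];
  const double s_spike   = par["s_spike_frac"];
  const double g_dr      = par["g_dr_ns"];
  const double dr_vhalf  = par["dr_vhalf_mv"];
  const double dr_k      = par["dr_k_mv"];
  const double e_k       = par["e_k_mv"];
  const double g_kir     = par["g_kir_ns"];
  const double kir_vhalf = par["kir_vhalf_mv"];
  const double kir_k     = par["kir_k_mv"];
  const double adapt_a   = par["adapt_a_ns"];
  const double adapt_b   = par["adapt_b_ns"];
  const double adapt_tau = par["adapt_tau_ms"];
  const double e_w       = par["e_w_mv"];

  const double dt = 1000.0 / fs_out / oversample;
  const int n_out = (int)std::lround(total_dur * fs_out / 1000.0);
  const int n_steps = n_out * oversample;
  const bool has_noise = noise.size() > 0;
  if (has_noise && noise.size() < n_steps)
    stop("noise vector shorter than the number of integration steps");

  NumericVector v_out(n_out);
  std::vector<double> spike_t;
  std::vector<int> spike_out_idx;

  double V = v0;
  double m_h = sig_dn(v0, h_vhalf, h_slope);
  double h_t = sig_dn(v0, t_vh, t_kh);
  double s = sig_dn(v0, s_vhalf, s_slope);
  double w = 0.0;  // spike-triggered adaptation conductance (nS)
  int refr = 0;
  const int refr_steps = (int)std::lround(t_ref / dt);

  for (int k = 0; k < n_steps; ++k) {
    if (k % oversample == 0) v_out[k / oversample] = V;
    const double t = k * dt;
    double i_inj = bias + ((t >= step_on && t < step_off) ? amp : 0.0);
    if (has_noise) i_inj += noise[k];

    // gates: exponential Euler
    const double tau_h = h_taumin + (h_taumax - h_taumin) /
      std::cosh((V - h_vhalf) / (2.0 * h_slope));
    m_h += (sig_dn(V, h_vhalf, h_slope) - m_h) * (-std::expm1(-dt / tau_h));
    const double tau_ht = t_tau_in + (t_tau_rec - t_tau_in) * sig_dn(V, t_tauvh, t_ktau);
    h_t += (sig_dn(V, t_vh, t_kh) - h_t) * (-std::expm1(-dt / tau_ht));
    s += (sig_dn(V, s_vhalf, s_slope) - s) * (-std::expm1(-dt / s_tau));
    w += ((adapt_a * sig_up(V, s_vhalf, s_slope) - w) / adapt_tau) * dt;

    if (refr > 0) {
      V = v_reset;
      --refr;
      continue;
    }

    const double mt = sig_up(V, t_vm, t_km);
    double i_mem = -g_leak * (V - e_leak)
                   - g_h * m_h * (V - e_h)
                   - g_t * mt * mt * h_t * (V - e_t)
                   - g_dr * sig_up(V, dr_vhalf, dr_k) * (V - e_k)
                   - g_kir * sig_dn(V, kir_vhalf, kir_k) * (V - e_k)
                   - w * (V - e_w) + i_inj;
    if (spiking) {
      // saturate the spike current at its trigger-level value so the
      // depolarization-block plateau stays bounded
      double ea = (V - v_t) / delta_t;
      const double ea_max = (v_trig - v_t) / delta_t;
      if (ea > ea_max) ea = ea_max;
      i_mem += g_leak * delta_t * s * std::exp(ea);
    }
    V += dt * i_mem / c_pf;

    if (!std::isfinite(V) || V < -250.0 || V > 250.0)
      stop("integration unstable at t = %.3f ms (dt = %.4f ms): |V| diverged",
           t, dt);

    if (spiking && V > v_trig && s >= s_block) {
      // emit a spike: stamp the peak on the nearest output sample
      spike_t.push_back(t);
      int j = (int)std::lround((double)k / oversample);
      if (j > n_out - 1) j = n_out - 1;
      spike_out_idx.push_back(j);
      V = v_reset;
      w += adapt_b;
      s *= (1.0 - s_spike);    // cumulative sodium inactivation
      refr = refr_steps;
    }
    // with s below s_block the cell is in depolarization block: V rides
    // up to the plateau set by the delayed-rectifier ceiling instead of
    // spiking
  }

  for (size_t q = 0; q < spike_out_idx.size(); ++q)
    v_out[spike_out_idx[q]] = v_peak;

  return List::create(_["v"] = v_out,
                      _["spike_t"] = wrap(spike_t),
                      _["m_h_end"] = m_h, _["h_t_end"] = h_t);
}

// Steady-state whole-cell current (pA) that must be injected to hold the
// membrane at voltage v: the closed-form current balance used by the
// holding-bias solver and the resting-potential calculation.
// [[Rcpp::export]]
NumericVector steady_current_cpp(List par, NumericVector v) {
  const double g_leak  = par["g_leak_ns"];
  const double e_leak  = par["e_leak_mv"];
  const double g_h     = par["g_h_ns"];
  const double e_h     = par["e_h_mv"];
  const double h_vhalf = par["h_vhalf_mv"];
  const double h_slope = par["h_slope_mv"];
  const double g_t     = par["g_t_ns"];
  const double t_vm    = par["t_vm_mv"];
  const double t_km    = par["t_km_mv"];
  const double t_vh    = par["t_vh_mv"];
  const double t_kh    = par["t_kh_mv"];
  const double e_t     = par["e_t_mv"];
  const bool   spiking = as<double>(par["spike_on"]) > 0.5;
  const double v_t     = par["v_t_mv"];
  const double delta_t = par["delta_t_mv"];
  const double v_trig  = par["v_trigger_mv"];
  const double s_vhalf = par["s_vhalf_mv"];
  const double s_slope = par["s_slope_mv"];
  const double g_dr    = par["g_dr_ns"];
  const double dr_vhalf= par["dr_vhalf_mv"];
  const double dr_k    = par["dr_k_mv"];
  const double e_k     = par["e_k_mv"];
  const double g_kir   = par["g_kir_ns"];
  const double kir_vhalf = par["kir_vhalf_mv"];
  const double kir_k   = par["kir_k_mv"];
  const double adapt_a = par["adapt_a_ns"];

  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) {
    const double V = v[i];
    const double mt = sig_up(V, t_vm, t_km);
    double cur = g_leak * (V - e_leak)
                 + g_h * sig_dn(V, h_vhalf, h_slope) * (V - e_h)
                 + g_t * mt * mt * sig_dn(V, t_vh, t_kh) * (V - e_t)
                 + g_dr * sig_up(V, dr_vhalf, dr_k) * (V - e_k)
                 + g_kir * sig_dn(V, kir_vhalf, kir_k) * (V - e_k)
                 + adapt_a * (V - e_leak);
    if (spiking) {
      double ea = (V - v_t) / delta_t;
      double ea_max = (v_trig - v_t) / delta_t;
      if (ea > ea_max) ea = ea_max;
      cur -= g_leak * delta_t * sig_dn(V, s_vhalf, s_slope) * std::exp(ea);
    }
    out[i] = cur;
  }
  return out;
}
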