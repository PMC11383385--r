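#' Simulation parameters for the single-compartment model neuron
#'
#' The synthetic neuron is a single compartment obeying
#' \deqn{C dV/dt = -g_L(V-E_L) - g_h m_h (V-E_h) - g_T m_\infty^2(V) h_T
#'   (V-E_T) + g_L \Delta_T s\, e^{(V-V_T)/\Delta_T} - w + I_{inj} + \xi}
#' with first-order HCN gating (`m_h`), T-type calcium with instantaneous
#' squared activation and first-order inactivation (`h_T`), an
#' exponential spike-initiation current gated by a slow
#' sodium-availability variable `s` (which produces depolarization block
#' at strong drive), and a spike-triggered adaptation current `w`. Spikes
#' are emitted (and the trace stamped with an overshooting peak) when the
#' voltage crosses `v_trigger_mv` with sufficient sodium availability,
#' then reset with a refractory period.
#'
#' Units: pF, nS, mV, ms, pA. Noise is white current noise (pA SD per
#' sample at the integration step), seeded.
#'
#' @param c_pf Capacitance (pF).
#' @param g_leak_ns Leak conductance (nS).
#' @param e_leak_mv Leak reversal (mV). When `NULL`, it is solved so the
#'   zero-bias resting potential equals `rmp_target_mv`.
#' @param rmp_target_mv Resting-potential target used when `e_leak_mv` is
#'   `NULL` (mV).
#' @param g_h_ns HCN maximal conductance (nS).
#' @param e_h_mv,h_vhalf_mv,h_slope_mv,h_taumax_ms,h_taumin_ms HCN
#'   reversal and gating parameters. Activation is
#'   `1/(1+exp((V - h_vhalf)/h_slope))`; the time constant is bell-shaped
#'   in voltage, capped at `h_taumax_ms`.
#' @param g_t_ns T-type maximal conductance (nS).
#' @param t_vm_mv,t_km_mv,t_vh_mv,t_kh_mv,t_tau_inact_ms,t_tau_rec_ms,t_ktau_mv,e_t_mv
#'   T-current activation/inactivation half-voltages, slopes, time
#'   constants and reversal.
#' @param spike_on Logical: include the spiking mechanism.
#' @param v_t_mv,delta_t_mv Exponential spike-initiation threshold and
#'   sharpness.
#' @param v_reset_mv,t_ref_ms Post-spike reset voltage and refractory
#'   period.
#' @param v_trigger_mv,v_peak_mv Spike emission trigger and stamped peak
#'   (peaks overshoot 0 mV, matching the recording-inclusion criterion).
#' @param s_vhalf_mv,s_slope_mv,s_tau_ms,s_block,s_spike_frac Slow
#'   sodium-availability gate: voltage-dependent recovery plus a
#'   fractional per-spike decrement; spikes require `s >= s_block`,
#'   otherwise the cell sits in depolarization block.
#' @param g_dr_ns,dr_vhalf_mv,dr_k_mv,e_k_mv Instantaneous
#'   delayed-rectifier ceiling that bounds the depolarization-block
#'   plateau.
#' @param g_kir_ns,kir_vhalf_mv,kir_k_mv Instantaneous inward-rectifier
#'   potassium conductance bounding deep hyperpolarization.
#' @param adapt_a_ns,adapt_b_ns,adapt_tau_ms,e_w_mv Spike-triggered
#'   adaptation conductance: per-spike increment, optional voltage-gated
#'   component, decay time constant, and its reversal (shallower than
#'   E_K, bounding post-burst afterhyperpolarizations).
#' @param noise_pa White current-noise SD (pA).
#' @param seed RNG seed used by [simulate_sweep()].
#' @return An object of class `ep_simparams` (named list).
#' @export
sim_params <- function(c_pf = 100, g_leak_ns = 1, e_leak_mv = NULL,
                       rmp_target_mv = -61,
                       g_h_ns = 0, e_h_mv = -35, h_vhalf_mv = -70,
                       h_slope_mv = 6, h_taumax_ms = 350, h_taumin_ms = 30,
                       g_t_ns = 0, t_vm_mv = -45, t_km_mv = 6.2,
                       t_vh_mv = -70, t_kh_mv = 2.3, t_tau_inact_ms = 4.5,
                       t_tau_rec_ms = 900, t_ktau_mv = 4, t_tauvh_mv = -50,
                       e_t_mv = 120,
                       spike_on = TRUE, v_t_mv = -39, delta_t_mv = 1.2,
                       v_reset_mv = -36, t_ref_ms = 0.8, v_trigger_mv = -30,
                       v_peak_mv = 35, s_vhalf_mv = -33, s_slope_mv = 4,
                       s_tau_ms = 250, s_block = 0.2, s_spike_frac = 0.2,
                       g_dr_ns = 150, dr_vhalf_mv = -18, dr_k_mv = 2.5,
                       e_k_mv = -90, g_kir_ns = 2, kir_vhalf_mv = -125,
                       kir_k_mv = 8,
                       adapt_a_ns = 0, adapt_b_ns = 4.3, adapt_tau_ms = 17,
                       e_w_mv = -75,
                       noise_pa = 2, seed = 1) {
  stopifnot(c_pf > 0, g_leak_ns > 0, g_h_ns >= 0, g_t_ns >= 0,
            noise_pa >= 0)
  p <- structure(as.list(environment()), class = "ep_simparams")
  p$spike_on <- as.numeric(spike_on)
  if (is.null(e_leak_mv)) p <- resolve_e_leak(p)
  p
}

#' @export
print.ep_simparams <- function(x, ...) {
  cat(sprintf(
    "<ep_simparams> C=%g pF, gL=%g nS (EL=%.2f mV), gH=%g nS, gT=%g nS, %s\n",
    x$c_pf, x$g_leak_ns, x$e_leak_mv, x$g_h_ns, x$g_t_ns,
    if (x$spike_on > 0) "spiking" else "passive"))
  invisible(x)
}

#' Preset parameter sets
#'
#' `md_m_params()` and `md_l_params()` are calibrated so that extracted
#' population medians land near the reference phenotypes: a
#' high-resistance, slower cell with moderate HCN conductance
#' (input resistance about 790 MOhm, sag at -100 mV about -4.6 mV) versus
#' a low-resistance, faster cell with strong HCN conductance (about
#' 440 MOhm and -7.7 mV). Both share the spiking and T-type machinery, and
#' both have the leak reversal solved so the zero-bias resting potential
#' is -61 mV. `passive_params()` is a pure RC cell (no HCN, no T, no
#' spiking) whose analytic ground truth is R = 1000/g_leak MOhm and
#' tau = C/g_leak ms.
#'
#' @param c_pf,g_leak_ns,noise_pa,seed Overridable basics.
#' @param ... Further overrides passed to [sim_params()].
#' @return An `ep_simparams` object.
#' @export
md_m_params <- function(noise_pa = 2, seed = 1, ...) {
  args <- list(c_pf = 115, g_leak_ns = 0.88, g_h_ns = 0.42,
               h_taumin_ms = 140, g_t_ns = 52, noise_pa = noise_pa,
               seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_params, args)
}

#' @rdname md_m_params
#' @export
md_l_params <- function(noise_pa = 2, seed = 1, ...) {
  args <- list(c_pf = 115, g_leak_ns = 0.85, g_h_ns = 1.0,
               h_taumin_ms = 50, g_t_ns = 72, t_vh_mv = -71.8,
               adapt_b_ns = 3.9, noise_pa = noise_pa, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_params, args)
}

#' @rdname md_m_params
#' @export
passive_params <- function(c_pf = 100, g_leak_ns = 2, noise_pa = 0,
                           seed = 1, ...) {
  sim_params(c_pf = c_pf, g_leak_ns = g_leak_ns, g_h_ns = 0, g_t_ns = 0,
             g_dr_ns = 0, g_kir_ns = 0, spike_on = FALSE,
             noise_pa = noise_pa, seed = seed, ...)
}

#' Ground truth implied by a parameter set
#'
#' Passive input resistance at the holding potential (1000 over the total
#' slope conductance of leak plus open HCN channels), the corresponding
#' membrane time constant, and whether any sag is expected (zero iff
#' `g_h_ns` is 0).
#'
#' @param p An `ep_simparams` object.
#' @param hold_mv Potential at which the chord values are taken.
#' @return List with `rn_true_mohm`, `tau_true_ms`, `sag_expected`.
#' @export
ground_truth <- function(p, hold_mv = -65) {
  m_h <- 1 / (1 + exp((hold_mv - p$h_vhalf_mv) / p$h_slope_mv))
  g <- p$g_leak_ns + p$g_h_ns * m_h
  list(rn_true_mohm = 1000 / g, tau_true_ms = p$c_pf / g,
       sag_expected = p$g_h_ns > 0)
}

#' Holding bias current
#'
#' Closed-form steady-state current balance: the bias (pA) that holds the
#' model at `hold_mv` in the absence of a step.
#'
#' @param p An `ep_simparams` object.
#' @param hold_mv Holding potential (mV).
#' @return Bias current (pA).
#' @export
holding_bias <- function(p, hold_mv = -65) {
  as.numeric(steady_current_cpp(p, hold_mv))
}

#' Resting membrane potential of the model
#'
#' Zero-injection fixed point of the steady-state current balance,
#' located by root bracketing on \[-90, -35\] mV.
#'
#' @param p An `ep_simparams` object.
#' @return RMP (mV).
#' @export
model_rmp <- function(p) {
  v_from_bias(p, 0)
}

#' Simulate one square-step sweep
#'
#' Fixed-step integration at dt = 0.025 ms (forward Euler on V,
#' exponential Euler on gates) decimated 2x to the 20 kHz output rate.
#' Deterministic given `(p, seed)`: the seeded white current noise is the
#' only stochastic element.
#'
#' @param p An `ep_simparams` object.
#' @param amp Step amplitude (pA).
#' @param step_on,step_off,total_dur Step timing (ms).
#' @param fs Output sampling rate (Hz); must be >= 10 kHz.
#' @param bias Holding bias current (pA).
#' @param seed RNG seed for the noise; defaults to `p$seed`.
#' @param sweep_id Identifier.
#' @param oversample Integration steps per output sample.
#' @return An [sweep()] object with attribute `spike_t_sim` (the emission
#'   times the integrator recorded).
#' @export
simulate_sweep <- function(p, amp, step_on = 250, step_off = 1250,
                           total_dur = 2500, fs = 20000, bias = 0,
                           seed = NULL, sweep_id = NULL, oversample = 2) {
  stopifnot(inherits(p, "ep_simparams"), fs >= 10000, step_on < step_off,
            step_off <= total_dur)
  if (is.null(seed)) seed <- p$seed
  n_out <- round(total_dur * fs / 1000)
  n_steps <- n_out * oversample
  noise <- numeric(0)
  if (p$noise_pa > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    noise <- rnorm(n_steps, 0, p$noise_pa)
  }
  v0 <- v_from_bias(p, bias)
  out <- sim_sweep_cpp(p, amp, step_on, step_off, total_dur, fs, bias,
                       v0, as.integer(oversample), noise)
  sw <- sweep(v = out$v, fs = fs, step_on = step_on, step_off = step_off,
              amp = amp, baseline_pa = bias, sweep_id = sweep_id)
  attr(sw, "spike_t_sim") <- out$spike_t
  sw
}

# initial voltage consistent with a given bias: root of the steady balance.
# The upper bracket stays below the spike-initiation region, where the
# exponential current bends the I-V curve back down.
v_from_bias <- function(p, bias) {
  f <- function(v) as.numeric(steady_current_cpp(p, v)) - bias
  lo <- -130
  for (hi in c(-48, -44, -40)) {
    if (f(lo) * f(hi) <= 0)
      return(uniroot(f, c(lo, hi), tol = 1e-9)$root)
  }
  p$e_leak_mv
}

#' Simulate a full protocol for one cell
#'
#' The holding bias is solved in closed form so the pre-step membrane
#' potential sits at `hold_mv` (within 0.5 mV; exactly at it in the
#' noise-free limit). One sweep is produced per amplitude, `n_reps`
#' sweeps for repeated protocols, each with a distinct derived seed.
#'
#' @param p An `ep_simparams` object.
#' @param spec An [protocol_spec()] object.
#' @param hold_mv Target holding potential (mV); `NA` simulates at rest
#'   (zero bias).
#' @param fs Output sampling rate (Hz).
#' @param group,condition,cell_id Labels copied into the recording.
#' @return An [recording()] object that passes [validate_protocol()] for
#'   `spec`.
#' @export
simulate_protocol <- function(p, spec, hold_mv = -65, fs = 20000,
                              group = NA_character_, condition = "baseline",
                              cell_id = "cell") {
  bias <- if (is.na(hold_mv)) 0 else holding_bias(p, hold_mv)
  total <- spec$pre_dur + spec$step_dur + spec$post_dur
  sweeps <- list()
  k <- 0L
  for (a in spec$amps) {
    for (r in seq_len(spec$n_reps)) {
      k <- k + 1L
      sid <- if (spec$n_reps > 1) sprintf("amp_%g_rep_%d", a, r)
             else sprintf("amp_%g", a)
      sweeps[[k]] <- simulate_sweep(
        p, a, step_on = spec$pre_dur, step_off = spec$pre_dur + spec$step_dur,
        total_dur = total, fs = fs, bias = bias,
        seed = (p$seed * 1009 + k * 7919) %% 2147483647, sweep_id = sid)
    }
  }
  recording(sweeps, cell_id = cell_id, holding_mv = hold_mv, group = group,
            condition = condition, protocol = spec$name)
}

#' Emulate HCN-channel block by ZD7288
#'
#' Bath application of the HCN inhibitor is modeled purely as scaling the
#' HCN maximal conductance by `1 - block_frac`; nothing else changes.
#'
#' @param p An `ep_simparams` object.
#' @param block_frac Fraction of conductance blocked, in \[0, 1\]
#'   (default 1 = complete block).
#' @return A modified copy of `p`.
#' @export
apply_zd7288 <- function(p, block_frac = 1) {
  if (block_frac < 0 || block_frac > 1)
    stop("block_frac must lie in [0, 1]", call. = FALSE)
  p$g_h_ns <- p$g_h_ns * (1 - block_frac)
  p
}

#' Draw a synthetic cell population around a preset
#'
#' Per-cell parameters are drawn lognormally around the preset:
#' capacitance, leak conductance, HCN conductance and T conductance are
#' scaled by independent lognormal factors with coefficient of variation
#' `cv`; the resting-potential target gets a small Gaussian jitter (SD
#' 1.5 mV) shared by both presets so that resting potential carries no
#' group signal. Deterministic per seed.
#'
#' @param preset `"MD-M"` or `"MD-L"`.
#' @param n Number of cells (>= 1).
#' @param cv Between-cell coefficient of variation, in \[0, 0.5\].
#' @param seed RNG seed.
#' @param ... Overrides forwarded to the preset constructor.
#' @return List of length `n`; each element is `list(params, truth)`.
#' @export
make_population <- function(preset = c("MD-M", "MD-L"), n, cv = 0.2,
                            seed = 1, ...) {
  preset <- match.arg(preset)
  stopifnot(n >= 1, cv >= 0, cv <= 0.5)
  set.seed(as.integer(seed %% .Machine$integer.max))
  sdlog <- sqrt(log(1 + cv^2))
  base_fun <- if (preset == "MD-M") md_m_params else md_l_params
  lapply(seq_len(n), function(i) {
    fac <- rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    rmp_jit <- rnorm(1, 0, 1.5)
    p <- base_fun(seed = (seed * 131 + i) %% 2147483647, ...)
    p$c_pf <- p$c_pf * fac[1]
    p$g_leak_ns <- p$g_leak_ns * fac[2]
    p$g_h_ns <- p$g_h_ns * fac[3]
    p$g_t_ns <- p$g_t_ns * fac[4]
    p$rmp_target_mv <- p$rmp_target_mv + rmp_jit
    p <- resolve_e_leak(p)
    list(params = p, truth = ground_truth(p))
  })
}

# re-solve the leak reversal so the zero-bias resting potential equals
# p$rmp_target_mv (closed form; assumes adapt_a_ns = 0 at rest)
resolve_e_leak <- function(p) {
  target <- p$rmp_target_mv
  p$e_leak_mv <- 0
  other <- as.numeric(steady_current_cpp(p, target)) - p$g_leak_ns * target
  p$e_leak_mv <- target + other / p$g_leak_ns
  p
}
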