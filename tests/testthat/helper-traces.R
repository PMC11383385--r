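# Programmatic trace fixtures (built in code; nothing stored on disk).

# sweep with a piecewise-constant voltage trace
flat_sweep <- function(pre_mv, step_mv, post_mv = pre_mv, amp = -10,
                       fs = 2000, pre = 250, dur = 1000, post = 250,
                       baseline_pa = 0) {
  dt <- 1000 / fs
  t <- seq(0, pre + dur + post - dt, by = dt)
  v <- ifelse(t < pre, pre_mv, ifelse(t < pre + dur, step_mv, post_mv))
  sweep(v = v, fs = fs, step_on = pre, step_off = pre + dur, amp = amp,
        baseline_pa = baseline_pa)
}

# RC-style sweep: exponential charge during the step, exponential decay
# after offset, both with time constant tau_ms
rc_sweep <- function(base_mv, d_mv, tau_ms, amp = -10, fs = 20000,
                     pre = 250, dur = 1000, post = 1250, baseline_pa = 0) {
  dt <- 1000 / fs
  t <- seq(0, pre + dur + post - dt, by = dt)
  v <- rep(base_mv, length(t))
  on <- t >= pre & t < pre + dur
  v[on] <- base_mv + d_mv * (1 - exp(-(t[on] - pre) / tau_ms))
  off <- t >= pre + dur
  d_off <- d_mv * (1 - exp(-dur / tau_ms))
  v[off] <- base_mv + d_off * exp(-(t[off] - pre - dur) / tau_ms)
  sweep(v = v, fs = fs, step_on = pre, step_off = pre + dur, amp = amp,
        baseline_pa = baseline_pa)
}

# trace with stereotyped triangular action potentials at given times
template_spike_sweep <- function(spike_t, amp = 50, base_mv = -65,
                                 peak_mv = 30, half_ms = 1, fs = 20000,
                                 pre = 250, dur = 1000, post = 1250,
                                 baseline_pa = 0) {
  dt <- 1000 / fs
  t <- seq(0, pre + dur + post - dt, by = dt)
  v <- rep(base_mv, length(t))
  for (ts in spike_t) {
    idx <- which(abs(t - ts) <= half_ms)
    v[idx] <- pmax(v[idx],
                   peak_mv - (peak_mv - base_mv) * abs(t[idx] - ts) / half_ms)
  }
  sweep(v = v, fs = fs, step_on = pre, step_off = pre + dur, amp = amp,
        baseline_pa = baseline_pa)
}

# small three-sweep recording used by IO round-trip tests
tiny_recording <- function(fs = 2000, seed = 1) {
  set.seed(seed)
  sweeps <- lapply(c(-10, 0, 10), function(a) {
    dt <- 1000 / fs
    t <- seq(0, 500 - dt, by = dt)
    v <- -65 + a * 0.5 * (t >= 100 & t < 400) + rnorm(length(t), 0, 0.3)
    sweep(v = v, fs = fs, step_on = 100, step_off = 400, amp = a,
          baseline_pa = -3.25)
  })
  recording(sweeps, cell_id = "tiny", holding_mv = -65, group = "G",
            condition = "baseline", protocol = "custom")
}
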