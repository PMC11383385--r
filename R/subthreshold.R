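#' Resting membrane potential
#'
#' Mean voltage over a baseline window of a zero-bias recording,
#' mimicking the value read off immediately after switching to current
#' clamp. The recording qualifies when its sweeps carry no holding bias
#' (baseline command current 0 pA) or when it is explicitly flagged as
#' at-rest (`holding_mv` is `NA`).
#'
#' @param rec An [recording()] object.
#' @param window_ms Baseline window from sweep start (ms).
#' @return RMP (mV), or `NA` with attribute `reason` when no zero-bias
#'   segment exists.
#' @export
estimate_rmp <- function(rec, window_ms = 100) {
  sw <- rec$sweeps[[1]]
  at_rest <- is.na(rec$holding_mv) || abs(sw$baseline_pa) < 1e-9
  if (!at_rest) {
    out <- NA_real_
    attr(out, "reason") <- "no zero-bias segment: recording held with bias"
    return(out)
  }
  mean(sw$v[sw$t < window_ms])
}

#' Membrane time constant from the averaged -10 pA response
#'
#' The repetitions of the -10 pA step are averaged point-wise and the
#' time for the voltage deflection to cover all but 1/e of its span is
#' located by linear interpolation between samples. In `"onset"` mode
#' (the default) this is the charging phase after step onset, which is
#' always spike-free; in `"offset"` mode it is the relaxation after step
#' offset, analysed up to the first rebound spike if any (cells with
#' low-threshold rebound bursts routinely fire within the post-offset
#' window even for -10 pA steps, which is why onset is the default).
#'
#' @param rec A tau-protocol [recording()] (>= 2 repetitions recommended).
#' @param mode `"onset"` (default) or `"offset"`.
#' @return Time constant (ms); `NA` with attribute `reason` if the
#'   deflection never reaches the 1/e level inside the analysed window.
#'   Spikes during the step raise a contamination error.
#' @export
estimate_time_constant <- function(rec, mode = c("onset", "offset")) {
  mode <- match.arg(mode)
  sw1 <- rec$sweeps[[1]]
  vs <- vapply(rec$sweeps, function(s) s$v, numeric(length(sw1$v)))
  v <- rowMeans(vs)
  t <- sw1$t
  in_step <- t >= sw1$step_on & t < sw1$step_off
  if (any(v[in_step] > 0))
    stop("contamination error: spikes detected during the averaged step",
         call. = FALSE)
  base <- mean(v[t < sw1$step_on])
  if (mode == "offset") {
    i0 <- max(which(t < sw1$step_off))          # last in-step sample
    seg <- which(t >= sw1$step_off)
    # rebound spikes end the usable relaxation segment
    spk <- seg[v[seg] > 0]
    if (length(spk)) seg <- seg[seg < min(spk) - round(0.002 * sw1$fs)]
    d0 <- v[i0] - base
  } else {
    i0 <- min(which(t >= sw1$step_on))
    seg <- which(t >= sw1$step_on & t < sw1$step_off)
    ss <- mean(v[t >= sw1$step_off - 100 & t < sw1$step_off])
    d0 <- ss - base
  }
  if (abs(d0) < 1e-9) {
    out <- NA_real_; attr(out, "reason") <- "no measurable deflection"
    return(out)
  }
  if (mode == "offset") {
    # deflection decays from d0 toward 0
    dv <- v[seg] - base
    target <- d0 / exp(1)
    hit <- which(abs(dv) <= abs(target))
  } else {
    # deflection charges from 0 toward d0; tau when 1 - 1/e of d0 reached
    dv <- v[seg] - v[i0]
    target <- d0 * (1 - 1 / exp(1))
    hit <- which(abs(dv) >= abs(target))
  }
  if (length(hit) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "deflection never reached the 1/e level in window"
    return(out)
  }
  k <- hit[1]
  t_ref <- if (mode == "offset") sw1$step_off else sw1$step_on
  if (k == 1) return(t[seg[1]] - t_ref)
  # linear interpolation between samples k-1 and k
  y0 <- abs(dv[k - 1]); y1 <- abs(dv[k]); yt <- abs(target)
  frac <- if (mode == "offset") (y0 - yt) / (y0 - y1) else (yt - y0) / (y1 - y0)
  t[seg[k - 1]] + frac * (t[seg[k]] - t[seg[k - 1]]) - t_ref
}

#' Input resistance from the subthreshold V-I relationship
#'
#' Steady-state voltage (mean of the last `ss_window_ms` of the step) is
#' regressed on step amplitude over spike-free sweeps by ordinary least
#' squares; the slope in mV/pA (= GOhm) is returned in MOhm.
#'
#' @param rec A fine-protocol [recording()].
#' @param ss_window_ms Steady-state averaging window before step offset
#'   (ms).
#' @return List with `rn_mohm` and `vi_curve` (data.frame: `amp_pa`,
#'   `v_ss_mv`, `has_spikes`). `rn_mohm` is `NA` with attribute `reason`
#'   when fewer than 3 spike-free sweeps exist.
#' @export
estimate_input_resistance <- function(rec, ss_window_ms = 100) {
  pts <- lapply(rec$sweeps, function(sw) {
    spikes <- detect_spikes(sw)
    in_step <- any(spikes >= sw$step_on & spikes < sw$step_off)
    ss <- mean(sw$v[sw$t >= sw$step_off - ss_window_ms & sw$t < sw$step_off])
    data.frame(amp_pa = sw$amp, v_ss_mv = ss, has_spikes = in_step)
  })
  vi <- do.call(rbind, pts)
  usable <- vi[!vi$has_spikes, ]
  if (nrow(usable) < 3) {
    rn <- NA_real_
    attr(rn, "reason") <- "fewer than 3 spike-free sweeps"
    return(list(rn_mohm = rn, vi_curve = vi))
  }
  slope <- coef(lm(v_ss_mv ~ amp_pa, data = usable))[["amp_pa"]]
  list(rn_mohm = 1000 * slope, vi_curve = vi)
}

#' Voltage sag of one hyperpolarizing sweep
#'
#' Sag is the minimum voltage during the step minus the mean voltage of
#' the last 25 ms of the step; signed negative for sagging cells
#' (the peak is more hyperpolarized than the late-step steady state).
#'
#' @param sw A hyperpolarizing [sweep()] (`amp < 0`).
#' @param steady_window_ms Late-step averaging window (ms).
#' @return List of class `ep_sag`: `peak_mv`, `steady_mv`, `sag_mv`
#'   (= peak - steady), `amp_pa`.
#' @export
measure_sag <- function(sw, steady_window_ms = 25) {
  if (sw$amp >= 0)
    stop("sag is defined on hyperpolarizing sweeps only (amp < 0)",
         call. = FALSE)
  in_step <- sw$t >= sw$step_on & sw$t < sw$step_off
  peak <- min(sw$v[in_step])
  steady <- mean(sw$v[sw$t >= sw$step_off - steady_window_ms &
                        sw$t < sw$step_off])
  structure(list(peak_mv = peak, steady_mv = steady,
                 sag_mv = peak - steady, amp_pa = sw$amp),
            class = "ep_sag")
}

#' Sag at a target peak hyperpolarization
#'
#' Selects the sweep whose peak hyperpolarization is closest to
#' `target_mv` (nearest peak, no interpolation across sweeps) and returns
#' its sag measure; a flag records whether the achieved peak lies within
#' `tol_mv` of the target.
#'
#' @param rec A coarse-protocol [recording()] with hyperpolarizing sweeps.
#' @param target_mv Target peak (mV), default -100.
#' @param tol_mv Acceptability half-width (mV).
#' @return An `ep_sag` list with extra fields `target_mv`,
#'   `within_tolerance`.
#' @export
sag_at_peak_target <- function(rec, target_mv = -100, tol_mv = 5) {
  hyp <- Filter(function(s) s$amp < 0, rec$sweeps)
  if (length(hyp) == 0)
    stop("no hyperpolarizing sweeps in recording", call. = FALSE)
  peaks <- vapply(hyp, function(s)
    min(s$v[s$t >= s$step_on & s$t < s$step_off]), 0)
  k <- which.min(abs(peaks - target_mv))
  out <- measure_sag(hyp[[k]])
  out$target_mv <- target_mv
  out$within_tolerance <- abs(peaks[k] - target_mv) <= tol_mv
  out
}

#' Afterhyperpolarization of one depolarizing sweep
#'
#' Minimum membrane potential in the `window_ms` following step offset,
#' with its latency.
#'
#' @param sw A depolarizing [sweep()] (`amp > 0`).
#' @param window_ms Post-offset window (ms); 250 ms by default, 500 ms is
#'   the common alternative.
#' @return List with `ahp_mv` and `t_min_ms` (latency after offset).
#' @export
measure_ahp <- function(sw, window_ms = 250) {
  if (sw$amp <= 0)
    stop("AHP is measured after depolarizing steps (amp > 0)", call. = FALSE)
  if (sw$step_off + window_ms > max(sw$t) + 1000 / sw$fs)
    stop("window error: post-offset window exceeds the trace", call. = FALSE)
  idx <- which(sw$t > sw$step_off & sw$t <= sw$step_off + window_ms)
  k <- idx[which.min(sw$v[idx])]
  list(ahp_mv = sw$v[k], t_min_ms = sw$t[k] - sw$step_off)
}

#' Per-recording AHP
#'
#' The AHP of a recording is the minimum post-offset voltage achieved
#' across all of its depolarizing sweeps.
#'
#' @inheritParams measure_ahp
#' @param rec An [recording()] object.
#' @return List with `ahp_mv`, `t_min_ms`, and `amp_pa` of the sweep that
#'   achieved the minimum; `NA` fields (with `reason`) when the recording
#'   has no depolarizing sweeps.
#' @export
recording_ahp <- function(rec, window_ms = 250) {
  dep <- Filter(function(s) s$amp > 0, rec$sweeps)
  if (length(dep) == 0) {
    out <- list(ahp_mv = NA_real_, t_min_ms = NA_real_, amp_pa = NA_real_)
    attr(out, "reason") <- "no depolarizing sweeps"
    return(out)
  }
  ms <- lapply(dep, measure_ahp, window_ms = window_ms)
  k <- which.min(vapply(ms, function(m) m$ahp_mv, 0))
  c(ms[[k]], list(amp_pa = dep[[k]]$amp))
}

#' Drug-matched AHP readout
#'
#' For pre/post drug comparisons the post-drug membrane potential is read
#' at exactly the time point at which the AHP was maximal (most negative)
#' in the pre-drug sweep.
#'
#' @param pre_sw,post_sw Depolarizing sweeps with identical step timing.
#' @param window_ms Post-offset search window for the pre-drug minimum
#'   (ms).
#' @return List with `pre_mv`, `post_mv`, `t_match_ms` (latency after
#'   offset).
#' @export
measure_ahp_matched <- function(pre_sw, post_sw, window_ms = 250) {
  if (abs(pre_sw$step_on - post_sw$step_on) > 1e-9 ||
      abs(pre_sw$step_off - post_sw$step_off) > 1e-9)
    stop("alignment error: step timing differs between sweeps",
         call. = FALSE)
  pre <- measure_ahp(pre_sw, window_ms)
  t_abs <- pre_sw$step_off + pre$t_min_ms
  k <- which.min(abs(post_sw$t - t_abs))
  list(pre_mv = pre$ahp_mv, post_mv = post_sw$v[k], t_match_ms = pre$t_min_ms)
}
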