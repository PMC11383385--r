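#' Detect action-potential peaks
#'
#' Local maxima of the voltage trace that overshoot 0 mV (the
#' recording-inclusion criterion for healthy spikes), with a minimum
#' separation of 1 ms; when two candidate peaks fall closer than that,
#' the higher peak wins. Deterministic; an empty result is valid.
#'
#' @param sw An [sweep()] object.
#' @param min_height_mv Minimum peak voltage (mV).
#' @param min_sep_ms Minimum peak separation (ms).
#' @return Spike peak times (ms), sorted increasing.
#' @export
detect_spikes <- function(sw, min_height_mv = 0, min_sep_ms = 1) {
  v <- sw$v
  n <- length(v)
  if (n < 3) return(numeric(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  cand <- cand[v[cand] > min_height_mv]
  if (length(cand) == 0) return(numeric(0))
  keep <- logical(length(cand))
  for (j in order(v[cand], decreasing = TRUE)) {
    tj <- sw$t[cand[j]]
    if (!any(keep & abs(sw$t[cand] - tj) < min_sep_ms)) keep[j] <- TRUE
  }
  sort(sw$t[cand[keep]])
}

#' Spike threshold by the third-derivative criterion
#'
#' The voltage trace is smoothed with a short boxcar, its third
#' derivative (centered five-point stencil, mV/ms^3) is computed, and the
#' window up to `search_ms` before the spike peak is scanned for the
#' earliest contiguous excursion above the cutoff; the threshold is the
#' voltage and time at the first sample of that excursion. If no
#' crossing exists, a fallback threshold is taken where dV/dt first
#' exceeds 5% of its pre-peak maximum, and the result carries attribute
#' `fallback = TRUE`.
#'
#' @param sw An [sweep()] object.
#' @param spike_t Spike peak time (ms), e.g. from [detect_spikes()].
#' @param cutoff Third-derivative cutoff (mV/ms^3); the conventional
#'   value is 0.3.
#' @param smooth_ms Boxcar width (ms).
#' @param search_ms Backwards search window from the peak (ms).
#' @return List with `thresh_v` (mV) and `thresh_t` (ms); attribute
#'   `fallback` when the derivative criterion failed.
#' @export
spike_threshold <- function(sw, spike_t, cutoff = 0.3, smooth_ms = 0.2,
                            search_ms = 3) {
  res <- spike_thresholds(sw, spike_t, cutoff, smooth_ms, search_ms)
  out <- list(thresh_v = res$thresh_v[1], thresh_t = res$thresh_t[1])
  if (res$fallback[1]) attr(out, "fallback") <- TRUE
  out
}

# vectorized worker: thresholds for several spikes of one sweep
spike_thresholds <- function(sw, spike_t, cutoff = 0.3, smooth_ms = 0.2,
                             search_ms = 3) {
  v <- sw$v
  n <- length(v)
  dt <- 1000 / sw$fs
  w <- max(1L, round(smooth_ms / dt))
  if (w %% 2 == 0) w <- w + 1L
  vs <- if (w > 1) as.numeric(stats::filter(v, rep(1 / w, w), sides = 2)) else v
  vs[is.na(vs)] <- v[is.na(vs)]
  d3 <- rep(NA_real_, n)
  if (n >= 5)
    d3[3:(n - 2)] <- (-vs[1:(n - 4)] + 2 * vs[2:(n - 3)] -
                        2 * vs[4:(n - 1)] + vs[5:n]) / (2 * dt^3)
  half_search <- round(search_ms / dt)
  m <- length(spike_t)
  tv <- tt <- rep(NA_real_, m)
  fb <- logical(m)
  for (q in seq_len(m)) {
    pk <- which.min(abs(sw$t - spike_t[q]))
    lo <- max(3L, pk - half_search)
    idx <- seq(lo, max(lo, pk - 1L))
    above <- !is.na(d3[idx]) & d3[idx] > cutoff
    if (any(above)) {
      runs <- rle(above)
      first_run <- which(runs$values)[1]
      start <- if (first_run == 1) 1 else sum(runs$lengths[1:(first_run - 1)]) + 1
      j <- idx[start]
    } else {
      dv <- diff(v[seq(lo, pk)]) / dt
      j <- idx[which(dv >= 0.05 * max(dv))[1]]
      fb[q] <- TRUE
    }
    tv[q] <- v[j]
    tt[q] <- sw$t[j]
  }
  list(thresh_v = tv, thresh_t = tt, fallback = fb)
}

#' Classification rule constants
#'
#' The interspike-interval (ISI) rules separating burst, tonic, rebound
#' and unclassifiable ("total") spiking. The ISI ratio of spike k is
#' ISI_k / ISI_(k-1) (current over previous interval), so a ratio >= 2
#' marks a sudden doubling of the interval — the burst-to-tonic
#' transition. The second spike of a train has only one interval, hence
#' no ratio; it is admitted into a burst on the ISI < 4 ms criterion
#' alone, which is what permits two-spike bursts.
#'
#' @param burst_onset_window_ms Bursts must start within this window
#'   after step onset.
#' @param burst_isi_max_ms Maximum ISI inside a burst.
#' @param burst_isi_ratio_lo,burst_isi_ratio_hi ISI-ratio band for burst
#'   membership.
#' @param tonic_isi_ratio_min Ratio at or above which a spike becomes the
#'   first tonic spike.
#' @param max_classifiable_spikes In-step spike count above which the
#'   whole sweep is labeled "total".
#' @param rebound_window_ms Post-offset window for rebound spikes on
#'   hyperpolarizing sweeps.
#' @param accommodation_min_tonic Minimum tonic spikes for the
#'   accommodation sweep.
#' @return An object of class `ep_rules`.
#' @export
classifier_rules <- function(burst_onset_window_ms = 500,
                             burst_isi_max_ms = 4,
                             burst_isi_ratio_lo = 0.50,
                             burst_isi_ratio_hi = 1.99,
                             tonic_isi_ratio_min = 2.0,
                             max_classifiable_spikes = 15,
                             rebound_window_ms = 1000,
                             accommodation_min_tonic = 12) {
  stopifnot(burst_isi_ratio_lo < burst_isi_ratio_hi,
            burst_onset_window_ms > 0, rebound_window_ms > 0)
  structure(as.list(environment()), class = "ep_rules")
}

#' Classify the spikes of one step sweep
#'
#' Rule-based partition of spikes into burst / tonic / rebound / total /
#' other:
#' \itemize{
#' \item Hyperpolarizing sweeps (`amp < 0`): spikes within the rebound
#'   window after step offset are `rebound`; all other spikes `other`.
#' \item Depolarizing sweeps with more than `max_classifiable_spikes`
#'   spikes during the step: every spike is `total`.
#' \item Otherwise, among in-step spikes: a spike belongs to the onset
#'   burst when it lies within the burst onset window, its ISI is below
#'   the burst maximum and its ISI ratio is inside the burst band (the
#'   second spike needs no ratio); the spike preceding a qualifying
#'   burst member is the burst's first spike. The first spike whose ISI
#'   ratio reaches the tonic minimum is the first tonic spike and every
#'   later in-step spike is tonic. Everything else is `other`.
#' }
#' Spikes outside the step on depolarizing sweeps are `other`. A zero
#' amplitude sweep follows the depolarizing branch.
#'
#' @param spike_t Sorted spike peak times (ms).
#' @param amp Step amplitude (pA).
#' @param step_on,step_off Step timing (ms).
#' @param rules An [classifier_rules()] object.
#' @return An object of class `ep_spikes`: list with `spike_t`, `label`,
#'   `isi` (NA for the first spike), `isi_ratio` (NA for the first two),
#'   `amp`, `step_on`, `step_off`.
#' @export
classify_step_spikes <- function(spike_t, amp, step_on, step_off,
                                 rules = classifier_rules()) {
  if (anyNA(spike_t) || is.unsorted(spike_t, strictly = TRUE))
    stop("spike times must be strictly increasing and complete",
         call. = FALSE)
  n <- length(spike_t)
  isi <- c(NA_real_, diff(spike_t))
  ratio <- rep(NA_real_, n)
  if (n >= 3) ratio[3:n] <- isi[3:n] / isi[2:(n - 1)]
  label <- rep("other", n)
  if (amp < 0) {
    reb <- spike_t > step_off &
      spike_t <= step_off + rules$rebound_window_ms
    label[reb] <- "rebound"
  } else if (n > 0) {
    in_step <- spike_t >= step_on & spike_t < step_off
    if (sum(in_step) > rules$max_classifiable_spikes) {
      label[] <- "total"
    } else {
      # rules operate on the step-evoked train: ISIs and ratios are taken
      # over the in-step subsequence
      ks <- which(in_step)
      ts <- spike_t[ks]
      m <- length(ts)
      isi_s <- c(NA_real_, diff(ts))
      ratio_s <- rep(NA_real_, m)
      if (m >= 3) ratio_s[3:m] <- isi_s[3:m] / isi_s[2:(m - 1)]
      first_tonic <-
        which(!is.na(ratio_s) & ratio_s >= rules$tonic_isi_ratio_min)[1]
      lab_s <- rep("other", m)
      for (j in seq_len(m)) {
        if (!is.na(first_tonic) && j >= first_tonic) {
          lab_s[j] <- "tonic"
        } else if (j >= 2 &&
                   (ts[j] - step_on) <= rules$burst_onset_window_ms &&
                   isi_s[j] < rules$burst_isi_max_ms &&
                   (j == 2 ||
                      (ratio_s[j] >= rules$burst_isi_ratio_lo &&
                         ratio_s[j] <= rules$burst_isi_ratio_hi))) {
          lab_s[j] <- "burst"
        }
      }
      # the spike leading a qualifying burst is the burst's first spike
      if (m >= 2 && lab_s[2] == "burst" &&
          (is.na(first_tonic) || first_tonic > 1))
        lab_s[1] <- "burst"
      label[ks] <- lab_s
    }
  }
  structure(list(spike_t = spike_t, label = label, isi = isi,
                 isi_ratio = ratio, amp = amp, step_on = step_on,
                 step_off = step_off),
            class = "ep_spikes")
}

#' @export
print.ep_spikes <- function(x, ...) {
  cat(sprintf("<ep_spikes> %d spikes (amp %g pA): %s\n", length(x$spike_t),
              x$amp, paste(x$label, collapse = " ")))
  invisible(x)
}

#' Classify every sweep of a recording
#'
#' Runs [detect_spikes()], [classify_step_spikes()] and (optionally)
#' [spike_threshold()] over all sweeps.
#'
#' @param rec An [recording()] object.
#' @param rules An [classifier_rules()] object.
#' @param thresholds Compute per-spike thresholds as well.
#' @return Named list (by sweep id) of `ep_spikes`, each with `thresh_v`
#'   and `thresh_t` fields when `thresholds = TRUE`.
#' @export
classify_recording <- function(rec, rules = classifier_rules(),
                               thresholds = FALSE) {
  out <- lapply(rec$sweeps, function(sw) {
    st <- detect_spikes(sw)
    cls <- classify_step_spikes(st, sw$amp, sw$step_on, sw$step_off, rules)
    if (thresholds && length(st) > 0) {
      th <- spike_thresholds(sw, st)
      cls$thresh_v <- th$thresh_v
      cls$thresh_t <- th$thresh_t
    }
    cls
  })
  names(out) <- vapply(rec$sweeps, function(s) s$sweep_id, "")
  out
}

#' Rheobase per firing mode
#'
#' The minimum input current eliciting a given spike class: for
#' `"tonic"` and `"burst_depol"`, the smallest depolarizing amplitude
#' whose sweep contains at least one spike of that class; for
#' `"rebound"`, the hyperpolarizing amplitude of smallest magnitude whose
#' sweep contains a rebound burst (>= 2 rebound spikes — single rebound
#' spikes do not qualify). Also reports the threshold voltage of the
#' first spike of that class at rheobase and, for rebound, the in-step
#' steady-state voltage of the rheobase sweep.
#'
#' @param rec An [recording()] object (fine protocol, typically).
#' @param mode `"tonic"`, `"burst_depol"` or `"rebound"`.
#' @param rules An [classifier_rules()] object.
#' @param cls Optional precomputed [classify_recording()] result.
#' @param ss_window_ms Steady-state window for the rebound sweep (ms).
#' @return List with `rheobase_pa`, `thresh_v_mv`, `thresh_t_ms`,
#'   `steady_mv` (rebound only, else `NA`), `sweep_id`; all `NA` with
#'   attribute `reason` when the class was never elicited.
#' @export
rheobase <- function(rec, mode = c("tonic", "burst_depol", "rebound"),
                     rules = classifier_rules(), cls = NULL,
                     ss_window_ms = 100) {
  mode <- match.arg(mode)
  if (is.null(cls)) cls <- classify_recording(rec, rules)
  amps <- sweep_amps(rec)
  want <- switch(mode, tonic = "tonic", burst_depol = "burst",
                 rebound = "rebound")
  need <- if (mode == "rebound") 2L else 1L
  hit <- vapply(cls, function(x) sum(x$label == want) >= need, TRUE)
  ok <- if (mode == "rebound") hit & amps < 0 else hit & amps > 0
  if (!any(ok)) {
    out <- list(rheobase_pa = NA_real_, thresh_v_mv = NA_real_,
                thresh_t_ms = NA_real_, steady_mv = NA_real_,
                sweep_id = NA_character_)
    attr(out, "reason") <- paste0("no sweep elicited ", mode, " spiking")
    return(out)
  }
  k <- which(ok)[which.min(abs(amps[ok]))]
  sw <- rec$sweeps[[k]]
  first_t <- cls[[k]]$spike_t[cls[[k]]$label == want][1]
  th <- spike_threshold(sw, first_t)
  steady <- NA_real_
  if (mode == "rebound")
    steady <- mean(sw$v[sw$t >= sw$step_off - ss_window_ms &
                          sw$t < sw$step_off])
  list(rheobase_pa = sw$amp, thresh_v_mv = th$thresh_v,
       thresh_t_ms = th$thresh_t, steady_mv = steady,
       sweep_id = sw$sweep_id)
}

#' Accommodation index
#'
#' In the lowest-amplitude depolarizing sweep with at least
#' `accommodation_min_tonic` tonic spikes, the least-squares slope of the
#' tonic interspike intervals against interval number — positive when
#' firing slows over the step.
#'
#' @param rec An [recording()] object.
#' @param rules An [classifier_rules()] object.
#' @param cls Optional precomputed [classify_recording()] result.
#' @return List with `slope_ms_per_interval` and `amp_used_pa`; `NA` with
#'   attribute `reason` when no sweep qualifies.
#' @export
accommodation_index <- function(rec, rules = classifier_rules(),
                                cls = NULL) {
  if (is.null(cls)) cls <- classify_recording(rec, rules)
  amps <- sweep_amps(rec)
  n_tonic <- vapply(cls, function(x) sum(x$label == "tonic"), 0L)
  ok <- amps > 0 & n_tonic >= rules$accommodation_min_tonic
  if (!any(ok)) {
    out <- list(slope_ms_per_interval = NA_real_, amp_used_pa = NA_real_)
    attr(out, "reason") <-
      sprintf("no depolarizing sweep with >= %d tonic spikes",
              rules$accommodation_min_tonic)
    return(out)
  }
  k <- which(ok)[which.min(amps[ok])]
  tt <- cls[[k]]$spike_t[cls[[k]]$label == "tonic"]
  isis <- diff(tt)
  slope <- coef(lm(isis ~ seq_along(isis)))[[2]]
  list(slope_ms_per_interval = slope, amp_used_pa = amps[k])
}

#' Firing-rate curves by spike class
#'
#' Per-amplitude spike counts by class. The tonic series includes
#' zero-spike sweeps; burst statistics exclude sweeps in which no burst
#' was fired (`include_burst` marks the sweeps that enter burst
#' averages).
#'
#' @param rec An [recording()] object.
#' @param rules An [classifier_rules()] object.
#' @param cls Optional precomputed [classify_recording()] result.
#' @return data.frame with columns `amp_pa`, `n_spikes`, `n_burst`,
#'   `n_tonic`, `n_rebound`, `n_total_label`, `include_burst`.
#' @export
fi_curve <- function(rec, rules = classifier_rules(), cls = NULL) {
  if (is.null(cls)) cls <- classify_recording(rec, rules)
  amps <- sweep_amps(rec)
  cnt <- function(x, lab) sum(x$label == lab)
  out <- data.frame(
    amp_pa = amps,
    n_spikes = vapply(cls, function(x) length(x$spike_t), 0L),
    n_burst = vapply(cls, cnt, 0L, lab = "burst"),
    n_tonic = vapply(cls, cnt, 0L, lab = "tonic"),
    n_rebound = vapply(cls, cnt, 0L, lab = "rebound"),
    n_total_label = vapply(cls, cnt, 0L, lab = "total"),
    row.names = NULL)
  out$include_burst <- out$amp_pa > 0 & out$n_burst > 0
  out
}
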