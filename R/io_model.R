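#' Construct a single current-clamp sweep
#'
#' A sweep is one stimulus episode: a uniformly sampled membrane-voltage
#' trace together with the command-current trace and the square-step
#' timing that produced it. Units follow patch-clamp convention throughout
#' the package: time in ms, voltage in mV, current in pA, sampling rate in
#' Hz.
#'
#' @param v Membrane potential trace (mV).
#' @param fs Sampling rate (Hz).
#' @param step_on,step_off Step onset/offset (ms from sweep start).
#' @param amp Step amplitude (pA), relative to the pre-step baseline
#'   current.
#' @param baseline_pa Constant command current outside the step (pA),
#'   i.e. the holding bias.
#' @param sweep_id Identifier; defaults to the amplitude.
#' @param i Optional explicit command-current trace (pA); reconstructed
#'   from the step description when missing.
#' @param t Optional explicit time axis (ms); reconstructed from `fs`.
#' @return An object of class `ep_sweep`: a list with fields `sweep_id`,
#'   `t`, `v`, `i`, `fs`, `step_on`, `step_off`, `amp`, `baseline_pa`.
#' @export
sweep <- function(v, fs, step_on, step_off, amp, baseline_pa = 0,
                  sweep_id = NULL, i = NULL, t = NULL) {
  n <- length(v)
  if (is.null(t)) t <- (seq_len(n) - 1) * (1000 / fs)
  if (is.null(i)) {
    i <- rep(baseline_pa, n)
    i[t >= step_on & t < step_off] <- baseline_pa + amp
  }
  if (is.null(sweep_id)) sweep_id <- paste0("amp_", amp)
  sw <- structure(
    list(sweep_id = as.character(sweep_id), t = t, v = v, i = i, fs = fs,
         step_on = step_on, step_off = step_off, amp = amp,
         baseline_pa = baseline_pa),
    class = "ep_sweep")
  validate_sweep(sw)
  sw
}

validate_sweep <- function(sw, tol_pa = 1e-6) {
  n <- length(sw$t)
  if (length(sw$v) != n || length(sw$i) != n)
    stop("sweep fields t, v, i must have equal length", call. = FALSE)
  dt <- 1000 / sw$fs
  dts <- diff(sw$t)
  if (any(dts <= 0) || any(abs(dts - dt) > dt * 1e-6))
    stop("sampling error: time base is not uniform at 1000/fs ms spacing",
         call. = FALSE)
  if (!(sw$step_on < sw$step_off && sw$step_off <= max(sw$t) + dt))
    stop("step timing invalid: need step_on < step_off <= max(t)",
         call. = FALSE)
  in_step <- sw$t >= sw$step_on & sw$t < sw$step_off
  expected <- sw$baseline_pa + ifelse(in_step, sw$amp, 0)
  if (any(abs(sw$i - expected) > tol_pa))
    stop("consistency error: command current does not match a ",
         sw$amp, " pA square step on a ", sw$baseline_pa, " pA baseline",
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a recording (ordered sweeps from one cell)
#'
#' @param sweeps List of [sweep()] objects, all sharing sampling rate and
#'   step timing. Sweeps are reordered by ascending step amplitude.
#' @param cell_id Cell identifier.
#' @param holding_mv Target holding potential (mV); `NA` for recordings at
#'   rest.
#' @param group Group label (e.g. `"MD-M"`, `"MD-L"`).
#' @param condition Condition label (`"baseline"`, `"ZD7288"`, ...).
#' @param protocol Protocol label (`"fine"`, `"coarse"`, `"tau"`, `"rmp"`,
#'   or custom).
#' @return An object of class `ep_recording`.
#' @export
recording <- function(sweeps, cell_id = "cell", holding_mv = -65,
                      group = NA_character_, condition = "baseline",
                      protocol = "custom") {
  if (length(sweeps) == 0)
    stop("validation error: a recording needs at least one sweep",
         call. = FALSE)
  fs <- vapply(sweeps, function(s) s$fs, 0)
  on <- vapply(sweeps, function(s) s$step_on, 0)
  off <- vapply(sweeps, function(s) s$step_off, 0)
  if (length(unique(fs)) != 1 || length(unique(on)) != 1 ||
      length(unique(off)) != 1)
    stop("all sweeps in a recording must share fs and step timing",
         call. = FALSE)
  amps <- vapply(sweeps, function(s) s$amp, 0)
  ord <- order(amps, vapply(sweeps, function(s) s$sweep_id, ""))
  structure(
    list(cell_id = cell_id, sweeps = sweeps[ord], holding_mv = holding_mv,
         group = group, condition = condition, protocol = protocol),
    class = "ep_recording")
}

#' @export
print.ep_recording <- function(x, ...) {
  amps <- vapply(x$sweeps, function(s) s$amp, 0)
  cat(sprintf(
    "<ep_recording> cell %s | group %s | condition %s | protocol %s\n",
    x$cell_id, x$group, x$condition, x$protocol))
  cat(sprintf("  %d sweeps, fs = %g Hz, step [%g, %g) ms, amps %g..%g pA\n",
              length(x$sweeps), x$sweeps[[1]]$fs, x$sweeps[[1]]$step_on,
              x$sweeps[[1]]$step_off, min(amps), max(amps)))
  invisible(x)
}

#' @export
plot.ep_sweep <- function(x, ...) {
  graphics::plot(x$t, x$v, type = "l", xlab = "time (ms)",
                 ylab = "membrane potential (mV)",
                 main = sprintf("sweep %s (%g pA)", x$sweep_id, x$amp), ...)
  invisible(x)
}

sweep_amps <- function(rec) vapply(rec$sweeps, function(s) s$amp, 0)

#' Stimulus protocol description
#'
#' The three standard episodic protocols are square 1,000-ms current
#' steps: a fine series (-60 to +60 pA in 5 pA increments) used for input
#' resistance, rheobase and firing-mode analysis; a coarse series (-250
#' to +350 pA in 25 pA increments) used for voltage sag; and a tau series
#' (-10 pA repeated 10 times) averaged for the membrane time constant.
#'
#' @param name Protocol label.
#' @param amps Step amplitudes (pA).
#' @param step_dur,pre_dur,post_dur Step / pre-step / post-step durations
#'   (ms). The post-step window defaults to 1,250 ms so that the 1-s
#'   rebound-spike window (plus margin) fits after step offset.
#' @param n_reps Repetitions per amplitude.
#' @return An object of class `ep_protocol`.
#' @export
protocol_spec <- function(name, amps, step_dur = 1000, pre_dur = 250,
                          post_dur = 1250, n_reps = 1) {
  stopifnot(length(amps) >= 1, step_dur > 0, pre_dur >= 0, post_dur >= 0,
            n_reps >= 1)
  structure(list(name = name, amps = sort(amps), step_dur = step_dur,
                 pre_dur = pre_dur, post_dur = post_dur, n_reps = n_reps),
            class = "ep_protocol")
}

#' @rdname protocol_spec
#' @export
protocol_fine <- function() protocol_spec("fine", seq(-60, 60, by = 5))

#' @rdname protocol_spec
#' @export
protocol_coarse <- function() protocol_spec("coarse", seq(-250, 350, by = 25))

#' @rdname protocol_spec
#' @export
protocol_tau <- function() protocol_spec("tau", -10, n_reps = 10)

#' Write a recording as a sweep-table CSV plus JSON sidecar
#'
#' The canonical on-disk format: a long CSV with header
#' `sweep_id,t_ms,v_mV,i_pA` (comma separator, dot decimal, UTF-8) and a
#' JSON sidecar holding sampling rate, step timing, per-sweep amplitudes
#' and labels. Numeric values are written with 17 significant digits so
#' that write-then-read round-trips are lossless at double precision.
#'
#' @param rec An [recording()] object.
#' @param path CSV path. The sidecar defaults to the same path with
#'   extension `.json`.
#' @param sidecar Optional explicit sidecar path.
#' @return Invisibly, the CSV path.
#' @export
write_sweep_table <- function(rec, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  if (length(rec$sweeps) == 0)
    stop("validation error: empty sweep list, nothing written", call. = FALSE)
  for (sw in rec$sweeps) validate_sweep(sw)
  tabs <- lapply(rec$sweeps, function(sw)
    data.table::data.table(sweep_id = sw$sweep_id,
                           t_ms = sprintf("%.17g", sw$t),
                           v_mV = sprintf("%.17g", sw$v),
                           i_pA = sprintf("%.17g", sw$i)))
  data.table::fwrite(data.table::rbindlist(tabs), path, quote = FALSE)
  meta <- list(
    cell_id = rec$cell_id, holding_mv = rec$holding_mv, group = rec$group,
    condition = rec$condition, protocol = rec$protocol,
    fs = rec$sweeps[[1]]$fs,
    step_on = rec$sweeps[[1]]$step_on, step_off = rec$sweeps[[1]]$step_off,
    sweeps = lapply(rec$sweeps, function(sw)
      list(sweep_id = sw$sweep_id, amp = sw$amp,
           baseline_pa = sw$baseline_pa)))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Read a sweep-table CSV plus JSON sidecar
#'
#' @param path CSV path written by [write_sweep_table()] (or produced
#'   externally in the same dialect).
#' @param sidecar Sidecar JSON path; defaults to `path` with extension
#'   `.json`.
#' @return An [recording()] object. Sweeps are ordered by ascending
#'   amplitude regardless of row order in the file.
#' @export
read_sweep_table <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  tab <- data.table::fread(path, colClasses = list(
    character = "sweep_id", numeric = c("t_ms", "v_mV", "i_pA")))
  need <- c("sweep_id", "t_ms", "v_mV", "i_pA")
  if (!all(need %in% names(tab)))
    stop("format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  fs <- meta$fs
  dt <- 1000 / fs
  sweeps <- lapply(meta$sweeps, function(m) {
    rows <- tab[tab$sweep_id == m$sweep_id, ]
    if (nrow(rows) == 0)
      stop("consistency error: sweep ", m$sweep_id,
           " listed in sidecar but absent from table", call. = FALSE)
    tvec <- rows$t_ms
    jit <- abs(diff(tvec) - dt)
    if (any(jit > dt * 1e-6))
      stop("sampling error: non-uniform time base in sweep ", m$sweep_id,
           call. = FALSE)
    sw <- structure(
      list(sweep_id = m$sweep_id, t = tvec, v = rows$v_mV, i = rows$i_pA,
           fs = fs, step_on = meta$step_on, step_off = meta$step_off,
           amp = m$amp, baseline_pa = m$baseline_pa),
      class = "ep_sweep")
    validate_sweep(sw)  # consistency error when sidecar amp != i column
    sw
  })
  recording(sweeps, cell_id = meta$cell_id,
            holding_mv = if (is.null(meta$holding_mv)) NA_real_ else meta$holding_mv,
            group = if (is.null(meta$group)) NA_character_ else meta$group,
            condition = meta$condition, protocol = meta$protocol)
}

#' Validate a recording against a protocol description
#'
#' Report-only check: lists missing step amplitudes, step-timing
#' deviations, and holding-potential violations (pre-step baseline outside
#' the -65 +/- 3 mV holding band for held protocols). The recording
#' passes iff the report is empty.
#'
#' @param rec An [recording()] object.
#' @param spec An [protocol_spec()] object.
#' @param holding_band Acceptable holding range (mV), default
#'   `c(-68, -62)`.
#' @return An object of class `ep_validation`: list with
#'   `missing_amps`, `timing`, `holding` and logical `pass`.
#' @export
validate_protocol <- function(rec, spec, holding_band = c(-68, -62)) {
  amps <- sweep_amps(rec)
  missing_amps <- setdiff(spec$amps, amps)
  timing <- character(0)
  sw1 <- rec$sweeps[[1]]
  if (abs((sw1$step_off - sw1$step_on) - spec$step_dur) > 1e-6)
    timing <- c(timing, sprintf("step duration %g ms, expected %g ms",
                                sw1$step_off - sw1$step_on, spec$step_dur))
  if (abs(sw1$step_on - spec$pre_dur) > 1e-6)
    timing <- c(timing, sprintf("step onset %g ms, expected %g ms",
                                sw1$step_on, spec$pre_dur))
  holding <- character(0)
  if (!is.na(rec$holding_mv)) {
    for (sw in rec$sweeps) {
      base <- mean(sw$v[sw$t < sw$step_on])
      if (base < holding_band[1] || base > holding_band[2]) {
        holding <- sprintf(
          "pre-step baseline %.2f mV outside holding band [%g, %g] mV",
          base, holding_band[1], holding_band[2])
        break
      }
    }
  }
  reps <- table(amps)
  if (spec$n_reps == 1 && any(reps > 1))
    timing <- c(timing, "duplicate amplitudes in a single-repetition protocol")
  structure(list(missing_amps = missing_amps, timing = timing,
                 holding = holding,
                 pass = length(missing_amps) == 0 && length(timing) == 0 &&
                   length(holding) == 0),
            class = "ep_validation")
}

#' @export
print.ep_validation <- function(x, ...) {
  cat("<ep_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$missing_amps))
    cat("  missing amplitudes (pA):", paste(x$missing_amps, collapse = ", "), "\n")
  for (m in x$timing) cat("  timing:", m, "\n")
  for (m in x$holding) cat("  holding:", m, "\n")
  invisible(x)
}
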