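#' Pipeline configuration
#'
#' Bundles every tunable the pipeline uses, with the defaults the
#' estimators are documented with. Unknown names are rejected up front.
#'
#' @param ... Overrides of the defaults listed below.
#' @return Object of class `ep_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tau_mode = "onset",           # membrane-time-constant segment
    rn_ss_window_ms = 100,        # steady-state window for the V-I fit
    sag_target_mv = -100,         # normalized sag readout peak
    sag_tol_mv = 5,
    ahp_window_ms = 250,          # post-offset AHP window
    rules = classifier_rules(),
    n_boot = 5000,
    seed = 1,
    hold_mv = -65,
    fs = 20000)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "ep_config")
}

#' Extract the per-cell intrinsic-property vector
#'
#' Runs every feature estimator over one cell's protocol set and returns
#' a one-row data.frame (the cell's feature vector). Features that cannot
#' be measured are `NA` and the reasons are collected in the `flags`
#' attribute — missing values are never silently zero.
#'
#' @param rec_fine Fine-protocol recording (input resistance, rheobase,
#'   firing modes, AHP).
#' @param rec_coarse Coarse-protocol recording (voltage sag).
#' @param rec_tau Tau-protocol recording (repeated -10 pA steps).
#' @param rec_rmp Optional zero-bias recording for the resting potential.
#' @param config An [pipeline_config()] object.
#' @return One-row data.frame with the feature columns; attribute
#'   `flags` names each missing feature with its reason.
#' @export
extract_features <- function(rec_fine, rec_coarse, rec_tau, rec_rmp = NULL,
                             config = pipeline_config()) {
  flags <- character(0)
  note <- function(field, val) {
    if (length(val) == 1 && is.na(val)) {
      r <- attr(val, "reason")
      flags[[field]] <<- if (is.null(r)) "not measurable" else r
    }
    as.numeric(val)
  }

  rmp <- if (is.null(rec_rmp)) {
    flags[["rmp_mv"]] <- "no zero-bias recording supplied"
    NA_real_
  } else note("rmp_mv", estimate_rmp(rec_rmp))

  tau <- note("tau_ms", estimate_time_constant(rec_tau, mode = config$tau_mode))
  rn <- note("rn_mohm",
             estimate_input_resistance(
               rec_fine, ss_window_ms = config$rn_ss_window_ms)$rn_mohm)
  sag <- sag_at_peak_target(rec_coarse, target_mv = config$sag_target_mv,
                            tol_mv = config$sag_tol_mv)
  ahp <- recording_ahp(rec_fine, window_ms = config$ahp_window_ms)
  if (is.na(ahp$ahp_mv)) flags[["ahp_mv"]] <- attr(ahp, "reason")

  cls <- classify_recording(rec_fine, config$rules)
  rh_t <- rheobase(rec_fine, "tonic", config$rules, cls = cls)
  rh_b <- rheobase(rec_fine, "burst_depol", config$rules, cls = cls)
  rh_r <- rheobase(rec_fine, "rebound", config$rules, cls = cls)
  for (nm in c("tonic", "burst", "rebound")) {
    obj <- switch(nm, tonic = rh_t, burst = rh_b, rebound = rh_r)
    if (is.na(obj$rheobase_pa)) {
      flags[[paste0("rheobase_", nm, "_pa")]] <- attr(obj, "reason")
      flags[[paste0("thresh_", nm, "_mv")]] <- attr(obj, "reason")
      if (nm == "rebound")
        flags[["steady_state_at_rebound_rheobase_mv"]] <- attr(obj, "reason")
    }
  }
  acc <- accommodation_index(rec_fine, config$rules, cls = cls)
  if (is.na(acc$slope_ms_per_interval)) {
    # fall back to the coarse protocol when the fine steps never reach
    # the required tonic train
    acc2 <- accommodation_index(rec_coarse, config$rules)
    if (!is.na(acc2$slope_ms_per_interval)) acc <- acc2
    else flags[["accommodation_index"]] <- attr(acc, "reason")
  }
  fi <- fi_curve(rec_fine, config$rules, cls = cls)
  total_spikes <- sum(fi$n_spikes[fi$amp_pa > 0])
  burst_sizes <- fi$n_burst[fi$include_burst]
  burst_mean <- if (length(burst_sizes)) mean(burst_sizes) else {
    flags[["burst_spikes_mean"]] <- "no depolarization-evoked bursts"
    NA_real_
  }

  out <- data.frame(
    cell_id = rec_fine$cell_id, group = rec_fine$group,
    condition = rec_fine$condition,
    rmp_mv = rmp, tau_ms = tau, rn_mohm = rn,
    sag_at_100_mv = sag$sag_mv, ahp_mv = ahp$ahp_mv,
    rheobase_tonic_pa = rh_t$rheobase_pa,
    rheobase_burst_pa = rh_b$rheobase_pa,
    rheobase_rebound_pa = rh_r$rheobase_pa,
    thresh_tonic_mv = rh_t$thresh_v_mv,
    thresh_burst_mv = rh_b$thresh_v_mv,
    thresh_rebound_mv = rh_r$thresh_v_mv,
    accommodation_index = acc$slope_ms_per_interval,
    steady_state_at_rebound_rheobase_mv = rh_r$steady_mv,
    burst_spikes_mean = burst_mean,
    total_spikes_fine = total_spikes,
    sag_within_tolerance = sag$within_tolerance,
    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}

#' Simulate the full protocol battery for one cell
#'
#' Fine, coarse and tau protocols at the holding potential plus a short
#' zero-bias recording for the resting potential.
#'
#' @param p An `ep_simparams` object.
#' @param hold_mv Holding potential (mV).
#' @param fs Sampling rate (Hz).
#' @param group,condition,cell_id Labels.
#' @return List with elements `fine`, `coarse`, `tau`, `rmp`.
#' @export
simulate_cell_recordings <- function(p, hold_mv = -65, fs = 20000,
                                     group = NA_character_,
                                     condition = "baseline",
                                     cell_id = "cell") {
  rmp_spec <- protocol_spec("rmp", 0, step_dur = 100, pre_dur = 200,
                            post_dur = 0)
  rmp_rec <- simulate_protocol(p, rmp_spec, hold_mv = NA, fs = fs,
                               group = group, condition = condition,
                               cell_id = cell_id)
  list(
    fine = simulate_protocol(p, protocol_fine(), hold_mv, fs, group,
                             condition, cell_id),
    coarse = simulate_protocol(p, protocol_coarse(), hold_mv, fs, group,
                               condition, cell_id),
    tau = simulate_protocol(p, protocol_tau(), hold_mv, fs, group,
                            condition, cell_id),
    rmp = rmp_rec)
}

#' Simulate and extract features for a whole population
#'
#' @param pop A [make_population()] result (list of `list(params, truth)`).
#' @param group Group label stamped on every cell.
#' @param condition Condition label.
#' @param config An [pipeline_config()] object.
#' @return data.frame with one feature row per cell; attribute
#'   `flags` is a named list of per-cell flag sets.
#' @export
population_features <- function(pop, group, condition = "baseline",
                                config = pipeline_config()) {
  rows <- vector("list", length(pop))
  flags <- vector("list", length(pop))
  for (i in seq_along(pop)) {
    cid <- sprintf("%s_%02d", group, i)
    recs <- simulate_cell_recordings(pop[[i]]$params,
                                     hold_mv = config$hold_mv,
                                     fs = config$fs, group = group,
                                     condition = condition, cell_id = cid)
    row <- extract_features(recs$fine, recs$coarse, recs$tau, recs$rmp,
                            config)
    rows[[i]] <- row
    flags[[i]] <- attr(row, "flags")
  }
  out <- do.call(rbind, rows)
  names(flags) <- out$cell_id
  attr(out, "flags") <- flags
  out
}

#' Compare two groups feature by feature
#'
#' Applies [compare_two_groups()] to every requested feature column of a
#' feature table split by a group column. The first group level (sorted,
#' or the order of `ref` when given) is the reference, so median
#' differences read "other minus reference".
#'
#' @param features Feature data.frame (rows = cells).
#' @param group_col Name of the grouping column.
#' @param columns Feature columns to compare; defaults to all numeric
#'   columns.
#' @param ref Reference group level; defaults to the first sorted level.
#' @param n_boot,seed Bootstrap settings.
#' @return List of class `ep_report`: `comparisons` (named list of
#'   `ep_comparison`), `table` (summary data.frame), `ref`, `other`.
#'   Groups with fewer than 5 usable cells trigger an under-powered
#'   warning.
#' @export
compare_groups <- function(features, group_col = "group", columns = NULL,
                           ref = NULL, n_boot = 5000, seed = 1) {
  g <- features[[group_col]]
  lev <- unique(g)
  if (length(lev) != 2)
    stop("compare_groups needs exactly two groups, found ",
         length(lev), call. = FALSE)
  if (is.null(ref)) ref <- sort(lev)[1]
  other <- setdiff(lev, ref)
  if (is.null(columns)) {
    num <- vapply(features, is.numeric, TRUE)
    columns <- setdiff(names(features)[num], group_col)
  }
  comparisons <- list()
  for (col in columns) {
    x <- features[[col]][g == ref]
    y <- features[[col]][g == other]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    if (length(x) < 5 || length(y) < 5)
      warning("under-powered comparison for ", col,
              ": fewer than 5 cells in a group", call. = FALSE)
    comparisons[[col]] <- compare_two_groups(x, y, n_boot = n_boot,
                                             seed = seed, label = col)
  }
  tab <- do.call(rbind, lapply(comparisons, function(cm)
    data.frame(feature = cm$label, statistic = cm$statistic,
               p_value = cm$p_value,
               median_ref = cm$median_a, median_other = cm$median_b,
               median_diff = cm$median_diff,
               ci_diff_lo = cm$ci_diff[1], ci_diff_hi = cm$ci_diff[2],
               eta_sq = cm$eta_sq, n_ref = cm$n_a, n_other = cm$n_b,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(comparisons = comparisons, table = tab, ref = ref,
                 other = other),
            class = "ep_report")
}

#' @export
print.ep_report <- function(x, ...) {
  cat(sprintf("<ep_report> %s (reference) vs %s\n", x$ref, x$other))
  print(x$table[, c("feature", "p_value", "median_ref", "median_other",
                    "median_diff", "eta_sq")], digits = 4)
  invisible(x)
}

#' Run the simulate -> extract -> compare pipeline
#'
#' Simulates two labeled populations, extracts the per-cell feature
#' vectors, compares the groups, and (optionally) writes the artifact
#' set: feature CSV, comparison CSV, and a JSON summary stamped with the
#' seed and a configuration hash.
#'
#' @param n Cells per group.
#' @param cv Between-cell coefficient of variation.
#' @param seed Master seed (drives simulation and bootstrap).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config An [pipeline_config()] object.
#' @param presets Two preset names (reference first).
#' @return An `ep_report` with an extra `features` element (and
#'   `artifacts` when files were written).
#' @export
run_pipeline <- function(n = 20, cv = 0.2, seed = 1, out_dir = NULL,
                         config = pipeline_config(),
                         presets = c("MD-M", "MD-L")) {
  pop_a <- make_population(presets[1], n = n, cv = cv, seed = seed)
  pop_b <- make_population(presets[2], n = n, cv = cv, seed = seed + 500000)
  fa <- population_features(pop_a, group = presets[1], config = config)
  fb <- population_features(pop_b, group = presets[2], config = config)
  features <- rbind(fa, fb)
  report <- compare_groups(features, n_boot = config$n_boot,
                           seed = config$seed, ref = presets[1])
  report$features <- features
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fcsv <- file.path(out_dir, "features.csv")
    ccsv <- file.path(out_dir, "comparisons.csv")
    jpath <- file.path(out_dir, "summary.json")
    data.table::fwrite(features, fcsv)
    data.table::fwrite(report$table, ccsv)
    jsonlite::write_json(
      list(seed = seed, n_per_group = n, cv = cv,
           config_hash = config_hash(config),
           presets = presets,
           comparisons = report$table),
      jpath, auto_unbox = TRUE, digits = NA)
    report$artifacts <- c(features = fcsv, comparisons = ccsv,
                          summary = jpath)
  }
  report
}

# order-independent FNV-style hash of the configuration, for provenance
# stamping of artifacts
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwXor(h * 16777619 %% 2^31, ch) %% 2^31
  sprintf("%08x", h)
}
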