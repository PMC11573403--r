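# Cystometrogram processing: preprocessing, pump correction, cycle
# segmentation and urodynamic parameter extraction.
#
# Conventions: a cycle is one constant-rate saline fill ending in a void.
# A 30-s baseline precedes the fill.  The storage phase runs from fill
# start to void onset; a leak (if any) happens inside storage and does not
# terminate it.  Normalized pressures are raw pressures minus the mean
# baseline vesical pressure of the same cycle.

event_time <- function(rec, kind) {
  tt <- rec$events$time_s[rec$events$kind == kind]
  if (length(tt)) tt[1L] else NA_real_
}

#' Preprocess a cystometry recording
#'
#' Removes linear drift (slope-only fit over the full trace, mean level
#' preserved) and applies a zero-phase low-pass Butterworth filter (default
#' 4th order, 5 Hz cutoff) to both pressure channels.  Events and metadata
#' are untouched.
#'
#' @param rec A [cmg_recording()].
#' @param settings A [cmg_settings()] list.
#' @return A new `cmg_recording` with filtered channels.
#' @export
preprocess <- function(rec, settings = cmg_settings()) {
  validate_cmg_recording(rec)
  if (rec$sample_rate <= 2 * settings$cutoff_hz) {
    abort_config(sprintf(
      "sample_rate (%g) must exceed twice the cutoff (%g Hz)",
      rec$sample_rate, settings$cutoff_hz))
  }
  out <- rec
  for (ch in c("pves", "pura")) {
    y <- rec[[ch]]
    if (settings$detrend) y <- detrend_keep_mean(y, rec$time)
    out[[ch]] <- lowpass_zero_phase(y, rec$sample_rate, settings$cutoff_hz,
                                    settings$butter_order)
  }
  out
}

#' Correct vesical pressure for syringe-pump pressure
#'
#' During constant-rate filling the pressure transducer sees the syringe
#' pump's driving pressure on top of the physiological vesical pressure.
#' This subtracts a pump offset from `pves` within the filling window
#' `[fill_start, fill_stop]` (or trace end when no `fill_stop` exists).
#' In `"step_estimate"` mode the offset is estimated as
#' `median(pves, 5 s after fill start) - median(pves, 5 s before)`.
#'
#' @param rec A `cmg_recording` with a `fill_start` event.
#' @param mode `"constant"` (subtract `offset`) or `"step_estimate"`.
#' @param offset Pump offset in mmHg, required for `mode = "constant"`.
#' @param window_s Estimator window on each side of fill start, s.
#' @return A corrected `cmg_recording`, with the offset used stored in
#'   attribute `"pump_offset"`.
#' @export
correct_pump_pressure <- function(rec, mode = c("step_estimate", "constant"),
                                  offset = NULL, window_s = 5) {
  validate_cmg_recording(rec)
  mode <- match.arg(mode)
  t_fill <- event_time(rec, "fill_start")
  if (is.na(t_fill)) abort_segmentation("no fill_start event in recording")
  t_stop <- event_time(rec, "fill_stop")
  if (is.na(t_stop)) t_stop <- rec$time[length(rec$time)]

  if (mode == "constant") {
    if (!is_scalar_number(offset)) {
      abort_config("mode = 'constant' requires a numeric offset")
    }
    used <- offset
  } else {
    pre <- rec$pves[rec$time >= t_fill - window_s & rec$time < t_fill]
    post <- rec$pves[rec$time >= t_fill & rec$time < t_fill + window_s]
    if (!length(pre) || !length(post)) {
      abort_segmentation("not enough samples around fill_start to estimate pump offset")
    }
    used <- median(post) - median(pre)
  }
  out <- rec
  in_fill <- rec$time >= t_fill & rec$time <= t_stop
  out$pves[in_fill] <- out$pves[in_fill] - used
  attr(out, "pump_offset") <- used
  out
}

#' Segment a cystometry cycle into phases
#'
#' Locates the pre-fill baseline window (default 30 s immediately before
#' `fill_start`), the storage window (fill start to void onset, falling
#' back to `fill_stop` or trace end), and the leak time.  The leak time is
#' taken from a `leak` annotation when present; otherwise, with
#' `settings$leak_detector = TRUE`, it is the first time during storage at
#' which the high-pass residual of the urethral pressure drops below
#' `-k` robust SDs of the baseline residual (a leak produces a sharp
#' transient loss of urethral closure pressure).
#'
#' @param rec A `cmg_recording` with a `fill_start` event.
#' @param settings A [cmg_settings()] list.
#' @return A `cycle_phases` list: `baseline_window`, `fill_start`,
#'   `storage_window`, `leak_time` (or `NA`), `void_onset` (or `NA`).
#' @export
segment_cycle <- function(rec, settings = cmg_settings()) {
  validate_cmg_recording(rec)
  t_fill <- event_time(rec, "fill_start")
  if (is.na(t_fill)) abort_segmentation("no fill_start event in recording")
  t0 <- t_fill - settings$baseline_s
  if (t0 < rec$time[1L] - 1e-9) {
    abort_segmentation(sprintf(
      "baseline window (%g s) would start before the trace begins",
      settings$baseline_s))
  }
  t_void <- event_time(rec, "void_start")
  t_stop <- event_time(rec, "fill_stop")
  if (!is.na(t_void) && t_void < t_fill) {
    abort_validation("void_start precedes fill_start")
  }
  storage_end <- if (!is.na(t_void)) {
    t_void
  } else if (!is.na(t_stop)) {
    t_stop
  } else {
    rec$time[length(rec$time)]
  }

  leak_time <- event_time(rec, "leak")
  if (is.na(leak_time) && settings$leak_detector) {
    leak_time <- detect_leak_transient(rec, t0, t_fill, storage_end, settings)
  }
  if (!is.na(leak_time) &&
      (leak_time < t_fill || leak_time > storage_end)) {
    abort_validation("leak time must lie inside the storage window")
  }

  structure(list(
    baseline_window = c(t0, t_fill),
    fill_start = t_fill,
    storage_window = c(t_fill, storage_end),
    leak_time = leak_time,
    void_onset = t_void
  ), class = "cycle_phases")
}

# P_ura transient detector: threshold the high-pass residual (signal minus
# its slow low-pass component) against a robust SD measured on the baseline
# window.
detect_leak_transient <- function(rec, t0, t_fill, storage_end, settings) {
  slow <- lowpass_zero_phase(rec$pura, rec$sample_rate,
                             settings$leak_detector_cutoff_hz, 2)
  resid <- rec$pura - slow
  in_base <- rec$time >= t0 & rec$time < t_fill
  s <- max(mad(resid[in_base]), 1e-9)
  in_storage <- rec$time >= t_fill & rec$time <= storage_end
  idx <- which(in_storage & resid < -settings$leak_k * s)
  if (!length(idx)) NA_real_ else rec$time[idx[1L]]
}

#' Extract urodynamic parameters from one cycle
#'
#' Computes the per-cycle parameter set: mean baseline vesical pressure,
#' mean and maximum storage-phase vesical pressure (raw and normalized
#' against the baseline mean), leak point pressure (normalized) and leak
#' point volume, infused / voided / residual volumes, and voiding
#' efficiency.
#'
#' Volumes follow the fill arithmetic: `leak_point_volume =
#' fill_rate * (leak_time - fill_start) / 60`; `infused_volume =
#' fill_rate * (fill duration) / 60`.  Voided volume comes from recording
#' metadata when measured; residual volume prefers the measured value and
#' falls back to `infused - voided`.  `voiding_efficiency = 100 * voided /
#' (voided + residual)`, reported `NA` (not zero) when the volumes are
#' unavailable.
#'
#' @param rec A preprocessed, pump-corrected `cmg_recording`.
#' @param phases A `cycle_phases` object from [segment_cycle()].
#' @return A one-row tibble of class parameters (columns named as the
#'   parameter set).
#' @export
compute_parameters <- function(rec, phases) {
  validate_cmg_recording(rec)
  bw <- phases$baseline_window
  sw <- phases$storage_window
  in_base <- rec$time >= bw[1L] & rec$time < bw[2L]
  in_storage <- rec$time >= sw[1L] & rec$time <= sw[2L]
  if (!any(in_base)) abort_segmentation("empty baseline window")
  if (!any(in_storage)) abort_segmentation("empty storage window")

  avg_baseline <- mean(rec$pves[in_base])
  avg_storage <- mean(rec$pves[in_storage])
  max_storage <- max(rec$pves[in_storage])

  leak_norm <- NA_real_
  leak_volume <- NA_real_
  if (!is.na(phases$leak_time)) {
    j <- which.min(abs(rec$time - phases$leak_time))
    leak_norm <- rec$pves[j] - avg_baseline
    leak_volume <- rec$fill_rate * (phases$leak_time - phases$fill_start) / 60
  }

  t_stop <- event_time(rec, "fill_stop")
  fill_end <- if (!is.na(t_stop)) t_stop else sw[2L]
  infused <- rec$fill_rate * (fill_end - phases$fill_start) / 60

  voided <- rec$voided_volume_measured
  residual <- rec$residual_volume_measured
  if (is.na(residual) && !is.na(voided)) residual <- infused - voided
  efficiency <- if (!is.na(voided) && !is.na(residual) &&
                    voided + residual > 0) {
    100 * voided / (voided + residual)
  } else {
    NA_real_
  }

  tibble::tibble(
    animal_id = rec$animal_id,
    avg_baseline_pves = avg_baseline,
    avg_storage_pves = avg_storage,
    avg_storage_pves_norm = avg_storage - avg_baseline,
    max_storage_pves = max_storage,
    max_storage_pves_norm = max_storage - avg_baseline,
    leak_point_pves_norm = leak_norm,
    leak_point_volume = leak_volume,
    infused_volume = infused,
    voided_volume = voided,
    residual_volume = residual,
    voiding_efficiency = efficiency
  )
}

#' Average cycle parameters within an animal
#'
#' Arithmetic mean of each parameter across cycles, ignoring missing values
#' per field (a cycle without a leak contributes nothing to the leak
#' fields).  Records the number of cycles used.
#'
#' @param cycles A tibble of per-cycle parameters ([compute_parameters()]
#'   rows) for one animal.
#' @return A one-row tibble with an added `n_cycles` column.
#' @export
aggregate_animal <- function(cycles) {
  cycles <- tibble::as_tibble(cycles)
  if (!nrow(cycles)) abort_validation("no cycles to aggregate")
  ids <- unique(cycles$animal_id)
  if (length(ids) > 1L) {
    abort_validation("cycles from multiple animals passed to aggregate_animal")
  }
  num_cols <- names(cycles)[vapply(cycles, is.numeric, logical(1))]
  means <- lapply(cycles[num_cols], function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
  out <- tibble::as_tibble(means)
  out$animal_id <- ids
  out$n_cycles <- nrow(cycles)
  out[, c("animal_id", num_cols, "n_cycles")]
}

#' Process one recording end to end
#'
#' Convenience wrapper: preprocess, pump-correct, segment and extract
#' parameters in one call.
#'
#' @inheritParams preprocess
#' @return A one-row parameter tibble.
#' @export
analyze_cycle <- function(rec, settings = cmg_settings()) {
  rec <- preprocess(rec, settings)
  rec <- correct_pump_pressure(rec, mode = settings$pump_mode,
                               offset = settings$pump_offset,
                               window_s = settings$pump_window_s)
  phases <- segment_cycle(rec, settings)
  compute_parameters(rec, phases)
}
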