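# On-disk formats: cystometry CSV, pad observation tables, study config.
#
# The CMG CSV dialect is deliberately plain: leading "# key=value" metadata
# lines, then comma-separated columns time_s, pves_mmHg, pura_mmHg, event.
# The event column is sparse text (empty when nothing happened at that
# sample), which keeps a one-file-per-cycle layout trivially diffable.

CMG_EVENT_KINDS <- c("fill_start", "fill_stop", "leak", "void_start", "void_end")
PAD_PERIODS <- c("baseline", "treatment")

#' Construct a cystometry recording
#'
#' A `cmg_recording` holds one sampled two-channel pressure trace: vesical
#' pressure (`pves`) and urethral pressure (`pura`), in mmHg, with sparse
#' event annotations and fill metadata.  This is the raw substrate of all
#' urodynamic analysis in the package.
#'
#' @param animal_id Animal identifier (text).
#' @param sample_rate Sampling rate in samples/s.
#' @param time Sample times in seconds, strictly increasing.
#' @param pves Vesical pressure per sample, mmHg.
#' @param pura Urethral pressure per sample, mmHg.
#' @param events Data frame with columns `time_s` and `kind`; `kind` is one
#'   of `fill_start`, `fill_stop`, `leak`, `void_start`, `void_end`.
#' @param fill_rate Saline infusion rate, mL/min (must be positive).
#' @param voided_volume_measured Measured voided volume, mL, or `NA`.
#' @param residual_volume_measured Measured residual volume, mL, or `NA`.
#'
#' @return An object of class `cmg_recording`.
#' @export
cmg_recording <- function(animal_id, sample_rate, time, pves, pura,
                          events = NULL, fill_rate = 2,
                          voided_volume_measured = NA_real_,
                          residual_volume_measured = NA_real_) {
  if (is.null(events)) {
    events <- tibble::tibble(time_s = numeric(), kind = character())
  }
  events <- tibble::as_tibble(events)
  rec <- structure(
    list(
      animal_id = as.character(animal_id),
      sample_rate = as.numeric(sample_rate),
      time = as.numeric(time),
      pves = as.numeric(pves),
      pura = as.numeric(pura),
      events = events,
      fill_rate = as.numeric(fill_rate),
      voided_volume_measured = as.numeric(voided_volume_measured),
      residual_volume_measured = as.numeric(residual_volume_measured)
    ),
    class = "cmg_recording"
  )
  validate_cmg_recording(rec)
}

#' Validate a cystometry recording
#'
#' Checks the structural invariants of a [cmg_recording()]: strictly
#' increasing time, equal-length channels, event times inside the trace,
#' known event kinds, positive fill rate, and at most one `fill_start`
#' preceding any `fill_stop`.
#'
#' @param rec A `cmg_recording`.
#' @return `rec`, invisibly unchanged, if valid; otherwise a validation
#'   error is raised.
#' @export
validate_cmg_recording <- function(rec) {
  n <- length(rec$time)
  if (n < 2L) abort_validation("recording must contain at least 2 samples")
  if (any(diff(rec$time) <= 0)) {
    abort_validation("time must be strictly increasing")
  }
  if (length(rec$pves) != n || length(rec$pura) != n) {
    abort_validation("pves and pura must have the same length as time")
  }
  if (!all(c("time_s", "kind") %in% names(rec$events))) {
    abort_validation("events must have columns time_s and kind")
  }
  bad_kind <- setdiff(rec$events$kind, CMG_EVENT_KINDS)
  if (length(bad_kind)) {
    abort_validation(paste0("unknown event kind(s): ",
                            paste(bad_kind, collapse = ", ")))
  }
  if (nrow(rec$events)) {
    out_of_range <- rec$events$time_s < rec$time[1L] |
      rec$events$time_s > rec$time[n]
    if (any(out_of_range)) {
      abort_validation("event times must lie within the recorded time span")
    }
  }
  if (!is_scalar_number(rec$fill_rate) || rec$fill_rate <= 0) {
    abort_validation("fill_rate must be a positive number")
  }
  fs <- rec$events$time_s[rec$events$kind == "fill_start"]
  fe <- rec$events$time_s[rec$events$kind == "fill_stop"]
  if (length(fs) > 1L) abort_validation("at most one fill_start event allowed")
  if (length(fs) == 1L && length(fe) >= 1L && any(fe <= fs)) {
    abort_validation("fill_start must precede fill_stop")
  }
  invisible(rec)
}

#' @export
print.cmg_recording <- function(x, ...) {
  cat(sprintf("<cmg_recording> animal %s: %d samples @ %g Hz (%.1f s), %d events, fill %g mL/min\n",
              x$animal_id, length(x$time), x$sample_rate,
              x$time[length(x$time)] - x$time[1L], nrow(x$events), x$fill_rate))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.6g", x)

#' Write a cystometry recording to CSV
#'
#' Serializes a [cmg_recording()] to the package's CMG CSV dialect:
#' `# key=value` metadata lines followed by columns
#' `time_s,pves_mmHg,pura_mmHg,event`.  Event annotations are written into
#' the sparse `event` column at the nearest sample; numbers are stored at
#' 6 significant digits, which round-trips losslessly for traces sampled on
#' a regular grid.
#'
#' @param rec A valid `cmg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cmg_csv <- function(rec, path) {
  validate_cmg_recording(rec)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort_io(sprintf("directory does not exist: %s", dirname(path)))
  header <- c(
    sprintf("# animal_id=%s", rec$animal_id),
    sprintf("# sample_rate_hz=%s", fmt_num(rec$sample_rate)),
    sprintf("# fill_rate_mL_min=%s", fmt_num(rec$fill_rate))
  )
  if (!is.na(rec$voided_volume_measured)) {
    header <- c(header, sprintf("# voided_volume_mL=%s",
                                fmt_num(rec$voided_volume_measured)))
  }
  if (!is.na(rec$residual_volume_measured)) {
    header <- c(header, sprintf("# residual_volume_mL=%s",
                                fmt_num(rec$residual_volume_measured)))
  }
  event_col <- character(length(rec$time))
  if (nrow(rec$events)) {
    for (i in seq_len(nrow(rec$events))) {
      j <- which.min(abs(rec$time - rec$events$time_s[i]))
      event_col[j] <- if (nzchar(event_col[j])) {
        paste(event_col[j], rec$events$kind[i], sep = ";")
      } else {
        rec$events$kind[i]
      }
    }
  }
  body <- paste(fmt_num(rec$time), fmt_num(rec$pves), fmt_num(rec$pura),
                event_col, sep = ",")
  con <- tryCatch(file(path, "w"), error = function(e) abort_io(conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, "time_s,pves_mmHg,pura_mmHg,event", body), con)
  invisible(path)
}

#' Read a cystometry recording from CSV
#'
#' Parses the CMG CSV dialect written by [write_cmg_csv()] and returns a
#' validated [cmg_recording()].  Missing required columns raise a format
#' error naming the column; rows whose numeric fields do not parse are
#' reported with their line numbers; non-monotone time raises a validation
#' error.
#'
#' @param path Path to a CMG CSV file.
#' @return A `cmg_recording`.
#' @export
read_cmg_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (!length(body)) abort_format("no data rows found")
  df <- read.csv(text = paste(body, collapse = "\n"),
                 colClasses = "character", check.names = FALSE)
  required <- c("time_s", "pves_mmHg", "pura_mmHg")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col)) {
    abort_format(paste0("missing required column(s): ",
                        paste(missing_col, collapse = ", ")))
  }
  if (!"event" %in% names(df)) df$event <- ""
  num <- lapply(df[required], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(seq_along(required), function(k) {
    is.na(num[[k]]) & nzchar(trimws(df[[required[k]]]))
  })))
  if (length(bad)) {
    file_lines <- length(meta_idx) + 1L + bad  # header line offset
    abort_format(paste0("unparseable numeric value(s) at line(s): ",
                        paste(file_lines, collapse = ", ")))
  }
  time <- num$time_s
  if (any(is.na(time))) abort_format("missing time values")
  if (any(diff(time) <= 0)) abort_validation("time must be strictly increasing")

  ev <- df$event
  has_ev <- which(nzchar(ev))
  events <- if (length(has_ev)) {
    kinds <- strsplit(ev[has_ev], ";", fixed = TRUE)
    tibble::tibble(
      time_s = rep(time[has_ev], lengths(kinds)),
      kind = unlist(kinds)
    )
  } else {
    tibble::tibble(time_s = numeric(), kind = character())
  }

  get_meta_num <- function(key, default = NA_real_) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  }
  sample_rate <- get_meta_num("sample_rate_hz")
  if (is.na(sample_rate)) sample_rate <- 1 / median(diff(time))

  cmg_recording(
    animal_id = meta[["animal_id"]] %||% "unknown",
    sample_rate = sample_rate,
    time = time, pves = num$pves_mmHg, pura = num$pura_mmHg,
    events = events,
    fill_rate = get_meta_num("fill_rate_mL_min", 2),
    voided_volume_measured = get_meta_num("voided_volume_mL"),
    residual_volume_measured = get_meta_num("residual_volume_mL")
  )
}

#' Read a pad observation table
#'
#' Reads a CSV with one row per pad-day: columns `animal_id`, `obs_date`,
#' `period` (`baseline` or `treatment`), optional `image_path`,
#' `pad_mass_dry_g`, `pad_mass_wet_g`, `water_intake_mL`,
#' `calibration_mm_per_px`.  Records violating the mass/positivity
#' invariants raise a validation error with the offending row index.
#'
#' @param path CSV file path.
#' @return A tibble of validated pad records.
#' @export
read_pad_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  required <- c("animal_id", "obs_date", "period", "pad_mass_dry_g",
                "pad_mass_wet_g", "water_intake_mL", "calibration_mm_per_px")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col)) {
    abort_format(paste0("missing required column(s): ",
                        paste(missing_col, collapse = ", ")))
  }
  if (!"image_path" %in% names(df)) df$image_path <- NA_character_
  validate_pad_table(df)
}

#' Validate a pad observation table
#'
#' @param df Data frame of pad records.
#' @return The validated tibble.
#' @export
validate_pad_table <- function(df) {
  df <- tibble::as_tibble(df)
  bad_period <- which(!df$period %in% PAD_PERIODS)
  if (length(bad_period)) {
    abort_validation(sprintf(
      "row %d: period must be one of {%s}, got '%s'",
      bad_period[1L], paste(PAD_PERIODS, collapse = ", "),
      df$period[bad_period[1L]]))
  }
  bad_mass <- which(df$pad_mass_wet_g < df$pad_mass_dry_g |
                      df$pad_mass_dry_g < 0)
  if (length(bad_mass)) {
    abort_validation(sprintf(
      "row %d: pad_mass_wet_g must be >= pad_mass_dry_g >= 0", bad_mass[1L]))
  }
  if (any(df$water_intake_mL < 0)) {
    abort_validation(sprintf("row %d: water_intake_mL must be >= 0",
                             which(df$water_intake_mL < 0)[1L]))
  }
  if (any(df$calibration_mm_per_px <= 0)) {
    abort_validation(sprintf("row %d: calibration_mm_per_px must be > 0",
                             which(df$calibration_mm_per_px <= 0)[1L]))
  }
  df$obs_date <- as.Date(df$obs_date)
  df
}

#' Write a pad observation table
#'
#' @param df Pad record tibble (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pad_table <- function(df, path) {
  df <- validate_pad_table(df)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Voiding-spot-assay thresholds
#'
#' Geometric and intensity thresholds driving spot detection and
#' classification.  The 30-mm default leak/void boundary implements the
#' "< 3 cm diameter" leak criterion; the splatter exclusion distance encodes
#' "away from an active void" (no published distance, same 30-mm scale by
#' default).
#'
#' @param leak_max_diameter Maximum equivalent diameter of a leak spot, mm.
#' @param void_min_diameter Minimum equivalent diameter of a void, mm.
#' @param splatter_exclusion_distance Minimum edge-to-edge distance from a
#'   void for a small spot to count as a leak rather than splatter, mm.
#' @param min_spot_area Smallest connected component kept, mm^2.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold in `[0, 1]` when
#'   `threshold_method = "fixed"`.
#' @param min_contrast Minimum separation of the foreground and background
#'   class mean intensities for Otsu's split to be accepted; guards against
#'   carving phantom spots out of sensor noise on stain-free pads.
#' @param invert Set `TRUE` when wet regions are darker than background.
#' @return A `vsa_thresholds` list.
#' @export
vsa_thresholds <- function(leak_max_diameter = 30,
                           void_min_diameter = 30,
                           splatter_exclusion_distance = 30,
                           min_spot_area = 10,
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL,
                           min_contrast = 0.1,
                           invert = FALSE) {
  threshold_method <- match.arg(threshold_method)
  thr <- structure(list(
    leak_max_diameter = leak_max_diameter,
    void_min_diameter = void_min_diameter,
    splatter_exclusion_distance = splatter_exclusion_distance,
    min_spot_area = min_spot_area,
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    min_contrast = min_contrast,
    invert = isTRUE(invert)
  ), class = "vsa_thresholds")
  validate_vsa_thresholds(thr)
}

validate_vsa_thresholds <- function(thr) {
  vals <- c(thr$leak_max_diameter, thr$void_min_diameter,
            thr$splatter_exclusion_distance, thr$min_spot_area)
  if (!all(vapply(vals, is_scalar_number, logical(1))) || any(vals <= 0)) {
    abort_config("all VSA thresholds must be positive numbers")
  }
  if (thr$leak_max_diameter > thr$void_min_diameter) {
    abort_config("leak_max_diameter must not exceed void_min_diameter")
  }
  thr
}

#' Cystometry processing settings
#'
#' @param baseline_s Length of the pre-fill baseline window, s.
#' @param butter_order Order of the low-pass Butterworth filter.
#' @param cutoff_hz Filter cutoff, Hz.
#' @param detrend Remove the best-fit linear drift (slope only, mean level
#'   preserved) before filtering.
#' @param pump_mode Syringe-pump correction mode: `"step_estimate"`
#'   (estimate the pressure step across fill start from the trace) or
#'   `"constant"` (subtract a supplied offset).
#' @param pump_offset Offset in mmHg for `pump_mode = "constant"`.
#' @param pump_window_s Window on each side of fill start used by the step
#'   estimator, s.
#' @param leak_detector Enable the urethral-pressure transient leak detector
#'   used when no leak annotation is present (off by default; leaks in the
#'   study were annotated from direct observation).
#' @param leak_k Detection threshold in robust SDs of the baseline urethral
#'   pressure residual.
#' @param leak_detector_cutoff_hz Cutoff of the low-pass whose residual the
#'   detector thresholds, Hz.
#' @return A `cmg_settings` list.
#' @export
cmg_settings <- function(baseline_s = 30, butter_order = 4, cutoff_hz = 5,
                         detrend = TRUE,
                         pump_mode = c("step_estimate", "constant"),
                         pump_offset = NULL, pump_window_s = 5,
                         leak_detector = FALSE, leak_k = 5,
                         leak_detector_cutoff_hz = 0.5) {
  pump_mode <- match.arg(pump_mode)
  if (baseline_s <= 0 || butter_order < 1 || cutoff_hz <= 0) {
    abort_config("baseline_s, butter_order and cutoff_hz must be positive")
  }
  structure(list(
    baseline_s = baseline_s, butter_order = butter_order,
    cutoff_hz = cutoff_hz, detrend = isTRUE(detrend),
    pump_mode = pump_mode, pump_offset = pump_offset,
    pump_window_s = pump_window_s,
    leak_detector = isTRUE(leak_detector), leak_k = leak_k,
    leak_detector_cutoff_hz = leak_detector_cutoff_hz
  ), class = "cmg_settings")
}

#' Default study configuration
#'
#' Encodes the study design: a young nulliparous control group (n = 5) and
#' two mature multiparous groups (sham n = 8, stimulated n = 8), observed
#' 3 days/week over a 2-week baseline and a 4-week treatment period, plus
#' the VSA thresholds, CMG processing settings, statistics settings and RNG
#' seed.
#'
#' @param seed Integer RNG seed stored with the config.
#' @return A `study_config` list.
#' @export
default_study_config <- function(seed = 1L) {
  structure(list(
    groups = list(
      list(name = "YN", n_animals = 5L, implant_active = FALSE),
      list(name = "MM-sham", n_animals = 8L, implant_active = FALSE),
      list(name = "MM-ES", n_animals = 8L, implant_active = TRUE)
    ),
    baseline_weeks = 2L,
    treatment_weeks = 4L,
    observations_per_week = 3L,
    vsa = vsa_thresholds(),
    cmg = cmg_settings(),
    stats = list(alpha = 0.05, rout_q = 1),
    seed = as.integer(seed)
  ), class = "study_config")
}

validate_study_config <- function(cfg) {
  if (!length(cfg$groups)) abort_config("config must define at least one group")
  for (g in cfg$groups) {
    if (!is.character(g$name) || g$n_animals < 1) {
      abort_config("each group needs a name and a positive n_animals")
    }
  }
  counts <- c(cfg$baseline_weeks, cfg$treatment_weeks, cfg$observations_per_week)
  if (any(counts < 1)) abort_config("weeks and observation counts must be positive")
  validate_vsa_thresholds(cfg$vsa)
  cfg
}

#' Read a study configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- default_study_config()
  for (key in c("baseline_weeks", "treatment_weeks", "observations_per_week",
                "seed")) {
    if (!is.null(raw[[key]])) cfg[[key]] <- as.integer(raw[[key]])
  }
  if (!is.null(raw$groups)) {
    cfg$groups <- lapply(raw$groups, function(g) {
      list(name = g$name, n_animals = as.integer(g$n_animals),
           implant_active = isTRUE(g$implant_active))
    })
  }
  if (!is.null(raw$vsa)) cfg$vsa <- do.call(vsa_thresholds, raw$vsa)
  if (!is.null(raw$cmg)) cfg$cmg <- do.call(cmg_settings, raw$cmg)
  if (!is.null(raw$stats)) cfg$stats <- utils::modifyList(cfg$stats, raw$stats)
  validate_study_config(cfg)
}

#' Write a study configuration to YAML
#'
#' @param cfg A `study_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(cfg, path) {
  validate_study_config(cfg)
  out <- list(
    groups = cfg$groups,
    baseline_weeks = cfg$baseline_weeks,
    treatment_weeks = cfg$treatment_weeks,
    observations_per_week = cfg$observations_per_week,
    vsa = cfg$vsa[!vapply(cfg$vsa, is.null, logical(1))],
    cmg = cfg$cmg[!vapply(cfg$cmg, is.null, logical(1))],
    stats = cfg$stats,
    seed = cfg$seed
  )
  out$vsa <- unclass(out$vsa)
  out$cmg <- unclass(out$cmg)
  yaml::write_yaml(out, path)
  invisible(path)
}
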