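# Per-animal, per-period micturition metrics and baseline-vs-treatment
# change scores.
#
# Leak frequency is the percentage of observation days with at least one
# leak ("leaked X% of the time" under a 3-days/week sampling scheme).  The
# per-day leak event count is aggregated separately (mean_leaks_per_day) and
# never mixed into the frequency.

MICTURITION_METRICS <- c(
  "leak_day_frequency", "mean_daily_mass_g", "mean_mass_per_void_g",
  "mean_voids_per_day", "mean_water_intake_mL", "mean_leaks_per_day"
)

#' Summarize one animal-period of daily observations
#'
#' @param obs Daily-observation tibble for a single animal and period
#'   (columns as produced by [summarize_pad()] or [gen_study()]).
#' @return A one-row period-summary tibble: `n_obs_days`,
#'   `leak_day_frequency` (percent of days with >= 1 leak),
#'   `mean_daily_mass_g`, `mean_mass_per_void_g` (over days where defined),
#'   `mean_voids_per_day`, `mean_water_intake_mL`, `mean_leaks_per_day`.
#' @export
summarize_period <- function(obs) {
  obs <- tibble::as_tibble(obs)
  if (!nrow(obs)) abort_validation("no observations to summarize")
  if (length(unique(obs$animal_id)) > 1L) {
    abort_validation("observations from multiple animals passed to summarize_period")
  }
  if (length(unique(obs$period)) > 1L) {
    abort_validation("observations from multiple periods passed to summarize_period")
  }
  mpv <- obs$mass_per_void_g[!is.na(obs$mass_per_void_g)]
  out <- tibble::tibble(
    animal_id = obs$animal_id[1L],
    period = obs$period[1L],
    n_obs_days = nrow(obs),
    leak_day_frequency = 100 * mean(obs$n_leaks >= 1L),
    mean_daily_mass_g = mean(obs$daily_micturition_mass_g),
    mean_mass_per_void_g = if (length(mpv)) mean(mpv) else NA_real_,
    mean_voids_per_day = mean(obs$n_voids),
    mean_water_intake_mL = mean(obs$water_intake_mL),
    mean_leaks_per_day = mean(obs$n_leaks)
  )
  if ("group" %in% names(obs)) {
    out <- tibble::add_column(out, group = obs$group[1L], .after = "animal_id")
  }
  out
}

#' Summarize every animal-period in a daily observation table
#'
#' @param obs Daily-observation tibble for any number of animals/periods.
#' @return A period-summary tibble with one row per animal x period.
#' @export
summarize_periods <- function(obs) {
  obs <- tibble::as_tibble(obs)
  dplyr::bind_rows(lapply(
    split(obs, list(obs$animal_id, obs$period), drop = TRUE),
    summarize_period
  ))
}

#' Baseline-vs-treatment change scores for one animal
#'
#' For each micturition metric, computes `absolute_change = treatment -
#' baseline` and `percent_change = 100 * (treatment - baseline) /
#' baseline` (absent where baseline is zero).  The leak-frequency change is
#' in percentage points in the `absolute_change` column, which is how a
#' "reduction in leak frequency" is reported.
#'
#' @param base,treat One-row period summaries for the same animal,
#'   `base$period == "baseline"` and `treat$period == "treatment"`.
#' @return A tibble with one row per metric: `animal_id`, `metric`,
#'   `baseline`, `treatment`, `absolute_change`, `percent_change`.
#' @export
change_scores <- function(base, treat) {
  base <- tibble::as_tibble(base)
  treat <- tibble::as_tibble(treat)
  if (nrow(base) != 1L || nrow(treat) != 1L) {
    abort_validation("base and treat must each be a single period summary")
  }
  if (base$animal_id != treat$animal_id) {
    abort_validation("base and treat must be the same animal")
  }
  if (base$period != "baseline" || treat$period != "treatment") {
    abort_validation("base must be a baseline summary and treat a treatment summary")
  }
  b <- unlist(base[MICTURITION_METRICS])
  t <- unlist(treat[MICTURITION_METRICS])
  abs_change <- t - b
  pct_change <- ifelse(!is.na(b) & b != 0, 100 * (t - b) / b, NA_real_)
  tibble::tibble(
    animal_id = base$animal_id,
    metric = MICTURITION_METRICS,
    baseline = as.numeric(b),
    treatment = as.numeric(t),
    absolute_change = as.numeric(abs_change),
    percent_change = as.numeric(pct_change)
  )
}

#' Change scores for every animal in a summary table
#'
#' Pairs each animal's baseline and treatment summaries and applies
#' [change_scores()].  Animals lacking either period are skipped.
#'
#' @param summaries Period-summary tibble ([summarize_periods()] output).
#' @return A long tibble of change scores (possibly empty).
#' @export
period_changes <- function(summaries) {
  summaries <- tibble::as_tibble(summaries)
  out <- list()
  for (id in unique(summaries$animal_id)) {
    base <- summaries[summaries$animal_id == id &
                        summaries$period == "baseline", ]
    treat <- summaries[summaries$animal_id == id &
                         summaries$period == "treatment", ]
    if (nrow(base) == 1L && nrow(treat) == 1L) {
      cs <- change_scores(base, treat)
      if ("group" %in% names(summaries)) cs$group <- base$group
      out[[id]] <- cs
    }
  }
  dplyr::bind_rows(out)
}

#' Group-level summary table
#'
#' Per group x period x metric: n, mean, SD and SEM (`SD / sqrt(n)`; absent
#' for n = 1).  Groups are taken from a `group` column when present,
#' otherwise inferred from the `"<group>-<number>"` animal-id convention,
#' and validated against the study design.
#'
#' @param summaries Period-summary tibble.
#' @param design A `study_config` (see [default_study_config()]).
#' @return A long tibble: `group`, `period`, `metric`, `n`, `mean`, `sd`,
#'   `sem`.
#' @export
group_table <- function(summaries, design = default_study_config()) {
  summaries <- tibble::as_tibble(summaries)
  if (!"group" %in% names(summaries)) {
    summaries$group <- sub("-[0-9]+$", "", summaries$animal_id)
  }
  known <- vapply(design$groups, `[[`, character(1), "name")
  bad <- setdiff(unique(summaries$group), known)
  if (length(bad)) {
    abort_validation(paste0("group(s) not in design: ",
                            paste(bad, collapse = ", ")))
  }
  long <- tidyr_pivot(summaries)
  dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$period, .data$metric),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    sem = .data$sd / sqrt(.data$n),
    .groups = "drop"
  )
}

# long format without a tidyr dependency
tidyr_pivot <- function(summaries) {
  metrics <- intersect(MICTURITION_METRICS, names(summaries))
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(
      group = summaries$group, period = summaries$period,
      animal_id = summaries$animal_id, metric = m,
      value = summaries[[m]]
    )
  }))
}
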