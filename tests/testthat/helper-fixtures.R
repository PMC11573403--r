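# Fixtures built in code: a tiny hand-constructed cystometry recording and
# a period-summary builder used across test files.

# Flat 2 mmHg baseline for 30 s, then a fill ramp with a +3 mmHg pump step;
# small enough to inspect by eye.
make_flat_recording <- function(fs = 20, baseline = 2, offset = 3,
                                slope_per_s = 0.01, t_fill = 30,
                                t_end = 90, events = NULL) {
  time <- seq(0, t_end, by = 1 / fs)
  pves <- rep(baseline, length(time))
  in_fill <- time >= t_fill
  pves[in_fill] <- baseline + offset + slope_per_s * (time[in_fill] - t_fill)
  if (is.null(events)) {
    events <- tibble::tibble(time_s = t_fill, kind = "fill_start")
  }
  cmg_recording(
    animal_id = "TEST-1", sample_rate = fs, time = time,
    pves = pves, pura = rep(8, length(time)), events = events,
    fill_rate = 2
  )
}

make_period_summary <- function(animal_id, period,
                                leak_day_frequency = 50,
                                mean_daily_mass_g = 60,
                                mean_mass_per_void_g = 25,
                                mean_voids_per_day = 2.5,
                                mean_water_intake_mL = 180,
                                mean_leaks_per_day = 1,
                                n_obs_days = 6) {
  tibble::tibble(
    animal_id = animal_id, period = period, n_obs_days = n_obs_days,
    leak_day_frequency = leak_day_frequency,
    mean_daily_mass_g = mean_daily_mass_g,
    mean_mass_per_void_g = mean_mass_per_void_g,
    mean_voids_per_day = mean_voids_per_day,
    mean_water_intake_mL = mean_water_intake_mL,
    mean_leaks_per_day = mean_leaks_per_day
  )
}

make_daily_obs <- function(animal_id = "A-1", period = "baseline",
                           n_leaks_by_day, mass = 60, voids = 2,
                           water = 180) {
  n <- length(n_leaks_by_day)
  tibble::tibble(
    animal_id = animal_id,
    obs_date = as.Date("2024-01-01") + seq_len(n),
    period = period,
    n_voids = rep_len(voids, n),
    n_leaks = n_leaks_by_day,
    daily_micturition_mass_g = rep_len(mass, n),
    mass_per_void_g = rep_len(mass, n) / rep_len(voids, n),
    water_intake_mL = rep_len(water, n)
  )
}
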