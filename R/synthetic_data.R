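# Synthetic data with known ground truth: cystometry cycles, pad images,
# and whole multi-animal studies.  Every generator is deterministic given a
# seed and returns the analytic truth alongside the data so that pipeline
# recovery can be asserted exactly.

#' Ground truth for one synthetic cystometry cycle
#'
#' Defaults are set at the scale of a healthy young nulliparous cycle:
#' total bladder content 43.7 mL (voided 6.9 mL + residual 36.8 mL, i.e.
#' voiding efficiency 15.8%), leak at 38.2 mL, compliance slope chosen so
#' the maximum normalized storage pressure is 9.8 mmHg and the normalized
#' leak point pressure about 8.6 mmHg, 2 mL/min fill.
#'
#' @param baseline_pves Resting vesical pressure, mmHg.
#' @param pump_offset Syringe-pump pressure step during filling, mmHg.
#' @param compliance_slope Pressure rise per unit infused volume, mmHg/mL.
#' @param fill_rate Infusion rate, mL/min.
#' @param leak_volume Infused volume at the leak, mL, or `NULL` for a
#'   leak-free cycle.
#' @param void_volume Infused volume at void onset (total bladder
#'   content), mL.
#' @param voided_fraction Fraction of bladder content expelled (voiding
#'   efficiency / 100).
#' @param contraction_amplitude Peak of the voiding contraction, mmHg.
#' @param pura_baseline Resting urethral pressure, mmHg.
#' @param leak_pura_drop Depth of the urethral-pressure transient at the
#'   leak, mmHg.
#' @param noise_sd Gaussian sensor noise SD on both channels, mmHg.
#' @param seed RNG seed (or `NULL`).
#' @return A `cmg_truth` list.
#' @export
cmg_truth <- function(baseline_pves = 2, pump_offset = 3,
                      compliance_slope = 9.8 / 43.7, fill_rate = 2,
                      leak_volume = 38.2, void_volume = 43.7,
                      voided_fraction = 0.158,
                      contraction_amplitude = 8,
                      pura_baseline = 8, leak_pura_drop = 6,
                      noise_sd = 0.3, seed = NULL) {
  if (!is.null(leak_volume) && leak_volume >= void_volume) {
    abort_config("leak_volume must be smaller than void_volume")
  }
  if (voided_fraction < 0 || voided_fraction > 1) {
    abort_config("voided_fraction must lie in [0, 1]")
  }
  structure(list(
    baseline_pves = baseline_pves, pump_offset = pump_offset,
    compliance_slope = compliance_slope, fill_rate = fill_rate,
    leak_volume = leak_volume, void_volume = void_volume,
    voided_fraction = voided_fraction,
    contraction_amplitude = contraction_amplitude,
    pura_baseline = pura_baseline, leak_pura_drop = leak_pura_drop,
    noise_sd = noise_sd, seed = seed
  ), class = "cmg_truth")
}

#' Generate a synthetic cystometry cycle
#'
#' Builds one fill-to-void cycle: a 30-s pre-fill baseline at
#' `baseline_pves`; constant-rate filling during which
#' `pves = baseline + pump_offset + compliance_slope * V(t)` (+ Gaussian
#' noise); an annotated leak (with a sharp urethral-pressure dip) when the
#' infused volume reaches `leak_volume`; and at `void_volume` a voiding
#' contraction (half-sine peak of the stated amplitude) with exponential
#' release of the stored elastic pressure.  The pump stops at void onset.
#' Measured voided/residual volumes are set to
#' `voided_fraction * infused` and its complement.
#'
#' @param truth A [cmg_truth()] parameter set.
#' @param animal_id Identifier stored in the recording.
#' @param sample_rate Sampling rate, samples/s.
#' @param baseline_s Pre-fill baseline duration, s.
#' @return A list: `recording` (a [cmg_recording()]), `phases` (the true
#'   [segment_cycle()] output), `parameters` (the analytic
#'   [compute_parameters()] row).
#' @export
gen_cmg <- function(truth = cmg_truth(), animal_id = "SYN-1",
                    sample_rate = 100, baseline_s = 30) {
  with_seed_if(truth$seed, {
    fs <- sample_rate
    t_fill <- baseline_s
    fill_s <- truth$void_volume / truth$fill_rate * 60
    t_void <- t_fill + fill_s
    t_end <- t_void + 30
    time <- seq(0, t_end, by = 1 / fs)
    # snap landmark times onto the sample grid for lossless serialization
    snap <- function(tt) time[which.min(abs(time - tt))]
    t_void <- snap(t_void)

    V <- pmax(0, pmin(time - t_fill, t_void - t_fill)) * truth$fill_rate / 60
    in_fill <- time >= t_fill & time < t_void
    post <- time >= t_void

    pves <- rep(truth$baseline_pves, length(time))
    pves[in_fill] <- truth$baseline_pves + truth$pump_offset +
      truth$compliance_slope * V[in_fill]
    stored <- truth$compliance_slope * truth$void_volume
    tau_release <- 5
    contraction <- ifelse(
      post & time <= t_void + 10,
      truth$contraction_amplitude * sin(pi * (time - t_void) / 10), 0)
    # pump pressure bleeds off through the open urethra rather than
    # vanishing instantly, keeping the trace continuous at void onset
    tau_pump <- 1
    pves[post] <- truth$baseline_pves +
      stored * exp(-(time[post] - t_void) / tau_release) +
      truth$pump_offset * exp(-(time[post] - t_void) / tau_pump) +
      contraction[post]

    pura <- rep(truth$pura_baseline, length(time))

    events <- tibble::tibble(
      time_s = c(t_fill, t_void, t_void, snap(t_void + 15)),
      kind = c("fill_start", "fill_stop", "void_start", "void_end")
    )
    leak_time <- NA_real_
    if (!is.null(truth$leak_volume)) {
      leak_time <- snap(t_fill + truth$leak_volume / truth$fill_rate * 60)
      events <- dplyr::bind_rows(
        events, tibble::tibble(time_s = leak_time, kind = "leak"))
      pura <- pura - truth$leak_pura_drop *
        exp(-((time - leak_time) / 0.3)^2)
    }

    if (truth$noise_sd > 0) {
      pves <- pves + rnorm(length(time), 0, truth$noise_sd)
      pura <- pura + rnorm(length(time), 0, truth$noise_sd)
    }

    infused <- truth$void_volume
    voided <- truth$voided_fraction * infused
    residual <- infused - voided

    rec <- cmg_recording(
      animal_id = animal_id, sample_rate = fs, time = time,
      pves = pves, pura = pura, events = events,
      fill_rate = truth$fill_rate,
      voided_volume_measured = voided,
      residual_volume_measured = residual
    )

    phases <- structure(list(
      baseline_window = c(t_fill - baseline_s, t_fill),
      fill_start = t_fill,
      storage_window = c(t_fill, t_void),
      leak_time = leak_time,
      void_onset = t_void
    ), class = "cycle_phases")

    parameters <- tibble::tibble(
      animal_id = animal_id,
      avg_baseline_pves = truth$baseline_pves,
      avg_storage_pves = truth$baseline_pves + stored / 2,
      avg_storage_pves_norm = stored / 2,
      max_storage_pves = truth$baseline_pves + stored,
      max_storage_pves_norm = stored,
      leak_point_pves_norm = if (is.na(leak_time)) NA_real_ else
        truth$compliance_slope * truth$leak_volume,
      leak_point_volume = if (is.na(leak_time)) NA_real_ else
        truth$leak_volume,
      infused_volume = infused,
      voided_volume = voided,
      residual_volume = residual,
      voiding_efficiency = 100 * truth$voided_fraction
    )

    list(recording = rec, phases = phases, parameters = parameters)
  })
}

#' Geometry settings for synthetic pad images
#'
#' @param canvas_mm Pad size `(width, height)` in mm.
#' @param calibration mm per pixel.
#' @param void_diameter_range Diameter range for rendered voids, mm.
#' @param leak_diameter_range Diameter range for rendered leaks, mm
#'   (kept below the 30-mm leak criterion).
#' @param min_edge_separation Minimum pairwise edge-to-edge spot
#'   separation, mm (default twice the splatter exclusion distance so that
#'   classification margins are respected by construction).
#' @param margin Margin kept free along the pad borders, mm.
#' @param background,foreground Background and stain intensities in
#'   `[0, 1]`.
#' @param image_noise_sd Gaussian pixel noise SD.
#' @param areal_density Absorbed mass per stained area, g/mm^2.
#' @param dry_mass Dry pad mass, g.
#' @return A `pad_geometry` list.
#' @export
pad_geometry <- function(canvas_mm = c(600, 600), calibration = 1,
                         void_diameter_range = c(60, 100),
                         leak_diameter_range = c(12, 28),
                         min_edge_separation = 60, margin = 10,
                         background = 0.12, foreground = 0.85,
                         image_noise_sd = 0.02,
                         areal_density = 0.006, dry_mass = 40) {
  structure(as.list(environment()), class = "pad_geometry")
}

#' Generate a synthetic pad image with known spots
#'
#' Renders the requested number of void and leak stains as filled disks on
#' a noisy background, enforcing the configured minimum edge separation
#' between all spots (so detection plus classification recovers the truth
#' exactly), and sets the wet pad mass consistently with the total stained
#' area.
#'
#' @param n_voids,n_leaks Number of void / leak stains to place.
#' @param geometry A [pad_geometry()] list.
#' @param seed RNG seed (or `NULL`).
#' @param animal_id,obs_date,period,water_intake Pad-record metadata.
#' @param max_tries Placement attempts per spot before giving up.
#' @return A list: `image` (intensity matrix), `pad` (one-row pad-record
#'   tibble), `truth` (tibble of true spots with labels).
#' @export
gen_pad_image <- function(n_voids, n_leaks, geometry = pad_geometry(),
                          seed = NULL, animal_id = "SYN-1",
                          obs_date = as.Date("2024-01-01"),
                          period = "baseline", water_intake = 180,
                          max_tries = 2000L) {
  g <- geometry
  with_seed_if(seed, {
    n_total <- n_voids + n_leaks
    diams <- as.numeric(c(
      if (n_voids > 0) runif(n_voids, g$void_diameter_range[1], g$void_diameter_range[2]),
      if (n_leaks > 0) runif(n_leaks, g$leak_diameter_range[1], g$leak_diameter_range[2])
    ))
    labels <- c(rep("void", n_voids), rep("leak", n_leaks))
    # place larger spots first: easier packing
    ord <- order(-diams)
    diams <- diams[ord]; labels <- labels[ord]
    xs <- ys <- numeric(0)
    placed_d <- numeric(0)
    for (i in seq_len(n_total)) {
      r <- diams[i] / 2
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, g$margin + r, g$canvas_mm[1] - g$margin - r)
        y <- runif(1, g$margin + r, g$canvas_mm[2] - g$margin - r)
        if (length(xs)) {
          gap <- sqrt((x - xs)^2 + (y - ys)^2) - r - placed_d / 2
          if (any(gap < g$min_edge_separation)) next
        }
        xs <- c(xs, x); ys <- c(ys, y); placed_d <- c(placed_d, diams[i])
        ok <- TRUE
        break
      }
      if (!ok) {
        abort_placement(sprintf(
          "could not place spot %d of %d after %d tries; enlarge the canvas or reduce separation",
          i, n_total, max_tries))
      }
    }

    nc <- round(g$canvas_mm[1] / g$calibration)
    nr <- round(g$canvas_mm[2] / g$calibration)
    img <- matrix(g$background, nr, nc)
    for (i in seq_along(xs)) {
      r_px <- (placed_d[i] / 2) / g$calibration
      cx <- xs[i] / g$calibration + 0.5
      cy <- ys[i] / g$calibration + 0.5
      col_rng <- max(1L, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
      row_rng <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
      dx <- outer(rep(1, length(row_rng)), col_rng - cx)
      dy <- outer(row_rng - cy, rep(1, length(col_rng)))
      inside <- dx^2 + dy^2 <= r_px^2
      block <- img[row_rng, col_rng]
      block[inside] <- g$foreground
      img[row_rng, col_rng] <- block
    }
    if (g$image_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, g$image_noise_sd), nr, nc)
      img <- pmin(pmax(img, 0), 1)
    }

    truth <- tibble::tibble(
      centroid_x_mm = xs, centroid_y_mm = ys,
      diameter_mm = placed_d,
      area_mm2 = pi * (placed_d / 2)^2,
      label = labels
    )
    pad <- tibble::tibble(
      animal_id = animal_id, obs_date = obs_date, period = period,
      image_path = NA_character_,
      pad_mass_dry_g = g$dry_mass,
      pad_mass_wet_g = g$dry_mass + g$areal_density * sum(truth$area_mm2),
      water_intake_mL = water_intake,
      calibration_mm_per_px = g$calibration
    )
    list(image = img, pad = pad, truth = truth)
  })
}

#' Default group-level study truth
#'
#' Per-group, per-period generating distributions for the synthetic study.
#' Defaults are parameterized at the printed group results: the young
#' nulliparous (YN) group never leaks; mature multiparous sham animals
#' leak on half of observation days in both periods (the reported 25-75%
#' range) with no treatment effect; the stimulated group's leak-day
#' probability falls from 0.694 at baseline to 0.294 during treatment, its
#' daily micturition mass rises from 54.5 g to 87.6 g, with voiding
#' frequency and water intake unchanged.  Between-animal SDs are the
#' printed SEMs times `sqrt(n)`.  Treatment-period truth differs from
#' baseline only for groups with an active implant.
#'
#' @return A `study_truth` list keyed by group name; each entry holds
#'   `leak_day_probability`, `daily_mass_mean`, `daily_mass_sd`,
#'   `voids_per_day_mean`, `water_mean`, `water_sd` -- each a
#'   `(baseline, treatment)` pair -- plus `extra_leaks_mean` (mean extra
#'   leak events beyond the first on a leak day).
#' @export
default_study_truth <- function() {
  per <- function(b, t = b) c(baseline = b, treatment = t)
  structure(list(
    "YN" = list(
      leak_day_probability = per(0),
      daily_mass_mean = per(60), daily_mass_sd = per(15),
      voids_per_day_mean = per(2.5),
      water_mean = per(180), water_sd = per(40),
      extra_leaks_mean = 0.5
    ),
    "MM-sham" = list(
      leak_day_probability = per(0.5),
      daily_mass_mean = per(93.8), daily_mass_sd = per(17.7 * sqrt(8)),
      voids_per_day_mean = per(2.8),
      water_mean = per(222.9), water_sd = per(33.8 * sqrt(8)),
      extra_leaks_mean = 0.5
    ),
    "MM-ES" = list(
      leak_day_probability = per(0.694, 0.294),
      daily_mass_mean = per(54.5, 87.6),
      daily_mass_sd = per(7.5 * sqrt(8), 8.3 * sqrt(8)),
      voids_per_day_mean = per(2.6),
      water_mean = per(160.8, 177.4),
      water_sd = per(16.3 * sqrt(8), 23.7 * sqrt(8)),
      extra_leaks_mean = 0.5
    )
  ), class = "study_truth")
}

#' Generate a synthetic multi-animal study
#'
#' Draws per-animal, per-observation-day micturition data under the study
#' design: leak days are Bernoulli with the group x period leak-day
#' probability (leak-day event counts are 1 plus a Poisson excess), daily
#' micturition mass and water intake are truncated normal, and daily voids
#' are shifted Poisson (minimum 1).  Treatment-period distributions differ
#' from baseline only for groups flagged `implant_active` in the design
#' (the truth constructor already enforces this for the defaults).
#'
#' @param truth A [default_study_truth()]-style list.
#' @param design A `study_config` ([default_study_config()]).
#' @param seed RNG seed (or `NULL`).
#' @return A daily-observation tibble with columns `group`, `animal_id`,
#'   `obs_date`, `period`, `n_voids`, `n_leaks`,
#'   `daily_micturition_mass_g`, `mass_per_void_g`, `water_intake_mL`.
#' @export
gen_study <- function(truth = default_study_truth(),
                      design = default_study_config(), seed = NULL) {
  validate_study_config(design)
  with_seed_if(seed, {
    rows <- list()
    day0 <- as.Date("2024-01-01")
    obs_per_week <- design$observations_per_week
    n_base <- design$baseline_weeks * obs_per_week
    n_treat <- design$treatment_weeks * obs_per_week
    for (grp in design$groups) {
      tr <- truth[[grp$name]]
      if (is.null(tr)) {
        abort_config(sprintf("no truth defined for group '%s'", grp$name))
      }
      if (!grp$implant_active) {
        # no-effect gate: inactive implants cannot produce a treatment effect
        for (f in c("leak_day_probability", "daily_mass_mean", "daily_mass_sd",
                    "voids_per_day_mean", "water_mean", "water_sd")) {
          tr[[f]]["treatment"] <- tr[[f]]["baseline"]
        }
      }
      for (a in seq_len(grp$n_animals)) {
        id <- sprintf("%s-%d", grp$name, a)
        for (period in c("baseline", "treatment")) {
          n_days <- if (period == "baseline") n_base else n_treat
          offset <- if (period == "baseline") 0 else
            design$baseline_weeks * 7
          day_idx <- seq_len(n_days)
          dates <- day0 + offset +
            (day_idx - 1) %/% obs_per_week * 7 +
            ((day_idx - 1) %% obs_per_week) * 2
          leak_day <- runif(n_days) < tr$leak_day_probability[period]
          n_leaks <- ifelse(leak_day, 1L + rpois(n_days, tr$extra_leaks_mean), 0L)
          n_voids <- 1L + rpois(n_days, max(0, tr$voids_per_day_mean[period] - 1))
          mass <- rtruncnorm(n_days, tr$daily_mass_mean[period],
                             tr$daily_mass_sd[period], lower = 0)
          water <- rtruncnorm(n_days, tr$water_mean[period],
                              tr$water_sd[period], lower = 0)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            group = grp$name, animal_id = id, obs_date = dates,
            period = period, n_voids = n_voids, n_leaks = n_leaks,
            daily_micturition_mass_g = mass,
            mass_per_void_g = mass / n_voids,
            water_intake_mL = water
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
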