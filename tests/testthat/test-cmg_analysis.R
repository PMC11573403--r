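test_that("zero-phase filtering passes DC and kills a 20 Hz artifact per the
           designed magnitude response", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  rec <- cmg_recording("a", fs, t, rep(10, length(t)), rep(10, length(t)),
                       events = tibble::tibble(time_s = 5, kind = "fill_start"))
  out <- preprocess(rec, cmg_settings())
  expect_lt(max(abs(out$pves - 10)), 1e-9)

  # oracle: squared magnitude response of the designed 4th-order filter
  flt <- signal::butter(4, 5 / (fs / 2), type = "low")
  gain2 <- urodyn:::filter_gain(flt$b, flt$a, 20, fs)^2
  x <- sin(2 * pi * 20 * t)
  rec2 <- cmg_recording("a", fs, t, x, x,
                        events = tibble::tibble(time_s = 5, kind = "fill_start"))
  out2 <- preprocess(rec2, cmg_settings(detrend = FALSE))
  mid <- t > 2 & t < 8
  expect_lt(max(abs(out2$pves[mid])), gain2 * 1.05 + 1e-12)
})

test_that("linear drift is removed (slope < 1e-6 mmHg/s) with mean preserved", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  y <- 2 + 0.01 * t
  rec <- cmg_recording("a", fs, t, y, y,
                       events = tibble::tibble(time_s = 30, kind = "fill_start"))
  out <- preprocess(rec, cmg_settings())
  slope <- coef(lm(out$pves ~ t))[2]
  expect_lt(abs(slope), 1e-6)
  expect_equal(mean(out$pves), mean(y), tolerance = 1e-6)
})

test_that("preprocessing rejects a sample rate at or below twice the cutoff", {
  rec <- make_flat_recording(fs = 8)
  expect_error(preprocess(rec, cmg_settings(cutoff_hz = 5)),
               class = "urodyn_config_error")
})

test_that("pump correction subtracts only within the fill window", {
  rec <- make_flat_recording(fs = 20, offset = 3, slope_per_s = 0)
  # constant mode, offset 0: identity
  same <- correct_pump_pressure(rec, mode = "constant", offset = 0)
  expect_identical(same$pves, rec$pves)
  # constant mode, offset 2: fill window reduced by exactly 2, baseline untouched
  corr <- correct_pump_pressure(rec, mode = "constant", offset = 2)
  in_fill <- rec$time >= 30
  expect_equal(corr$pves[in_fill], rec$pves[in_fill] - 2)
  expect_identical(corr$pves[!in_fill], rec$pves[!in_fill])
  # step estimate recovers an injected 3 mmHg step on flat physiology
  est <- correct_pump_pressure(rec, mode = "step_estimate")
  expect_equal(attr(est, "pump_offset"), 3, tolerance = 0.1)
  expect_lt(diff(range(est$pves)), 1e-9)  # corrected trace is step-free
  # errors
  norec <- make_flat_recording(events = tibble::tibble(time_s = numeric(),
                                                       kind = character()))
  expect_error(correct_pump_pressure(norec, mode = "constant", offset = 1),
               class = "urodyn_segmentation_error")
  expect_error(correct_pump_pressure(rec, mode = "constant"),
               class = "urodyn_config_error")
})

test_that("cycle segmentation maps annotations to phases", {
  ev <- tibble::tibble(time_s = c(30, 630, 900),
                       kind = c("fill_start", "leak", "void_start"))
  t <- seq(0, 950, by = 0.1)
  rec <- cmg_recording("a", 10, t, rep(2, length(t)), rep(8, length(t)),
                       events = ev)
  ph <- segment_cycle(rec)
  expect_equal(ph$baseline_window, c(0, 30))
  expect_equal(ph$storage_window, c(30, 900))
  expect_equal(ph$leak_time, 630)
  expect_equal(ph$void_onset, 900)

  # baseline window falling off the trace start
  rec2 <- cmg_recording("a", 10, t, rep(2, length(t)), rep(8, length(t)),
                        events = tibble::tibble(time_s = 10, kind = "fill_start"))
  expect_error(segment_cycle(rec2), class = "urodyn_segmentation_error")
})

test_that("the urethral-pressure transient detector locates an unannotated leak", {
  sim <- gen_cmg(cmg_truth(noise_sd = 0.05, seed = 5, void_volume = 20,
                           leak_volume = 15.67), sample_rate = 50)
  rec <- sim$recording
  rec$events <- rec$events[rec$events$kind != "leak", ]
  st <- cmg_settings(detrend = FALSE, leak_detector = TRUE)
  ph <- segment_cycle(preprocess(rec, st), st)
  expect_equal(ph$leak_time, sim$phases$leak_time, tolerance = 0.5)
})

test_that("parameter extraction implements the normalization and volume formulae", {
  # constructed trace: baseline 2, storage averaging 6, max 11.8
  fs <- 10
  t <- seq(0, 90, by = 1 / fs)
  pves <- rep(2, length(t))
  storage <- t >= 30
  pves[storage] <- 6
  pves[t >= 89] <- 11.8
  ev <- tibble::tibble(time_s = c(30, 60), kind = c("fill_start", "leak"))
  rec <- cmg_recording("a", fs, t, pves, rep(8, length(t)), events = ev,
                       fill_rate = 2, voided_volume_measured = 6.9,
                       residual_volume_measured = 36.8)
  ph <- segment_cycle(rec)
  p <- compute_parameters(rec, ph)
  expect_equal(p$avg_baseline_pves, 2)
  expect_equal(p$max_storage_pves_norm, 11.8 - 2)
  expect_equal(p$avg_storage_pves_norm, p$avg_storage_pves - 2)
  # leak 30 s after fill start at 2 mL/min -> 1 mL
  expect_equal(p$leak_point_volume, 1)
  # printed-scale worked example: voided 6.9, residual 36.8 -> 15.8%
  expect_equal(round(p$voiding_efficiency, 1), 15.8)
})

test_that("leak point volume is fill rate times elapsed fill time", {
  ev <- tibble::tibble(time_s = c(30, 630), kind = c("fill_start", "leak"))
  t <- seq(0, 700, by = 0.1)
  rec <- cmg_recording("a", 10, t, rep(2, length(t)), rep(8, length(t)),
                       events = ev, fill_rate = 2)
  p <- compute_parameters(rec, segment_cycle(rec))
  expect_equal(p$leak_point_volume, 20)  # 2 mL/min x 10 min
  expect_true(is.na(p$voiding_efficiency))  # no volumes -> absent, not zero
})

test_that("per-animal aggregation averages fields and ignores missing leaks", {
  one <- tibble::tibble(animal_id = "a", avg_baseline_pves = 2,
                        leak_point_volume = 10)
  expect_equal(aggregate_animal(one)$leak_point_volume, 10)
  expect_equal(aggregate_animal(one)$n_cycles, 1L)
  three <- tibble::tibble(animal_id = "a", avg_baseline_pves = c(1, 2, 3),
                          leak_point_volume = c(10, 20, 30))
  expect_equal(aggregate_animal(three)$leak_point_volume, 20)
  mixed <- tibble::tibble(animal_id = "a", avg_baseline_pves = c(1, 2, 3),
                          leak_point_volume = c(10, NA, 30))
  expect_equal(aggregate_animal(mixed)$leak_point_volume, 20)
  expect_error(aggregate_animal(mixed[0, ]), class = "urodyn_validation_error")
  expect_error(
    aggregate_animal(tibble::tibble(animal_id = c("a", "b"),
                                    avg_baseline_pves = 1:2)),
    class = "urodyn_validation_error")
})

test_that("normalization identity holds on noisy generated cycles", {
  for (s in 1:5) {
    sim <- gen_cmg(cmg_truth(noise_sd = 0.4, void_volume = 10, leak_volume = 7,
                             seed = s), sample_rate = 25)
    st <- cmg_settings(detrend = FALSE)
    rec <- correct_pump_pressure(preprocess(sim$recording, st))
    p <- compute_parameters(rec, segment_cycle(rec, st))
    expect_equal(p$avg_storage_pves_norm,
                 p$avg_storage_pves - p$avg_baseline_pves)
    expect_equal(p$max_storage_pves_norm,
                 p$max_storage_pves - p$avg_baseline_pves)
    expect_gte(p$max_storage_pves_norm, p$avg_storage_pves_norm)
    expect_lte(p$leak_point_volume, p$infused_volume)
  }
})

test_that("parameters are invariant to a 20 Hz artifact after filtering", {
  sim <- gen_cmg(cmg_truth(noise_sd = 0, void_volume = 10, leak_volume = 7),
                 sample_rate = 100)
  st <- cmg_settings(detrend = FALSE)
  clean <- sim$recording
  dirty <- clean
  dirty$pves <- dirty$pves + 1 * sin(2 * pi * 20 * dirty$time)
  extract <- function(r) {
    r <- correct_pump_pressure(preprocess(r, st), mode = "constant", offset = 3)
    unlist(compute_parameters(r, segment_cycle(r, st))[-1])
  }
  pc <- extract(clean)
  pd <- extract(dirty)
  expect_lt(max(abs(pd - pc) / pmax(abs(pc), 1e-9)), 0.01)
})

test_that("increasing the injected leak volume strictly increases leak point volume", {
  lv <- c(4, 6, 8)
  got <- vapply(lv, function(v) {
    sim <- gen_cmg(cmg_truth(noise_sd = 0, void_volume = 10, leak_volume = v),
                   sample_rate = 25)
    rec <- correct_pump_pressure(sim$recording, mode = "constant", offset = 3)
    compute_parameters(rec, sim$phases)$leak_point_volume
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})
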