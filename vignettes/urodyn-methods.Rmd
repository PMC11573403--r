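---
title: "Methods: voiding spot assay, cystometry and the gated statistical workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voiding spot assay, cystometry and the gated statistical workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urodyn)
```

# What this package models

Stress urinary incontinence (SUI) is involuntary urine leakage under sudden
abdominal pressure.  In the multiparous-rabbit model of SUI, two behavioural
and one functional readout quantify the deficit and its response to
perineal-nerve neuromodulation:

* the **voiding spot assay (VSA)** — absorbent pads under the cage floor are
  photographed after 24-h periods (3 observation days per week); large
  stains are micturition events (voids), small isolated spots are leaks;
* daily **micturition metrics** — pad mass gain (grams of absorbed urine,
  treated as millilitres of voided volume), voids per day, mass per void,
  water intake, and the percentage of observation days with at least one
  leak;
* **cystometry (CMG)** — the bladder is filled with saline at a constant
  2 mL/min while vesical pressure `P_ves` and urethral pressure `P_ura`
  are recorded; one fill-to-void is a cycle, preceded by a 30-s baseline.

`urodyn` implements the full analysis stack for such a study — image
analysis, signal processing, aggregation, and the statistical comparison
workflow — driven by synthetic generators with known ground truth, so every
stage is testable without animal data.

# Voiding spot assay

`detect_spots()` binarizes a grayscale pad image (Otsu's threshold by
default), labels 8-connected components, drops components below
`min_spot_area` (10 mm² by default) and reports geometry in millimetres
via the `mm/pixel` calibration.  The **equivalent diameter**
`2 * sqrt(area / pi)` defines "diameter" for irregular stains; it is robust
to shape and standard in blob analysis.

`classify_spots()` applies the leak criteria:

1. a spot at least `void_min_diameter` (30 mm) across is a **void**;
2. a spot smaller than `leak_max_diameter` (30 mm) is a **leak** only if
   its edge-to-edge distance to every void is at least
   `splatter_exclusion_distance` (30 mm); otherwise it is
   **splatter_excluded** — small stains thrown off by an active void.

The 30-mm boundary implements the "less than 3 cm in diameter" leak
criterion; a 3-mm reading of the same rule is physically implausible for a
pad stain and is not used.  No published distance defines "away from an
active void", so the exclusion radius defaults to the same 30-mm scale and
is configurable.  When the two diameter thresholds are configured apart,
spots falling in the gap are excluded as ambiguous rather than guessed
into either class, so the three labels always partition the detections.

Otsu's method degenerates on a stain-free pad: it will split sensor noise
into two classes and report phantom spots.  `min_contrast` (default 0.1
intensity units) rejects any Otsu split whose class means are closer than
the floor; a genuinely blank pad then yields an empty spot list.

# Micturition metrics

`summarize_period()` reduces one animal-period to: leak-day frequency
(percent of observation days with ≥ 1 leak), mean daily micturition mass,
mean mass per void (averaged over days where it is defined — a void-free
day contributes no zero), mean voids/day, mean water intake, and — kept
strictly separate — the mean leak-event count per day.  The frequency is
deliberately binary per day: with 3 sampling days per week, "leaked X% of
the time" is a per-day presence/absence statement, and the event-rate
variant is emitted alongside for sensitivity, never mixed in.

`change_scores()` computes treatment-minus-baseline differences per metric,
both absolute and percent; leak-frequency changes are reported in
percentage points.  `group_table()` gives mean, SD, SEM (`SD/sqrt(n)`,
absent for `n = 1`) per group × period × metric.

# Cystometry processing

`preprocess()` applies, per channel:

* **drift removal** (optional, on by default): the best-fit linear slope
  over the full trace is subtracted with the mean level preserved.  This
  targets slow transducer/chart drift in real recordings; a constant trace
  passes through bit-exactly, and a pure linear drift leaves a residual
  slope below 1e-6 mmHg/s.  Because it removes *any* full-trace linear
  component, it also flattens part of a compliance ramp; for synthetic
  drift-free cycles the recovery analyses therefore run with
  `detrend = FALSE`.
* a **zero-phase low-pass Butterworth** filter, 4th order, 5 Hz cutoff by
  default.  Order and forward–backward application are this package's
  choices (standard practice, and they make the response testable: the
  two-pass gain is the designed `|H(f)|` squared).  The implementation
  pads with an odd reflection of ~25 cutoff periods before the two passes
  so that no startup transient reaches the retained samples — a constant
  input is reproduced to ≤ 1e-9.

`correct_pump_pressure()` removes the syringe-pump driving pressure from
`P_ves` within `[fill_start, fill_stop]`.  Because no pump-pressure channel
exists in the recordings, two modes are supported, both explicit guesses:
a user-supplied constant offset, and `step_estimate`, which measures the
median pressure step across fill start (5-s windows each side).

`segment_cycle()` defines the 30-s baseline window immediately before
`fill_start`, the storage window from `fill_start` to void onset (a leak
does **not** terminate storage; storage metrics run to void onset while
leak metrics are reported separately), and the leak time.  Leaks were
observed visually in the study, so the leak time is annotation-driven by
default; an optional detector thresholds the high-pass residual of
`P_ura` at `-k` robust SDs (default `k = 5`) of the baseline residual —
a leak is a transient loss of urethral closure pressure.

`compute_parameters()` evaluates the per-cycle parameter set.  Normalized
pressures subtract the same cycle's mean baseline `P_ves` (the identity
`norm = raw − baseline mean` holds exactly on every output).  Volumes are
derived from the fill arithmetic — no volume channel exists — as
`fill_rate × elapsed time`: the leak point volume uses time from fill
start to the leak, the infused volume the full fill duration.  Voided
volume is taken from measured metadata; residual volume prefers the
measured value and falls back to `infused − voided` (saline fill conserves
volume).  `voiding_efficiency = 100 × voided / (voided + residual)`, and
is reported absent — never zero — when the volumes are unavailable.
`aggregate_animal()` averages cycles within an animal field-by-field,
ignoring missing values (a leak-free cycle contributes nothing to leak
fields), as at least three cycles per animal were collected when possible.

# Stimulation protocol

`stim_protocol()` encodes the treatment schedule: 40-Hz, 200-µs
cathodic-first biphasic pulses, 8 cycles of 15 s on / 45 s off
(25% duty cycle, 120 s effective stimulation per session), 3 sessions per
week.  The biphasic pulse is modelled charge-balanced with equal phase
widths and no interphase gap (none is stated for the device).  Derived
quantities are pure arithmetic: duty cycle, effective stimulation time,
and charge per phase (`mA × µs = nC`; 20 nC at the 0.1-mA contraction
threshold, 46 nC at the 0.23-mA maximum output).  The chronically applied
amplitude is a free field: only the threshold and maximum are known.

# Statistical workflow

The workflow mirrors a Prism-style analysis:

* **ROUT outlier exclusion (Q = 1)**.  ROUT is published for nonlinear
  regression; applying it to a univariate group sample means robustly
  fitting a constant.  This package's specialization: Tukey-biweight IRLS
  location, robust scale RSDR = 68.27th percentile of absolute residuals
  × `N/(N−K)` with `K = 1`, per-point t statistics `|res|/RSDR` on `N−K`
  df, and flagging from the extremes inward by Benjamini–Hochberg step-up
  at rate Q%.  Under clean-normal nulls (n = 8) this flags ~0.2% of
  points; a 10-SD contaminant in n = 20 is flagged essentially always,
  and exclusively in ~98–99% of samples (near-threshold companions are
  occasionally swept in — an inherent property of FDR step-up, not of the
  contaminant's size).
* **Normality gate**: Shapiro–Wilk at α = 0.05 — on the difference vector
  for paired tests, on each sample separately otherwise (the choice is
  recorded in the result, and the route is reproducible from the recorded
  normality p-values).
* **Two-group tests**: paired t / Wilcoxon signed-rank within groups;
  Welch t / Mann–Whitney between groups; all two-tailed.
* **Three-group tests**: Brown–Forsythe *and* Welch one-way ANOVA for
  normal data (the reported omnibus p is Welch's, with the Brown–Forsythe
  F* — the test on means, not the Levene-type spread test — recorded
  alongside), or Kruskal–Wallis otherwise.  Pairwise follow-up uses
  Dunnett's T3 (Welch t statistics against the Studentized Maximum
  Modulus distribution, computed by numerical integration over the scale)
  or Dunn's rank z tests with Bonferroni adjustment.  The specific
  multiple-comparison procedures are named choices; only "with multiple
  comparisons" is prescribed.
* Results report mean ± SEM and the star scheme `* p<0.05`, `** p<0.01`,
  `*** p<0.005` (note the non-standard third tier), `**** p<0.0001`.

Under matched null simulations (10,000 reps) the gated paired and
three-group procedures hold a type-I error close to the nominal 5%
(measured ≈ 5.6% and ≈ 4.6%); the tests assert the 5 ± 1.5% band.
Outlier exclusion is opt-in (`rout_q`) in the comparison functions so the
calibration of the gate itself can be measured cleanly; the study-level
driver `run_study()` passes the workflow's Q = 1.

# Synthetic data: what it emulates, and what it does not

The generators' defaults *are* the study conditions:

* `gen_study()` — groups YN (n = 5, never leaks), MM-sham (n = 8,
  leak-day probability 0.5 in both periods) and MM-ES (n = 8, leak-day
  probability 0.694 at baseline, 0.294 during treatment; daily mass 54.5 g
  → 87.6 g; voids/day and water intake unchanged), observed 3 days/week
  over a 2-week baseline and 4-week treatment.  Between-animal SDs are the
  printed SEMs × √n.  Distribution families — Bernoulli leak days with a
  Poisson excess of events, truncated-normal masses and water, shifted
  Poisson voids (minimum 1) — are this package's choices; only means and
  SEMs are reported for the real data.  Treatment-period truth is forced
  equal to baseline truth for groups without an active implant: a sham
  implant cannot produce an effect, and the sham group's printed
  treatment-period means are sampling noise around no change by its own
  non-significant tests.  Observation days are independent; a per-animal
  random intercept is deliberately not defaulted on, as the within-animal
  day-to-day correlation is unknown.
* `gen_cmg()` — a stylized cycle: 30-s baseline, linear compliance ramp
  with a pump-pressure step, annotated leak with a urethral-pressure
  transient, and a half-sine voiding contraction with exponential pressure
  release (no detrusor biomechanics are modelled; the pump pressure bleeds
  off smoothly at void onset, keeping the trace continuous).  Defaults sit
  at the healthy-control scale: total bladder content 43.7 mL = voided
  6.9 mL + residual 36.8 mL (15.8% efficiency), leak at 38.2 mL,
  compliance slope set so the maximum normalized storage pressure is
  9.8 mmHg and the normalized leak point pressure ≈ 8.6 mmHg; sensor noise
  0.3 mmHg; 100 samples/s (the acquisition rate is not published, so it is
  carried as metadata, and the default is chosen so that 5-Hz two-pass
  filtering of the default sensor noise keeps extraction of the storage
  maximum well inside the recovery tolerances).
* `gen_pad_image()` — disks on a noisy background with pairwise edge
  separation at least twice the splatter exclusion distance, leak
  diameters strictly inside the < 30 mm criterion, and wet mass set
  proportional to stained area.

Because the generators are stylized, passing recovery tests demonstrates
that the pipeline's arithmetic and segmentation are correct under the
stated measurement structure — not that it is robust to overlapping
stains, non-circular spots, movement artifacts, anesthesia effects on the
micturition reflex, or correlated repeated measures, none of which are
modelled.

# Numerical choices and problem sizes

Tolerances asserted by the test suite: noise-free CMG recovery within 1%
relative; 0.3-mmHg noise within 5% over 50 seeded replicates; synthetic-pad
classification exactly equal to truth over 20 seeds; the 200-replicate
synthetic-study mean leak-frequency reduction within ±6 percentage points
of 40; statistical calibrations at 10,000 null replicates.  These problem
sizes keep a full run of the suite to roughly a minute on one core while
leaving Monte-Carlo error far inside each asserted band.  Degenerate
inputs are handled explicitly rather than by fallthrough: all-zero paired
differences short-circuit to p = 1; a uniform image yields no spots; an
absent voided volume yields an absent efficiency; event times are snapped
to the sample grid on serialization (6 significant digits, lossless for
regularly sampled traces).

# Known limitations

* Table-rendered formula cells in the source material are reconstructed
  from the surrounding text; the volume arithmetic is exact but the pump
  correction is necessarily a modelling choice.
* ROUT's exact commercial thresholds are not published in citable closed
  form; the FDR step-up used here matches the procedure's published intent
  and calibrates correctly, but individual borderline calls may differ
  from other implementations.
* The leak detector assumes leaks manifest as sharp `P_ura` drops; slow
  leaks without a urethral transient require annotations.
* No urethral pressure profilometry, EMG, histology or morphometry, and
  no modelling of induction power delivery.
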