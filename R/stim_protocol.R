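# Intermittent electrical stimulation schedule and its derived quantities.

#' Construct a stimulation protocol
#'
#' Defaults encode the treatment schedule: 40-Hz, 200-microsecond
#' cathodic-first biphasic pulses, delivered as 8 cycles of a 15-s train
#' followed by 45 s rest (25% duty cycle, 120 s effective stimulation per
#' session), 3 sessions per week on alternate days.  Amplitude defaults to
#' the maximum induction-powered output of 0.23 mA (the muscle-contraction
#' threshold is 0.1 mA); the chronically used amplitude is a free field.
#'
#' @param frequency_hz Pulse frequency, Hz.
#' @param pulse_width_us Pulse width per phase, microseconds.
#' @param amplitude_ma Current amplitude, mA.
#' @param waveform Only `"biphasic_cathodic_first"` is supported; the
#'   biphasic pulse is assumed charge-balanced with equal phase widths and
#'   no interphase gap.
#' @param n_cycles Number of on/off cycles per session.
#' @param on_time_s Stimulation-train duration per cycle, s.
#' @param off_time_s Rest duration per cycle, s.
#' @param sessions_per_week Treatment sessions per week.
#' @return A `stim_protocol` list.
#' @export
stim_protocol <- function(frequency_hz = 40, pulse_width_us = 200,
                          amplitude_ma = 0.23,
                          waveform = "biphasic_cathodic_first",
                          n_cycles = 8, on_time_s = 15, off_time_s = 45,
                          sessions_per_week = 3) {
  if (!identical(waveform, "biphasic_cathodic_first")) {
    abort_config("waveform must be 'biphasic_cathodic_first'")
  }
  vals <- c(frequency_hz, pulse_width_us, amplitude_ma, n_cycles,
            on_time_s, off_time_s, sessions_per_week)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_config("protocol fields must be non-negative numbers")
  }
  if (on_time_s + off_time_s <= 0) {
    abort_config("on_time_s + off_time_s must be positive")
  }
  structure(list(
    frequency_hz = frequency_hz, pulse_width_us = pulse_width_us,
    amplitude_ma = amplitude_ma, waveform = waveform,
    n_cycles = n_cycles, on_time_s = on_time_s, off_time_s = off_time_s,
    sessions_per_week = sessions_per_week
  ), class = "stim_protocol")
}

#' Duty cycle of a stimulation protocol
#'
#' @param p A [stim_protocol()].
#' @return Percent on-time: `100 * on / (on + off)`.
#' @export
duty_cycle <- function(p) {
  100 * p$on_time_s / (p$on_time_s + p$off_time_s)
}

#' Effective stimulation time per session
#'
#' @param p A [stim_protocol()].
#' @return Seconds of active stimulation: `n_cycles * on_time_s`.
#' @export
effective_stim_time <- function(p) {
  p$n_cycles * p$on_time_s
}

#' Charge per phase
#'
#' Safety bookkeeping for chronic stimulation: amplitude (mA) times phase
#' width (microseconds) gives the injected charge per phase in
#' nanocoulombs.
#'
#' @param p A [stim_protocol()].
#' @return Charge per phase, nC.
#' @export
charge_per_phase <- function(p) {
  p$amplitude_ma * p$pulse_width_us
}

#' Session duration
#'
#' @param p A [stim_protocol()].
#' @return Total wall-clock duration of one session, s.
#' @export
session_duration <- function(p) {
  p$n_cycles * (p$on_time_s + p$off_time_s)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("<stim_protocol> %g Hz, %g us/phase, %g mA (%s)\n",
           "  %d x %g s on / %g s off  (duty %.1f%%, %g s effective, %g nC/phase)\n",
           "  %g sessions/week\n"),
    x$frequency_hz, x$pulse_width_us, x$amplitude_ma, x$waveform,
    x$n_cycles, x$on_time_s, x$off_time_s, duty_cycle(x),
    effective_stim_time(x), charge_per_phase(x), x$sessions_per_week))
  invisible(x)
}
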