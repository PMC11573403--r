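# Internal helpers shared across modules.

# Typed conditions: every validation failure in the package raises one of
# these classes so callers (and the CLI) can distinguish bad input data from
# bad configuration or I/O trouble.
urodyn_error <- function(message, class) {
  stop(structure(
    class = c(paste0("urodyn_", class, "_error"), "urodyn_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_format       <- function(msg) urodyn_error(msg, "format")
abort_validation   <- function(msg) urodyn_error(msg, "validation")
abort_config       <- function(msg) urodyn_error(msg, "config")
abort_segmentation <- function(msg) urodyn_error(msg, "segmentation")
abort_io           <- function(msg) urodyn_error(msg, "io")
abort_detection    <- function(msg) urodyn_error(msg, "detection")
abort_placement    <- function(msg) urodyn_error(msg, "placement")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Single linear filter pass (direct form, zero initial state), vectorised via
# stats::filter: a convolution stage for the MA part feeding a recursive stage
# for the AR part.
lin_filter <- function(b, a, x) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[(nb - 1L) + seq_along(x)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

# Zero-phase (forward-backward) application of an IIR filter with
# odd-reflection edge padding, so that a constant trace passes unchanged and
# no startup transient leaks into the retained segment.  `pad` is the number
# of reflected samples on each side.
zero_phase_filter <- function(b, a, x, pad) {
  n <- length(x)
  if (n < 4L) return(x)
  L <- min(n - 1L, as.integer(pad))
  xp <- c(2 * x[1L] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
  y <- lin_filter(b, a, xp)
  y <- rev(lin_filter(b, a, rev(y)))
  y[(L + 1L):(L + n)]
}

# Low-pass Butterworth, zero phase.  Coefficients come from signal::butter;
# padding length scales with the filter's settling time (~25 cutoff periods
# leaves transients below 1e-12 for a 4th-order design).
lowpass_zero_phase <- function(x, fs, cutoff_hz, order) {
  if (fs <= 2 * cutoff_hz) {
    abort_config(sprintf(
      "sample_rate (%g) must exceed twice the filter cutoff (%g Hz)",
      fs, cutoff_hz))
  }
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  zero_phase_filter(flt$b, flt$a, x, pad = ceiling(25 * fs / cutoff_hz))
}

# Magnitude response |H(f)| of a designed digital filter at frequency f (Hz);
# the two-pass zero-phase gain is this squared.
filter_gain <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * w * (seq_along(a) - 1))
  Mod(num / sum(a * z))
}

# Remove the best-fit linear slope while preserving the mean level: drift
# correction that leaves a constant (and the DC level of any trace) intact.
detrend_keep_mean <- function(y, t) {
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc * tc)
  y - slope * tc
}

# Truncated normal draw via inverse-CDF; degenerate sd = 0 returns the mean.
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- pnorm((lower - mean) / sd)
  u <- runif(n, p_lo, 1)
  mean + sd * qnorm(u)
}

# Minimal union-find over integer labels 1..n (used to merge 4-connected
# components that touch diagonally into 8-connected ones).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
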