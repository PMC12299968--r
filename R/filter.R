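# 4th-order analog Bessel low-pass prototype, normalized so the -3 dB point
# sits at omega = 1 rad/s (magnitude normalization). All-pole filter.
bessel4_proto_poles <- c(
  complex(real = -0.99520876, imaginary = 1.25710574),
  complex(real = -0.99520876, imaginary = -1.25710574),
  complex(real = -1.37006783, imaginary = 0.41024972),
  complex(real = -1.37006783, imaginary = -0.41024972)
)

# Digital 4-pole Bessel low-pass at cutoff_Hz via prewarped bilinear
# transform; returns list(b, a) with unit DC gain.
design_bessel4 <- function(cutoff_Hz, sampling_rate_Hz) {
  if (cutoff_Hz <= 0 || cutoff_Hz > sampling_rate_Hz / 2) {
    abort("cutoff must lie in (0, Nyquist]", class = "blm_error_cutoff")
  }
  fs <- sampling_rate_Hz
  wa <- 2 * fs * tan(pi * cutoff_Hz / fs)   # prewarped analog cutoff, rad/s
  p <- bessel4_proto_poles * wa
  pz <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, 4)))  # 4 zeros at z = -1
  b <- b * sum(a) / sum(b)                   # DC gain (z = 1) exactly 1
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, highest power first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# Causal IIR filtering; the input is offset by its first sample so a trace
# that starts on a non-zero baseline shows no startup transient.
apply_bessel4 <- function(x, cutoff_Hz, sampling_rate_Hz) {
  ba <- design_bessel4(cutoff_Hz, sampling_rate_Hz)
  x0 <- x[1]
  as.numeric(signal::filter(ba$b, ba$a, x - x0)) + x0
}

#' Low-pass filter a current trace
#'
#' Applies a causal 4-pole Bessel-type low-pass, the conventional anti-alias
#' characteristic of patch/bilayer amplifiers (flat group delay, so edges are
#' smoothed without ringing). DC gain is exactly 1, so plateau currents are
#' preserved.
#'
#' @param trace A [blm_trace()].
#' @param cutoff_Hz Cutoff (-3 dB) frequency; defaults to the trace's
#'   `bandwidth_Hz` (itself defaulting to sampling rate / 20).
#' @return A filtered [blm_trace()] with `bandwidth_Hz` set to `cutoff_Hz`.
#' @examples
#' tr <- blm_trace(c(rep(0, 500), rep(1.44, 2000), rep(0, 500)))
#' filt <- lowpass_filter(tr)
#' max(filt$current_pA)
#' @export
lowpass_filter <- function(trace, cutoff_Hz = NULL) {
  stopifnot(inherits(trace, "blm_trace"))
  m <- trace_meta(trace)
  cutoff_Hz <- cutoff_Hz %||% m$bandwidth_Hz
  y <- apply_bessel4(trace$current_pA, cutoff_Hz, m$sampling_rate_Hz)
  blm_trace(y,
    sampling_rate_Hz = m$sampling_rate_Hz,
    voltage_mV = m$voltage_mV,
    bandwidth_Hz = cutoff_Hz,
    t0_s = m$t0_s,
    channel_id = m$channel_id
  )
}

# RMS gain of the filter for white input noise: sqrt(sum h^2) from the
# impulse response. Used to pre-scale simulated instrument noise so its
# post-filter SD matches the requested value.
white_noise_gain <- function(cutoff_Hz, sampling_rate_Hz) {
  n <- max(64, ceiling(8 * sampling_rate_Hz / cutoff_Hz))
  ba <- design_bessel4(cutoff_Hz, sampling_rate_Hz)
  h <- as.numeric(signal::filter(ba$b, ba$a, c(1, numeric(n - 1))))
  sqrt(sum(h^2))
}
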