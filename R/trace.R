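#' Construct a single-channel current trace
#'
#' A `blm_trace` is a tibble with columns `time_s` and `current_pA`, carrying
#' the acquisition metadata every downstream computation needs: the holding
#' potential (conductance is current over voltage), the sampling rate, and the
#' final low-pass bandwidth of the recording chain.
#'
#' Unit conventions are fixed package-wide: currents in pA, voltages in mV,
#' conductances in pS, lifetimes in ms, pore dimensions in Angstrom, AFM
#' heights in nm, times in seconds. Sample indices are 0-based and event
#' windows are half-open `[start, end)`.
#'
#' @param current_pA Numeric vector of current samples, in pA.
#' @param sampling_rate_Hz Samples per second. Default 5000, the acquisition
#'   rate the package's simulator emulates.
#' @param voltage_mV Holding potential in mV (non-zero). Default 100.
#' @param bandwidth_Hz Final low-pass bandwidth in Hz. Defaults to
#'   `sampling_rate_Hz / 20` (the conventional SR/20 recording bandwidth).
#' @param t0_s Time of the first sample, seconds.
#' @param channel_id Free-text identifier of the recording.
#'
#' @return A tibble of class `blm_trace` with columns `time_s`, `current_pA`
#'   and attributes `voltage_mV`, `sampling_rate_Hz`, `bandwidth_Hz`,
#'   `channel_id`, `t0_s`.
#' @examples
#' tr <- blm_trace(rnorm(1000, sd = 0.15))
#' trace_meta(tr)
#' @export
blm_trace <- function(current_pA,
                      sampling_rate_Hz = 5000,
                      voltage_mV = 100,
                      bandwidth_Hz = sampling_rate_Hz / 20,
                      t0_s = 0,
                      channel_id = "sim") {
  if (length(current_pA) < 2) {
    abort("a trace needs at least 2 samples", class = "blm_error_short_trace")
  }
  if (!all(is.finite(current_pA))) {
    abort("trace contains non-finite samples", class = "blm_error_bad_samples")
  }
  check_meta(voltage_mV, sampling_rate_Hz, bandwidth_Hz)
  out <- tibble::tibble(
    time_s = t0_s + (seq_along(current_pA) - 1) / sampling_rate_Hz,
    current_pA = as.numeric(current_pA)
  )
  structure(out,
    class = c("blm_trace", class(out)),
    voltage_mV = voltage_mV,
    sampling_rate_Hz = sampling_rate_Hz,
    bandwidth_Hz = bandwidth_Hz,
    channel_id = channel_id,
    t0_s = t0_s
  )
}

check_meta <- function(voltage_mV, sampling_rate_Hz, bandwidth_Hz) {
  if (!is.finite(sampling_rate_Hz) || sampling_rate_Hz <= 0) {
    abort("sampling_rate_Hz must be positive", class = "blm_error_meta")
  }
  if (!is.finite(bandwidth_Hz) || bandwidth_Hz <= 0 ||
      bandwidth_Hz > sampling_rate_Hz / 2) {
    abort("bandwidth_Hz must lie in (0, sampling_rate_Hz/2]",
      class = "blm_error_meta")
  }
  if (!is.finite(voltage_mV) || voltage_mV == 0) {
    abort("voltage_mV must be non-zero", class = "blm_error_meta")
  }
  invisible(TRUE)
}

#' Acquisition metadata of a trace
#'
#' @param trace A `blm_trace`.
#' @return A one-row tibble with `voltage_mV`, `sampling_rate_Hz`,
#'   `bandwidth_Hz`, `channel_id`, `t0_s`, `n_samples`, `duration_s`.
#' @export
trace_meta <- function(trace) {
  stopifnot(inherits(trace, "blm_trace"))
  tibble::tibble(
    voltage_mV = attr(trace, "voltage_mV"),
    sampling_rate_Hz = attr(trace, "sampling_rate_Hz"),
    bandwidth_Hz = attr(trace, "bandwidth_Hz"),
    channel_id = attr(trace, "channel_id"),
    t0_s = attr(trace, "t0_s"),
    n_samples = nrow(trace),
    duration_s = nrow(trace) / attr(trace, "sampling_rate_Hz")
  )
}

#' @export
print.blm_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf(
    "<blm_trace: %d samples, %.3f s at %g Hz, %g mV, bandwidth %g Hz>\n",
    m$n_samples, m$duration_s, m$sampling_rate_Hz, m$voltage_mV,
    m$bandwidth_Hz
  ))
  NextMethod()
}

# conductance in pS from a baseline-subtracted current in pA at voltage in mV
conductance_pS <- function(current_pA, voltage_mV) {
  1000 * current_pA / voltage_mV
}

#' Recognized event class labels
#'
#' The event taxonomy used throughout: `spike` (acute short transient),
#' `bump` (gradual symmetric rise and fall), `step` (abrupt rise to a stable
#' plateau, the channel open state), `erratic` (large irregular current
#' attributed to membrane damage), and `unclassified`.
#' @export
event_classes <- function() {
  c("spike", "bump", "step", "erratic", "unclassified")
}
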