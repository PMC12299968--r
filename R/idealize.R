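#' Robust baseline estimate of a current trace
#'
#' The baseline level is the sample median and the noise scale is
#' 1.4826 x the median absolute deviation (Gaussian-consistent), refined by
#' one exclusion pass: samples more than 3 x the initial MAD above the
#' median — upward event excursions — are dropped and the MAD recomputed,
#' so the noise scale is not inflated when events occupy an appreciable
#' fraction of the recording. Both statistics stay robust as long as events
#' occupy less than about half of the trace.
#'
#' @param trace A [blm_trace()].
#' @return A one-row tibble: `level_pA`, `noise_sd_pA`, `method`.
#' @export
estimate_baseline <- function(trace) {
  stopifnot(inherits(trace, "blm_trace"))
  if (nrow(trace) < 100) {
    abort("trace too short for baseline estimation (need >= 100 samples)",
      class = "blm_error_short_trace")
  }
  x <- trace$current_pA
  level <- median(x)
  s0 <- mad(x)   # 1.4826 * MAD
  s <- if (s0 > 0) mad(x[x < level + 3 * s0], center = level) else s0
  tibble::tibble(
    level_pA = level,
    noise_sd_pA = s,
    method = "median/MAD(trimmed)"
  )
}

#' Detect current events by hysteresis thresholding
#'
#' Operationalizes the rule of measuring each fluctuation from the beginning
#' of the current increase to the current drop: an event opens when the
#' current exceeds `baseline + k_on x noise_sd`, closes when it falls below
#' `baseline + k_off x noise_sd`, and its boundaries are then extended
#' backward and forward to the nearest baseline crossing. Events shorter
#' than `min_duration_ms` are dropped; events separated by less than
#' `merge_gap_ms` are merged. Only upward deflections are considered (the
#' recordings of interest are at positive holding potential and report
#' current increases).
#'
#' @param trace A [blm_trace()].
#' @param baseline Optional baseline tibble from [estimate_baseline()];
#'   computed from the trace when omitted.
#' @param k_on,k_off Opening / closing threshold multipliers of the noise SD
#'   (`k_on > k_off > 0`); defaults 4 and 1.
#' @param min_duration_ms Shortest retained event; default 2 ms (about half
#'   the rise time of a 250 Hz recording filter).
#' @param merge_gap_ms Events closer than this are merged; default 5 ms.
#' @return A tibble of events (columns of [read_event_table()] plus
#'   `start_index`, `end_index`), all labelled `unclassified`.
#' @examples
#' sim <- simulate_trace(abeta_config(seed = 7, duration_s = 20))
#' detect_events(sim$trace)
#' @export
detect_events <- function(trace, baseline = NULL, k_on = 4, k_off = 1,
                          min_duration_ms = 2, merge_gap_ms = 5) {
  stopifnot(inherits(trace, "blm_trace"))
  if (!(k_on > k_off && k_off > 0)) {
    abort("need k_on > k_off > 0", class = "blm_error_thresholds")
  }
  baseline <- baseline %||% estimate_baseline(trace)
  m <- trace_meta(trace)
  fs <- m$sampling_rate_Hz
  x <- trace$current_pA - baseline$level_pA
  sd0 <- baseline$noise_sd_pA
  if (sd0 == 0) {
    warn("noise SD is zero; falling back to an absolute threshold of 3 x machine epsilon")
    sd0 <- 3 * .Machine$double.eps
  }

  above_off <- x > k_off * sd0
  above_on <- x > k_on * sd0
  runs <- run_bounds(above_off)
  if (nrow(runs) == 0) return(empty_event_table())

  # keep runs that actually reach the opening threshold
  reaches <- vapply(seq_len(nrow(runs)), function(i) {
    any(above_on[runs$start[i]:(runs$end[i] - 1L)])
  }, logical(1))
  runs <- runs[reaches, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_event_table())

  # extend to the nearest baseline crossing on each side
  positive <- x > 0
  runs$start <- vapply(runs$start, function(s) {
    while (s > 1L && positive[s - 1L]) s <- s - 1L
    s
  }, integer(1))
  runs$end <- vapply(runs$end, function(e) {
    while (e <= length(x) && positive[e]) e <- e + 1L
    e
  }, integer(1))

  # merge events separated by less than merge_gap_ms
  gap_samples <- merge_gap_ms / 1000 * fs
  if (nrow(runs) > 1) {
    merged <- list()
    cur <- c(runs$start[1], runs$end[1])
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - cur[2] < gap_samples) {
        cur[2] <- max(cur[2], runs$end[i])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- c(runs$start[i], runs$end[i])
      }
    }
    merged[[length(merged) + 1]] <- cur
    runs <- tibble::tibble(
      start = vapply(merged, `[`, numeric(1), 1),
      end = vapply(merged, `[`, numeric(1), 2)
    )
  }

  # duration cut, then measure
  len_ms <- (runs$end - runs$start) / fs * 1000
  runs <- runs[len_ms >= min_duration_ms, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_event_table())

  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    measure_event(trace, baseline, runs$start[i] - 1L, runs$end[i] - 1L)
  })
}

# half-open [start, end) 1-based bounds of TRUE runs
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values] + 1L)
}

empty_event_table <- function() {
  tibble::tibble(
    start_index = integer(), end_index = integer(),
    start_s = numeric(), end_s = numeric(), lifetime_ms = numeric(),
    mean_current_pA = numeric(), peak_current_pA = numeric(),
    mean_conductance_pS = numeric(), peak_conductance_pS = numeric(),
    class_label = character()
  )
}

#' Measure one event window
#'
#' Mean and peak of the baseline-subtracted current over the half-open,
#' 0-based window `[start_index, end_index)`, with conductance from Ohm's
#' law: G (pS) = 1000 x I (pA) / V (mV).
#'
#' @inheritParams detect_events
#' @param start_index,end_index 0-based half-open sample window.
#' @return A one-row event tibble, labelled `unclassified`.
#' @export
measure_event <- function(trace, baseline = NULL, start_index, end_index) {
  stopifnot(inherits(trace, "blm_trace"))
  baseline <- baseline %||% estimate_baseline(trace)
  n <- nrow(trace)
  if (start_index < 0 || end_index > n || end_index <= start_index) {
    abort("event window outside trace", class = "blm_error_bad_window")
  }
  m <- trace_meta(trace)
  fs <- m$sampling_rate_Hz
  x <- trace$current_pA[(start_index + 1L):end_index] - baseline$level_pA
  tibble::tibble(
    start_index = as.integer(start_index),
    end_index = as.integer(end_index),
    start_s = m$t0_s + start_index / fs,
    end_s = m$t0_s + end_index / fs,
    lifetime_ms = (end_index - start_index) / fs * 1000,
    mean_current_pA = mean(x),
    peak_current_pA = max(x),
    mean_conductance_pS = conductance_pS(mean(x), m$voltage_mV),
    peak_conductance_pS = conductance_pS(max(x), m$voltage_mV),
    class_label = "unclassified"
  )
}
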