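#' Classification rule thresholds
#'
#' Numeric cutoffs that operationalize the qualitative event taxonomy.
#' The source descriptions are qualitative (spikes have "tens of
#' milliseconds" dwell times; steps are stable plateaus; bumps rise and fall
#' gradually; erratic currents exceed 20 pA with irregular shape), so every
#' cutoff is exposed here rather than hard-coded.
#'
#' @param erratic_threshold_pA Peak current above which an irregular event is
#'   attributed to membrane damage; default 20 pA.
#' @param cv_erratic Minimum plateau coefficient of variation for the erratic
#'   call (so a large clean step is not mislabelled); default 0.3.
#' @param spike_max_ms Maximum spike lifetime; default 50 ms.
#' @param rise_step Maximum rise fraction for a step; default 0.15.
#' @param cv_step Maximum plateau CV for a step; default 0.25. Because a CV
#'   cutoff is amplitude-dependent (the same instrument noise gives a small
#'   step a large CV), a plateau also counts as stable when its SD is
#'   explained by the recording noise, see `noise_consistency`.
#' @param noise_consistency Multiple of the baseline noise SD that the
#'   plateau SD may reach and still count as a stable plateau; default 1
#'   (plateau variability at or below the trace's own noise floor).
#' @param symmetry_bump Maximum asymmetry for a bump; default 0.5.
#' @return A named list of class `classifier_rules`.
#' @export
classifier_rules <- function(erratic_threshold_pA = 20, cv_erratic = 0.3,
                             spike_max_ms = 50, rise_step = 0.15,
                             cv_step = 0.25, noise_consistency = 1,
                             symmetry_bump = 0.5) {
  structure(list(
    erratic_threshold_pA = erratic_threshold_pA, cv_erratic = cv_erratic,
    spike_max_ms = spike_max_ms, rise_step = rise_step, cv_step = cv_step,
    noise_consistency = noise_consistency, symmetry_bump = symmetry_bump
  ), class = "classifier_rules")
}

#' Shape features of an idealized event
#'
#' Quantifies the shape descriptors the taxonomy rests on:
#' `rise_fraction` — time from event start to the first sample reaching 90%
#' of the robust peak, divided by the lifetime (an acute rise gives ~0);
#' `plateau_cv` — coefficient of variation of the baseline-subtracted
#' current over the central 50% of the window (a stable plateau gives ~0);
#' `symmetry` — |time to peak - time from peak| / lifetime (0 for a
#' symmetric rise-and-fall); plus `plateau_sd` (the absolute-scale
#' counterpart of `plateau_cv`), `lifetime_ms`, `peak_current_pA` and the
#' baseline `noise_sd_pA` the event was measured against.
#'
#' Shape features are computed on a boxcar-smoothed copy of the event
#' segment (window of about half the recording filter's rise time,
#' `sampling_rate / (2 x bandwidth)` samples) so they describe the waveform
#' rather than the residual instrument noise; `peak_current_pA` is taken
#' from the unsmoothed segment. The rise and symmetry references use a
#' robust peak — the 95th percentile of the smoothed segment — because on a
#' long noisy plateau the raw maximum grows with the window length and
#' would place the 90% crossing at an arbitrary noise excursion. On
#' noiseless canonical shapes these choices are inconsequential.
#'
#' @inheritParams detect_events
#' @param event One event row (from [detect_events()] / [measure_event()]).
#' @return A one-row tibble of features, or all-`NA` features (routed to
#'   `unclassified`) for events shorter than 4 samples.
#' @export
event_features <- function(trace, baseline = NULL, event) {
  stopifnot(inherits(trace, "blm_trace"))
  baseline <- baseline %||% estimate_baseline(trace)
  i0 <- event$start_index
  i1 <- event$end_index
  n <- i1 - i0
  if (n < 4) {
    return(tibble::tibble(lifetime_ms = event$lifetime_ms,
      rise_fraction = NA_real_, plateau_cv = NA_real_, plateau_sd = NA_real_,
      symmetry = NA_real_, peak_current_pA = event$peak_current_pA,
      noise_sd_pA = baseline$noise_sd_pA))
  }
  x <- trace$current_pA[(i0 + 1L):i1] - baseline$level_pA
  m <- trace_meta(trace)
  w <- max(1L, min(n %/% 4L,
    as.integer(round(m$sampling_rate_Hz / (2 * m$bandwidth_Hz)))))
  xs <- boxcar_smooth(x, w)
  robust_peak <- unname(quantile(xs, 0.95, type = 7))
  # rise threshold: 90% of the robust peak. For plateau-like events (median
  # close to the robust peak) the threshold is capped at the median, so a
  # low plateau buried in residual noise still reads as a fast rise; for
  # graded shapes (median well below peak) the cap must not apply or a slow
  # rise would be misread as fast.
  q50 <- median(xs)
  rise_level <- if (q50 > 0.75 * robust_peak) {
    min(0.9 * robust_peak, q50)
  } else {
    0.9 * robust_peak
  }
  i_peak <- which.max(xs)
  i_90 <- which(xs >= rise_level)[1]
  if (is.na(i_90)) i_90 <- i_peak
  mid <- xs[seq.int(floor(n * 0.25) + 1L, ceiling(n * 0.75))]
  cv <- if (mean(mid) > 0) sd(mid) / mean(mid) else Inf
  tibble::tibble(
    lifetime_ms = event$lifetime_ms,
    rise_fraction = (i_90 - 1) / n,
    plateau_cv = cv,
    plateau_sd = sd(mid),
    symmetry = abs((i_peak - 1) - (n - i_peak)) / n,
    peak_current_pA = max(x),
    noise_sd_pA = baseline$noise_sd_pA
  )
}

# centred moving average with shrinking windows at the edges
boxcar_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Classify one event from its shape features
#'
#' A fixed decision cascade; the first matching rule wins:
#' \enumerate{
#'   \item erratic — peak current above the damage threshold AND not
#'     step-like (an irregular plateau, high CV, or a slow rise), so that a
#'     large clean step is never attributed to membrane damage;
#'   \item spike — lifetime below `spike_max_ms`;
#'   \item step — fast rise and stable plateau;
#'   \item bump — gradual, roughly symmetric rise and fall;
#'   \item otherwise unclassified.
#' }
#' Only the erratic rule depends on absolute current; the spike/bump/step
#' decisions are invariant under uniform current rescaling.
#'
#' @param features One-row tibble from [event_features()].
#' @param rules A [classifier_rules()] list.
#' @return A class label string.
#' @export
classify_event <- function(features, rules = classifier_rules()) {
  f <- features
  if (anyNA(f[c("rise_fraction", "plateau_cv", "symmetry")])) {
    return("unclassified")
  }
  if (f$peak_current_pA > rules$erratic_threshold_pA &&
      (f$plateau_cv > rules$cv_erratic ||
         f$rise_fraction >= rules$rise_step)) {
    return("erratic")
  }
  if (f$lifetime_ms < rules$spike_max_ms) return("spike")
  plateau_stable <- f$plateau_cv < rules$cv_step ||
    f$plateau_sd <= rules$noise_consistency * f$noise_sd_pA
  if (f$rise_fraction < rules$rise_step && plateau_stable) {
    return("step")
  }
  if (f$rise_fraction >= rules$rise_step && f$symmetry < rules$symmetry_bump) {
    return("bump")
  }
  "unclassified"
}

#' Label all events in a trace
#'
#' Extracts shape features for each event and applies the classification
#' cascade. When a ground-truth table is supplied (e.g. from
#' [simulate_trace()]), events are matched to true events by window overlap
#' (at least 50% of the shorter window) and a per-class precision/recall
#' summary is attached.
#'
#' @inheritParams detect_events
#' @param events Tibble of idealized events from [detect_events()].
#' @param rules A [classifier_rules()] list.
#' @param truth Optional ground-truth tibble (`class_label`, `start_s`,
#'   `end_s`).
#' @return The events tibble with `class_label` filled in; when `truth` is
#'   given, a `confusion` attribute holds a tibble with per-class `n_true`,
#'   `n_detected`, `recall`, `precision`.
#' @examples
#' sim <- simulate_trace(abeta_config(seed = 3, duration_s = 30))
#' ev <- detect_events(sim$trace)
#' labeled <- classify_all(sim$trace, ev, truth = sim$truth)
#' attr(labeled, "confusion")
#' @export
classify_all <- function(trace, events, rules = classifier_rules(),
                         baseline = NULL, truth = NULL) {
  if (nrow(events) == 0) {
    out <- events
    if (!is.null(truth)) attr(out, "confusion") <- confusion_table(events, truth)
    return(out)
  }
  baseline <- baseline %||% estimate_baseline(trace)
  labels <- vapply(seq_len(nrow(events)), function(i) {
    classify_event(event_features(trace, baseline, events[i, ]), rules)
  }, character(1))
  out <- dplyr::mutate(events, class_label = labels)
  if (!is.null(truth)) attr(out, "confusion") <- confusion_table(out, truth)
  out
}

# match detected to true events by >= 50% overlap of the shorter window
match_events <- function(events, truth) {
  if (nrow(events) == 0 || nrow(truth) == 0) {
    return(tibble::tibble(event = integer(), truth = integer()))
  }
  pairs <- tidyr::expand_grid(event = seq_len(nrow(events)),
    truth = seq_len(nrow(truth)))
  ov_start <- pmax(events$start_s[pairs$event], truth$start_s[pairs$truth])
  ov_end <- pmin(events$end_s[pairs$event], truth$end_s[pairs$truth])
  shorter <- pmin(events$end_s[pairs$event] - events$start_s[pairs$event],
    truth$end_s[pairs$truth] - truth$start_s[pairs$truth])
  keep <- (ov_end - ov_start) >= 0.5 * shorter & shorter > 0
  pairs <- pairs[keep, , drop = FALSE]
  # at most one match per true event: keep the largest-overlap pair
  ov <- (ov_end - ov_start)[keep]
  pairs <- pairs[order(-ov), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$truth), , drop = FALSE]
  pairs[!duplicated(pairs$event), , drop = FALSE]
}

confusion_table <- function(events, truth) {
  matches <- match_events(events, truth)
  truth_label <- truth$class_label
  det_label <- events$class_label
  purrr::map_dfr(setdiff(event_classes(), "unclassified"), function(cl) {
    true_idx <- which(truth_label == cl)
    det_idx <- which(det_label == cl)
    hit <- sum(truth_label[matches$truth] == cl &
                 det_label[matches$event] == cl)
    tibble::tibble(
      class_label = cl,
      n_true = length(true_idx),
      n_detected = length(det_idx),
      recall = if (length(true_idx) > 0) hit / length(true_idx) else NA_real_,
      precision = if (length(det_idx) > 0) hit / length(det_idx) else NA_real_
    )
  })
}
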