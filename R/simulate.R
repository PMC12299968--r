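#' Describe one class of simulated channel events
#'
#' A class is a Poisson stream of events whose per-event mean conductance is
#' drawn from a normal law truncated at zero and whose open lifetime is drawn
#' from a log-normal (parameterized by median and log-scale sigma) or an
#' exponential law. The `shape` selects the waveform: `rectangular` (channel
#' open state: plateau at the drawn conductance), `raised_cosine` (gradual
#' symmetric rise and fall whose time-average equals the drawn mean),
#' `impulse` (one-sample rise, exponential decay over the lifetime; the
#' recording filter turns this into the familiar spike) or `irregular`
#' (positive-clipped random walk representing destructive membrane damage,
#' with peak current forced above the erratic floor).
#'
#' @param label Class label, one of [event_classes()] minus `unclassified`.
#' @param rate_per_s Poisson arrival rate, events per second.
#' @param mean_conductance_pS,sd_conductance_pS Centre and spread of the
#'   per-event mean conductance (pS).
#' @param lifetime_ms_median Median lifetime (ms).
#' @param lifetime_ms_sigma Log-normal sigma; ignored for the exponential law.
#' @param lifetime_law `"lognormal"` or `"exponential"`.
#' @param shape Waveform, see above.
#' @param min_peak_pA For `irregular` only: every event's peak current is
#'   forced above this floor (pA).
#' @return A one-row tibble.
#' @export
event_class_spec <- function(label, rate_per_s,
                             mean_conductance_pS, sd_conductance_pS,
                             lifetime_ms_median, lifetime_ms_sigma = 0,
                             lifetime_law = c("lognormal", "exponential"),
                             shape = c("rectangular", "raised_cosine",
                                       "impulse", "irregular"),
                             min_peak_pA = NA_real_) {
  shape <- match.arg(shape)
  lifetime_law <- match.arg(lifetime_law)
  stopifnot(
    label %in% setdiff(event_classes(), "unclassified"),
    rate_per_s >= 0, mean_conductance_pS > 0, sd_conductance_pS >= 0,
    lifetime_ms_median > 0, lifetime_ms_sigma >= 0
  )
  tibble::tibble(
    label = label, rate_per_s = rate_per_s,
    mean_conductance_pS = mean_conductance_pS,
    sd_conductance_pS = sd_conductance_pS,
    lifetime_ms_median = lifetime_ms_median,
    lifetime_ms_sigma = lifetime_ms_sigma,
    lifetime_law = lifetime_law, shape = shape,
    min_peak_pA = min_peak_pA
  )
}

# Log-normal sigma such that, with the median fixed at `med`, the
# distribution's SD equals `sd`. With x = exp(sigma^2), SD^2 = med^2 x(x-1),
# so x solves x^2 - x - (sd/med)^2 = 0.
lognormal_sigma <- function(med, sd) {
  r2 <- (sd / med)^2
  x <- (1 + sqrt(1 + 4 * r2)) / 2
  sqrt(log(x))
}

#' Default amyloid-beta oligomer simulation configuration
#'
#' Encodes the published per-class statistics of oligomer-induced current
#' signals at 100 mV: spikes (mean conductance 13.38 +/- 10.28 pS, lifetime
#' 9.04 ms), bumps (8.79 +/- 3.34 pS, 321.30 ms), steps (14.40 +/- 7.64 pS,
#' 277.20 ms), plus a low-rate erratic class whose peak current exceeds
#' 20 pA. Lifetimes are log-normal with median at the printed class mean and
#' sigma chosen so the log-normal SD matches the printed SD (the printed SDs
#' exceed the means for bumps and steps, which a normal law cannot produce).
#' Arrival rates are not published; the defaults approximately preserve the
#' published class proportions (27:31:137 spikes:bumps:steps) at a realistic
#' overall event density.
#'
#' @param seed Integer seed; fully determines the simulated recording.
#' @param duration_s Recording length in seconds.
#' @param noise_sd_pA Instrument noise SD after filtering (pA).
#' @return A `sim_config` list, see [simulate_trace()].
#' @export
abeta_config <- function(seed = 1L, duration_s = 120, noise_sd_pA = 0.15) {
  classes <- dplyr::bind_rows(
    event_class_spec("spike", 0.10, 13.38, 10.28,
      9.04, lognormal_sigma(9.04, 4.58), shape = "impulse"),
    event_class_spec("bump", 0.12, 8.79, 3.34,
      321.30, lognormal_sigma(321.30, 426.47), shape = "raised_cosine"),
    event_class_spec("step", 0.50, 14.40, 7.64,
      277.20, lognormal_sigma(277.20, 371.14), shape = "rectangular"),
    event_class_spec("erratic", 0.01, 300, 80,
      300, 0.8, shape = "irregular", min_peak_pA = 20)
  )
  sim_config(classes, seed = seed, duration_s = duration_s,
    noise_sd_pA = noise_sd_pA)
}

#' Default gramicidin simulation configuration
#'
#' A single rectangular (step) class emulating gramicidin D single-channel
#' activity: conductance 11.73 +/- 3.13 pS (normal truncated at zero) and
#' exponentially distributed lifetimes — the standard kinetics of dimer
#' dissociation — with the 75th percentile at 165 ms, i.e. mean
#' 165 / ln 4 (about 119.05 ms) and median 165 ln 2 / ln 4 = 82.5 ms.
#'
#' @inheritParams abeta_config
#' @return A `sim_config` list.
#' @export
gramicidin_config <- function(seed = 1L, duration_s = 120,
                              noise_sd_pA = 0.15) {
  med <- 165 * log(2) / log(4)
  classes <- event_class_spec("step", 0.5, 11.73, 3.13,
    med, lifetime_law = "exponential", shape = "rectangular")
  sim_config(classes, seed = seed, duration_s = duration_s,
    noise_sd_pA = noise_sd_pA)
}

#' Assemble a simulation configuration
#'
#' @param classes Tibble of class rows from [event_class_spec()].
#' @param seed Integer seed; identical configs give identical output.
#' @param duration_s Recording length (s), > 0.
#' @param voltage_mV,sampling_rate_Hz,bandwidth_Hz Acquisition settings;
#'   defaults 100 mV, 5 kHz, sampling rate / 20.
#' @param baseline_pA Baseline current (pA).
#' @param noise_sd_pA White instrument noise, expressed as its SD after
#'   low-pass filtering (pA); internally scaled up by the filter's white-noise
#'   gain before being added pre-filter.
#' @param drift_pA_per_s Linear baseline drift.
#' @param allow_overlap If `FALSE` (default) events are redrawn until their
#'   windows are disjoint.
#' @param filter Apply the recording low-pass ([lowpass_filter()])?
#' @return A `sim_config` list.
#' @export
sim_config <- function(classes, seed = 1L, duration_s = 120,
                       voltage_mV = 100, sampling_rate_Hz = 5000,
                       bandwidth_Hz = sampling_rate_Hz / 20,
                       baseline_pA = 0, noise_sd_pA = 0.15,
                       drift_pA_per_s = 0, allow_overlap = FALSE,
                       filter = TRUE) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    abort("duration_s must be positive", class = "blm_error_config")
  }
  stopifnot(noise_sd_pA >= 0)
  check_meta(voltage_mV, sampling_rate_Hz, bandwidth_Hz)
  structure(list(
    classes = classes, seed = as.integer(seed), duration_s = duration_s,
    voltage_mV = voltage_mV, sampling_rate_Hz = sampling_rate_Hz,
    bandwidth_Hz = bandwidth_Hz, baseline_pA = baseline_pA,
    noise_sd_pA = noise_sd_pA, drift_pA_per_s = drift_pA_per_s,
    allow_overlap = allow_overlap, filter = filter
  ), class = "sim_config")
}

#' Draw per-event statistics for one event class
#'
#' Samples (mean conductance, lifetime) pairs from a class's laws without
#' building a trace — the generator-level view used for statistical checks
#' and power analyses.
#'
#' @param class_spec A one-row tibble from [event_class_spec()].
#' @param n Number of events.
#' @param seed Optional integer seed.
#' @return Tibble with `label`, `mean_conductance_pS`, `lifetime_ms`.
#' @export
sample_class_events <- function(class_spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    label = class_spec$label,
    mean_conductance_pS = rnorm_trunc0(n, class_spec$mean_conductance_pS,
      class_spec$sd_conductance_pS),
    lifetime_ms = draw_lifetimes(class_spec, n)
  )
}

# Zero-truncated normal draws whose post-truncation mean equals `mean`:
# truncating N(mu, sd) at zero shifts its mean up by sd*phi(mu/sd)/Phi(mu/sd),
# so mu is solved for first; without this the recovered class means would sit
# above the configured central values (by ~2 pS for the spike class).
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  mu <- trunc0_location(mean, sd)
  x <- rnorm(n, mu, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mu, sd)
    bad <- which(x <= 0)
  }
  x
}

# location mu such that E[X | X > 0] = target for X ~ N(mu, sd)
trunc0_location <- function(target, sd) {
  f <- function(mu) {
    a <- mu / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a) - target
  }
  stats::uniroot(f, lower = target - 5 * sd, upper = target,
    extendInt = "upX", tol = 1e-10)$root
}

draw_lifetimes <- function(class_spec, n) {
  if (class_spec$lifetime_law == "exponential") {
    rexp(n, rate = log(2) / class_spec$lifetime_ms_median)
  } else {
    rlnorm(n, meanlog = log(class_spec$lifetime_ms_median),
      sdlog = class_spec$lifetime_ms_sigma)
  }
}

#' Simulate a single-channel current recording
#'
#' Builds baseline + drift + the sum of per-event waveforms + white Gaussian
#' noise, then (by default) applies the recording low-pass at
#' `bandwidth_Hz`. Event amplitudes follow Ohm's law: a drawn mean
#' conductance G (pS) at voltage V (mV) contributes a mean excess current of
#' G x V / 1000 pA over the event window. Ground truth (class, window, true
#' mean/peak conductance) is returned alongside; the same config (including
#' seed) always yields bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A list of class `blm_simulation` with elements `trace`
#'   (a [blm_trace()]) and `truth` (tibble: `class_label`, `start_s`,
#'   `end_s`, `lifetime_ms`, `true_mean_conductance_pS`,
#'   `true_peak_conductance_pS`, `truncated`).
#' @examples
#' sim <- simulate_trace(abeta_config(seed = 42, duration_s = 20))
#' dplyr::count(sim$truth, class_label)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_Hz
  n_samples <- round(config$duration_s * fs)
  v <- config$voltage_mV

  # draw all events class by class, in the order the classes are listed
  events <- list()
  for (i in seq_len(nrow(config$classes))) {
    cls <- config$classes[i, ]
    n_ev <- rpois(1, cls$rate_per_s * config$duration_s)
    if (n_ev == 0) next
    events[[length(events) + 1]] <- tibble::tibble(
      label = cls$label, shape = cls$shape,
      mean_conductance_pS = rnorm_trunc0(n_ev, cls$mean_conductance_pS,
        cls$sd_conductance_pS),
      lifetime_ms = draw_lifetimes(cls, n_ev),
      min_peak_pA = cls$min_peak_pA
    )
  }
  events <- if (length(events) > 0) dplyr::bind_rows(events) else tibble::tibble()

  signal_pA <- rep(config$baseline_pA, n_samples)
  if (config$drift_pA_per_s != 0) {
    signal_pA <- signal_pA +
      config$drift_pA_per_s * (seq_len(n_samples) - 1) / fs
  }

  truth <- tibble::tibble(
    class_label = character(), start_s = numeric(), end_s = numeric(),
    lifetime_ms = numeric(), true_mean_conductance_pS = numeric(),
    true_peak_conductance_pS = numeric(), truncated = logical()
  )

  if (nrow(events) > 0) {
    placed <- matrix(numeric(0), ncol = 2)  # accepted [i0, i1) windows
    rows <- vector("list", nrow(events))
    for (j in seq_len(nrow(events))) {
      ev <- events[j, ]
      len <- max(1L, as.integer(round(ev$lifetime_ms / 1000 * fs)))
      i0 <- place_event(len, n_samples, placed, config$allow_overlap)
      if (is.na(i0)) next  # unplaceable after bounded retries
      i1 <- min(i0 + len, n_samples)
      truncated <- (i0 + len) > n_samples
      w <- event_waveform(ev, len, fs, v)[seq_len(i1 - i0)]
      idx <- (i0 + 1):i1
      signal_pA[idx] <- signal_pA[idx] + w
      placed <- rbind(placed, c(i0, i0 + len))
      rows[[j]] <- tibble::tibble(
        class_label = ev$label, start_s = i0 / fs, end_s = i1 / fs,
        lifetime_ms = (i1 - i0) / fs * 1000,
        true_mean_conductance_pS = conductance_pS(mean(w), v),
        true_peak_conductance_pS = conductance_pS(max(w), v),
        truncated = truncated
      )
    }
    truth <- dplyr::bind_rows(rows)
    if (nrow(truth) > 0) truth <- dplyr::arrange(truth, .data$start_s)
  }

  if (config$noise_sd_pA > 0) {
    pre_sd <- if (config$filter) {
      config$noise_sd_pA / white_noise_gain(config$bandwidth_Hz, fs)
    } else {
      config$noise_sd_pA
    }
    signal_pA <- signal_pA + rnorm(n_samples, sd = pre_sd)
  }

  tr <- blm_trace(signal_pA, sampling_rate_Hz = fs, voltage_mV = v,
    bandwidth_Hz = config$bandwidth_Hz)
  if (config$filter) tr <- lowpass_filter(tr, config$bandwidth_Hz)
  structure(list(trace = tr, truth = truth), class = "blm_simulation")
}

# draw a start index; reject-and-redraw while it overlaps accepted windows
place_event <- function(len, n_samples, placed, allow_overlap,
                        max_tries = 10000L) {
  for (try in seq_len(max_tries)) {
    i0 <- as.integer(floor(runif(1, 0, n_samples - 1)))
    if (allow_overlap || nrow(placed) == 0) return(i0)
    i1 <- i0 + len
    if (!any(i0 < placed[, 2] & i1 > placed[, 1])) return(i0)
  }
  warn("could not place an event without overlap; event dropped")
  NA_integer_
}

# per-event excess-current waveform (pA) on a length-`len` sample grid
event_waveform <- function(ev, len, fs, voltage_mV) {
  mean_pA <- ev$mean_conductance_pS * voltage_mV / 1000
  switch(ev$shape,
    rectangular = rep(mean_pA, len),
    raised_cosine = {
      # midpoint phase: the discrete time-average is exactly mean_pA
      ph <- 2 * pi * (seq_len(len) - 0.5) / len
      mean_pA * (1 - cos(ph))
    },
    impulse = {
      # full amplitude on the first sample, exponential decay; k chosen so
      # the window mean equals the drawn mean: mean = P (1 - e^-k) / k
      k <- 2
      p <- mean_pA * k / (1 - exp(-k))
      p * exp(-k * (seq_len(len) - 1) / len)
    },
    irregular = {
      w <- abs(cumsum(rnorm(len)))
      peak_pA <- ev$min_peak_pA + rexp(1, rate = 1 / 10)
      if (max(w) == 0) w[] <- 1
      w * (peak_pA / max(w))
    },
    abort(paste0("unknown shape: ", ev$shape))
  )
}
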