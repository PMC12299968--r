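# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# the standard seeded amyloid-beta recording (~200 events) used for
# detection/classification regression checks
abeta_fixture <- function() {
  fixture("abeta_280s", function() {
    sim <- simulate_trace(abeta_config(seed = 1, duration_s = 280))
    baseline <- estimate_baseline(sim$trace)
    events <- detect_events(sim$trace, baseline)
    labeled <- classify_all(sim$trace, events, baseline = baseline,
      truth = sim$truth)
    list(sim = sim, baseline = baseline, events = events, labeled = labeled,
      confusion = attr(labeled, "confusion"))
  })
}

# a flat baseline descriptor for constructed-trace tests
flat_baseline <- function(noise_sd_pA = 0.01) {
  tibble::tibble(level_pA = 0, noise_sd_pA = noise_sd_pA, method = "fixed")
}

# embed a waveform in a zero trace with padding on both sides
embed_waveform <- function(w, pad = 1000, sampling_rate_Hz = 5000,
                           voltage_mV = 100) {
  blm_trace(c(rep(0, pad), w, rep(0, pad)),
    sampling_rate_Hz = sampling_rate_Hz, voltage_mV = voltage_mV)
}

# canonical noiseless waveforms (amplitudes in pA)
rect_wave <- function(amp_pA, n) rep(amp_pA, n)
raised_cosine_wave <- function(mean_pA, n) {
  mean_pA * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
}
impulse_wave <- function(mean_pA, n, k = 2) {
  p <- mean_pA * k / (1 - exp(-k))
  p * exp(-k * (seq_len(n) - 1) / n)
}
irregular_wave <- function(peak_pA, n, seed = 2) {
  set.seed(seed)
  w <- abs(cumsum(rnorm(n)))
  w / max(w) * peak_pA
}

# classify a single embedded waveform
classify_waveform <- function(w, rules = classifier_rules(), pad = 1000) {
  tr <- embed_waveform(w, pad = pad)
  ev <- measure_event(tr, flat_baseline(), pad, pad + length(w))
  classify_event(event_features(tr, flat_baseline(), ev), rules)
}
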