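test_that("baseline estimation is exact on constant traces and robust to events", {
  const <- blm_trace(rep(2, 1000))
  b <- estimate_baseline(const)
  expect_equal(b$level_pA, 2)
  expect_equal(b$noise_sd_pA, 0)

  set.seed(42)
  noise <- blm_trace(rnorm(1e5, sd = 0.1))
  bn <- estimate_baseline(noise)
  expect_lt(abs(bn$noise_sd_pA - 0.1) / 0.1, 0.10)
  expect_lt(abs(bn$level_pA), 0.01)

  # one 1.44 pA plateau over 10% of the samples must not move the level
  x <- rep(0, 1e4)
  x[4001:5000] <- 1.44
  bp <- estimate_baseline(blm_trace(x))
  expect_lt(abs(bp$level_pA), 0.01)

  expect_error(estimate_baseline(blm_trace(rnorm(50))),
    class = "blm_error_short_trace")
})

test_that("a single clean pulse is recovered with exact boundaries", {
  x <- rep(0, 5000)
  x[1001:2000] <- 1.44   # samples 1000..1999, 0-based
  tr <- blm_trace(x)
  expect_warning(ev <- detect_events(tr), "noise SD is zero")
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$start_index - 1000), 1)
  expect_lte(abs(ev$end_index - 2000), 1)
  expect_equal(ev$mean_conductance_pS, 14.40, tolerance = 1e-9)

  flat <- blm_trace(rep(0, 5000))
  expect_warning(none <- detect_events(flat), "noise SD is zero")
  expect_equal(nrow(none), 0)
})

test_that("pulse pairs merge below the merge gap and stay apart above it", {
  mk <- function(gap_samples) {
    x <- rep(0, 6000)
    x[1001:1500] <- 1.5
    x[(1501 + gap_samples):(2000 + gap_samples)] <- 1.5
    blm_trace(x)
  }
  bl <- flat_baseline(noise_sd_pA = 0.05)
  near <- detect_events(mk(10), bl)    # 2 ms gap < 5 ms default
  far <- detect_events(mk(100), bl)    # 20 ms gap
  expect_equal(nrow(near), 1)
  expect_equal(nrow(far), 2)
})

test_that("event measurement applies Ohm's law to the window statistics", {
  x <- rep(0, 2000)
  x[501:1000] <- 1.173   # 100 ms at 5 kHz
  tr <- blm_trace(x)
  m <- measure_event(tr, flat_baseline(), 500, 1000)
  expect_equal(m$mean_conductance_pS, 11.73, tolerance = 1e-9)
  expect_equal(m$lifetime_ms, 100)

  x2 <- rep(0, 2000)
  x2[501:1000] <- 1.440
  m2 <- measure_event(blm_trace(x2), flat_baseline(), 500, 1000)
  expect_equal(m2$mean_conductance_pS, 14.40, tolerance = 1e-9)

  z <- measure_event(blm_trace(rep(0, 2000)), flat_baseline(), 500, 1000)
  expect_equal(z$mean_conductance_pS, 0)
  expect_equal(z$peak_conductance_pS, 0)

  expect_error(measure_event(tr, flat_baseline(), 1500, 2500),
    class = "blm_error_bad_window")
})

test_that("noiseless synthetic recordings are idealized to ground truth", {
  cfg <- abeta_config(seed = 6, duration_s = 60)
  cfg$noise_sd_pA <- 0
  cfg$filter <- FALSE
  sim <- simulate_trace(cfg)
  fs <- trace_meta(sim$trace)$sampling_rate_Hz
  # no gap merging: it is a noise heuristic, and without noise two events a
  # few ms apart are genuinely resolvable
  suppressWarnings(ev <- detect_events(sim$trace, merge_gap_ms = 0))
  truth <- sim$truth[sim$truth$lifetime_ms >= 2, ]
  expect_equal(nrow(ev), nrow(truth))
  expect_true(all(abs(round(ev$start_s * fs) - round(truth$start_s * fs)) <= 1))
  expect_true(all(abs(round(ev$end_s * fs) - round(truth$end_s * fs)) <= 1))
  expect_equal(ev$mean_conductance_pS, truth$true_mean_conductance_pS,
    tolerance = 1e-6)
})

test_that("detection recalls nearly all >= 5 pS step and bump events at default noise", {
  fx <- abeta_fixture()
  m <- blmchannel:::match_events(fx$events, fx$sim$truth)
  truth <- dplyr::mutate(fx$sim$truth,
    detected = seq_len(nrow(fx$sim$truth)) %in% m$truth)
  big <- dplyr::filter(truth,
    .data$class_label %in% c("step", "bump"),
    .data$true_mean_conductance_pS >= 5)
  expect_gte(mean(big$detected), 0.95)

  # spurious detections: unmatched events per 100 s, at most 5
  spurious <- sum(!(seq_len(nrow(fx$events)) %in% m$event))
  duration_s <- trace_meta(fx$sim$trace)$duration_s
  expect_lte(spurious / duration_s * 100, 5)
})

test_that("every detected event has peak >= mean and detection is idempotent", {
  fx <- abeta_fixture()
  expect_true(all(fx$events$peak_current_pA >= fx$events$mean_current_pA))
  expect_true(all(fx$events$lifetime_ms > 0))
  again <- detect_events(fx$sim$trace, fx$baseline)
  expect_identical(again, fx$events)
})

test_that("threshold multipliers must satisfy k_on > k_off > 0", {
  tr <- blm_trace(rnorm(1000))
  expect_error(detect_events(tr, k_on = 1, k_off = 4),
    class = "blm_error_thresholds")
})
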