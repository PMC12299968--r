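test_that("the amyloid default configuration carries the published class values", {
  cfg <- abeta_config(seed = 1)
  cls <- cfg$classes
  step <- cls[cls$label == "step", ]
  spike <- cls[cls$label == "spike", ]
  bump <- cls[cls$label == "bump", ]
  expect_equal(step$mean_conductance_pS, 14.40)
  expect_equal(step$sd_conductance_pS, 7.64)
  expect_equal(step$lifetime_ms_median, 277.20)
  expect_equal(spike$mean_conductance_pS, 13.38)
  expect_equal(spike$lifetime_ms_median, 9.04)
  expect_equal(bump$mean_conductance_pS, 8.79)
  expect_equal(bump$lifetime_ms_median, 321.30)
  expect_equal(bump$shape, "raised_cosine")
  expect_equal(step$shape, "rectangular")
  expect_true("erratic" %in% cls$label)
})

test_that("log-normal lifetime sigmas reproduce the published SDs", {
  # with median m and sigma s, SD = m * exp(s^2/2) * sqrt(exp(s^2) - 1)
  cls <- abeta_config(seed = 1)$classes
  lnorm_sd <- function(m, s) m * exp(s^2 / 2) * sqrt(exp(s^2) - 1)
  expect_equal(lnorm_sd(277.20, cls$lifetime_ms_sigma[cls$label == "step"]),
    371.14, tolerance = 1e-6)
  expect_equal(lnorm_sd(321.30, cls$lifetime_ms_sigma[cls$label == "bump"]),
    426.47, tolerance = 1e-6)
  expect_equal(lnorm_sd(9.04, cls$lifetime_ms_sigma[cls$label == "spike"]),
    4.58, tolerance = 1e-6)
})

test_that("the gramicidin lifetime law puts its 75th percentile at 165 ms", {
  cfg <- gramicidin_config(seed = 1)
  cls <- cfg$classes
  expect_equal(cls$mean_conductance_pS, 11.73)
  expect_equal(cls$sd_conductance_pS, 3.13)
  expect_equal(cls$lifetime_law, "exponential")
  # exponential with median 165 ln2/ln4 has mean 165/ln4 ~ 119.05 ms
  mean_ms <- cls$lifetime_ms_median / log(2)
  expect_equal(mean_ms, 165 / log(4), tolerance = 1e-9)

  draws <- sample_class_events(cls, 1e5, seed = 99)
  q75 <- lifetime_quantile(draws$lifetime_ms, 0.75)
  expect_lt(abs(q75 - 165) / 165, 0.02)
})

test_that("sampled per-class conductances recover the configured centres", {
  cls <- abeta_config(seed = 1)$classes
  for (lab in c("spike", "bump", "step")) {
    spec <- cls[cls$label == lab, ]
    draws <- sample_class_events(spec, 2000, seed = 17)
    se <- sd(draws$mean_conductance_pS) / sqrt(2000)
    expect_lt(abs(mean(draws$mean_conductance_pS) - spec$mean_conductance_pS),
      3 * se)
  }
})

test_that("a null configuration yields a constant baseline and empty truth", {
  cfg <- sim_config(
    event_class_spec("step", 0, 10, 1, 100),
    seed = 4, duration_s = 2, noise_sd_pA = 0, filter = FALSE,
    baseline_pA = 1.5
  )
  sim <- simulate_trace(cfg)
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$trace$current_pA == 1.5))
})

test_that("a rectangular event at 14.40 pS and 100 mV is a 1.440 pA plateau", {
  cfg <- sim_config(
    event_class_spec("step", 0.5, 14.40, 0, 400),
    seed = 8, duration_s = 4, noise_sd_pA = 0, filter = FALSE
  )
  sim <- simulate_trace(cfg)
  expect_gt(nrow(sim$truth), 0)
  plat <- max(sim$trace$current_pA)
  expect_equal(plat, 1.440, tolerance = 1e-9)
  expect_equal(sim$truth$true_mean_conductance_pS[1], 14.40,
    tolerance = 1e-9)
})

test_that("the same seed reproduces the recording bit for bit", {
  a <- simulate_trace(abeta_config(seed = 123, duration_s = 10))
  b <- simulate_trace(abeta_config(seed = 123, duration_s = 10))
  expect_identical(a$trace$current_pA, b$trace$current_pA)
  expect_identical(a$truth, b$truth)
})

test_that("event counts follow the configured Poisson rate", {
  # 50 expected events over 1000 s at 0.05/s (low sampling rate keeps the
  # trace small; the arrival process does not depend on it)
  cfg <- sim_config(
    event_class_spec("step", 0.05, 10, 1, 50),
    seed = 21, duration_s = 1000, sampling_rate_Hz = 500,
    noise_sd_pA = 0, filter = FALSE
  )
  n <- nrow(simulate_trace(cfg)$truth)
  expect_lt(abs(n - 50), 3 * sqrt(50))
})

test_that("event time-averages equal the drawn means when noise and filter are off", {
  cfg <- abeta_config(seed = 31, duration_s = 40)
  cfg$noise_sd_pA <- 0
  cfg$filter <- FALSE
  sim <- simulate_trace(cfg)
  fs <- trace_meta(sim$trace)$sampling_rate_Hz
  ok_shapes <- sim$truth$class_label %in% c("step", "bump")
  for (i in which(ok_shapes & !sim$truth$truncated)) {
    i0 <- round(sim$truth$start_s[i] * fs)
    i1 <- round(sim$truth$end_s[i] * fs)
    seg <- sim$trace$current_pA[(i0 + 1):i1]
    g <- 1000 * mean(seg) / 100
    expect_equal(g, sim$truth$true_mean_conductance_pS[i], tolerance = 1e-6)
  }
})

test_that("every erratic event peaks above 20 pA at 100 mV", {
  cfg <- abeta_config(seed = 5, duration_s = 600)
  cfg$classes <- cfg$classes[cfg$classes$label == "erratic", ]
  cfg$classes$rate_per_s <- 0.05
  sim <- simulate_trace(cfg)
  expect_gt(nrow(sim$truth), 10)
  peaks_pA <- sim$truth$true_peak_conductance_pS * 100 / 1000
  expect_true(all(peaks_pA > 20))
})

test_that("zero-duration configurations are rejected", {
  expect_error(
    sim_config(event_class_spec("step", 1, 10, 1, 100), duration_s = 0),
    class = "blm_error_config"
  )
})
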