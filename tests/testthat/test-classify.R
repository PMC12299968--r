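test_that("canonical noiseless waveforms receive their defining labels", {
  # 1.44 pA plateau, 1 s; 8.79 pS-mean raised cosine; short decaying
  # transient; 25 pA irregular excursion
  expect_equal(classify_waveform(rect_wave(1.44, 5000)), "step")
  expect_equal(classify_waveform(raised_cosine_wave(0.879, 2000)), "bump")
  expect_equal(classify_waveform(impulse_wave(1.3, 50)), "spike")
  expect_equal(classify_waveform(irregular_wave(25, 3000)), "erratic")
})

test_that("shape features take their defining values on canonical shapes", {
  tr <- embed_waveform(rect_wave(1.44, 5000))
  ev <- measure_event(tr, flat_baseline(), 1000, 6000)
  f <- event_features(tr, flat_baseline(), ev)
  expect_lt(f$rise_fraction, 0.02)
  expect_lt(f$plateau_cv, 1e-9)
  expect_equal(f$peak_current_pA, 1.44)

  trc <- embed_waveform(raised_cosine_wave(0.879, 2000))
  evc <- measure_event(trc, flat_baseline(), 1000, 3000)
  fc <- event_features(trc, flat_baseline(), evc)
  # the 90%-of-peak crossing of 1 - cos(2*pi*t) sits near t = 0.4
  expect_gt(fc$rise_fraction, 0.3)
  expect_lt(fc$rise_fraction, 0.45)
  expect_lt(fc$symmetry, 0.05)

  tri <- embed_waveform(impulse_wave(1.3, 50))
  evi <- measure_event(tri, flat_baseline(), 1000, 1050)
  fi <- event_features(tri, flat_baseline(), evi)
  expect_lt(fi$rise_fraction, 0.1)
  expect_equal(fi$lifetime_ms, 10)
})

test_that("a large clean step is not attributed to membrane damage", {
  # 25 pA exceeds the damage threshold but the shape is a textbook step
  expect_equal(classify_waveform(rect_wave(25, 5000)), "step")
})

test_that("spike, bump and step calls are invariant under current rescaling", {
  for (s in c(0.5, 2)) {
    expect_equal(classify_waveform(rect_wave(1.44 * s, 5000)), "step")
    expect_equal(classify_waveform(raised_cosine_wave(0.879 * s, 2000)), "bump")
    expect_equal(classify_waveform(impulse_wave(1.3 * s, 50)), "spike")
  }
})

test_that("events too short to carry shape information stay unclassified", {
  x <- rep(0, 3000)
  x[1001:1003] <- 1.5
  tr <- blm_trace(x)
  ev <- measure_event(tr, flat_baseline(), 1000, 1003)
  f <- event_features(tr, flat_baseline(), ev)
  expect_true(is.na(f$rise_fraction))
  expect_equal(classify_event(f), "unclassified")
})

test_that("per-class recall on the seeded noisy recording meets the study bars", {
  conf <- abeta_fixture()$confusion
  recall <- function(cl) conf$recall[conf$class_label == cl]
  expect_gte(recall("step"), 0.9)
  expect_gte(recall("bump"), 0.9)
  expect_gte(recall("spike"), 0.8)
  expect_true(all(conf$n_true > 0))
})

test_that("event matching requires majority overlap of the shorter window", {
  ev <- tibble::tibble(start_s = c(0, 10), end_s = c(1, 11))
  truth <- tibble::tibble(start_s = c(0.3, 20), end_s = c(1.3, 21),
    class_label = c("step", "step"))
  m <- blmchannel:::match_events(ev, truth)
  expect_equal(nrow(m), 1)
  expect_equal(m$event, 1)
  expect_equal(m$truth, 1)

  # 40% overlap of the shorter window is not a match
  truth2 <- tibble::tibble(start_s = 0.6, end_s = 1.6, class_label = "step")
  expect_equal(nrow(blmchannel:::match_events(ev, truth2)), 0)
})

test_that("the confusion summary accounts for every labelled class", {
  conf <- abeta_fixture()$confusion
  expect_setequal(conf$class_label, c("spike", "bump", "step", "erratic"))
  expect_true(all(conf$recall >= 0 & conf$recall <= 1, na.rm = TRUE))
  expect_true(all(conf$precision >= 0 & conf$precision <= 1, na.rm = TRUE))
})
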