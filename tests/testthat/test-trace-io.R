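test_that("trace files round-trip and the header carries the metadata", {
  tr <- blm_trace(sin(seq_len(500)) * 2, sampling_rate_Hz = 5000,
    voltage_mV = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)

  header <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("voltage_mV", header)))
  expect_true(any(grepl("sampling_rate_Hz", header)))
  expect_true(any(grepl("bandwidth_Hz", header)))

  back <- read_trace(path)
  expect_equal(back$current_pA, tr$current_pA, tolerance = 1e-6)
  expect_equal(trace_meta(back)$voltage_mV, 100)
  expect_equal(trace_meta(back)$sampling_rate_Hz, 5000)
})

test_that("sampling rate is inferred from the time column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "0.0002,0", "0.0004,1"), path)
  tr <- read_trace(path, voltage_mV = 100)
  expect_equal(nrow(tr), 3)
  expect_equal(trace_meta(tr)$sampling_rate_Hz, 5000)
})

test_that("degenerate and malformed trace files raise distinct errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_trace(empty), class = "blm_error_no_samples")

  expect_error(read_trace(file.path(tempdir(), "nope.csv")),
    class = "blm_error_missing_file")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "0.0002,zap"), bad)
  expect_error(read_trace(bad), class = "blm_error_bad_rows")

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines("0,0", one)
  expect_error(read_trace(one), class = "blm_error_short_trace")

  jitter <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "0.0002,0", "0.00041,1", "0.0006,0"), jitter)
  expect_error(read_trace(jitter), class = "blm_error_irregular_sampling")
})

test_that("event tables round-trip and reject unknown labels", {
  ev <- tibble::tibble(
    start_s = 0.2, end_s = 0.3, lifetime_ms = 100,
    mean_current_pA = 1.173, peak_current_pA = 1.3,
    mean_conductance_pS = 11.73, peak_conductance_pS = 13,
    class_label = "step"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ev))

  empty <- ev[0, ]
  write_event_table(empty, path)
  expect_equal(nrow(read_event_table(path)), 0)

  bad <- dplyr::mutate(ev, class_label = "wiggle")
  expect_error(write_event_table(bad, path), "wiggle",
    class = "blm_error_bad_label")
  readr::write_csv(bad, path)
  expect_error(read_event_table(path), "wiggle",
    class = "blm_error_bad_label")
})

test_that("height maps round-trip with their pixel size", {
  sim <- synth_height_map(5, seed = 3, grid_size = 64)
  path <- withr::local_tempfile(fileext = ".txt")
  write_height_map(sim$map, path)
  back <- read_height_map(path)
  expect_equal(attr(back, "pixel_size_nm"), attr(sim$map, "pixel_size_nm"))
  expect_equal(unclass(back), unclass(sim$map), tolerance = 1e-4,
    ignore_attr = TRUE)
})

test_that("trace constructor enforces metadata invariants", {
  expect_error(blm_trace(c(0, 1), voltage_mV = 0), class = "blm_error_meta")
  expect_error(blm_trace(c(0, 1), bandwidth_Hz = 5000),
    class = "blm_error_meta")
  expect_error(blm_trace(c(0, NA)), class = "blm_error_bad_samples")
  expect_error(blm_trace(1), class = "blm_error_short_trace")
})
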