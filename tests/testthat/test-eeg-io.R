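test_that("recording constructor enforces its invariants", {
  rec <- recording(matrix(rnorm(800), ncol = 2), fs = 400)
  expect_equal(rec$duration_s, 1)
  expect_equal(rec$channel_labels, c("ch1", "ch2"))
  expect_error(recording(matrix(1, 1, 1), fs = 0), "positive")
  expect_error(recording(matrix(1:4, 2), fs = 400, channel_labels = "a"),
               "channel_labels")
})

test_that("csv recordings read with sidecar or explicit fs and conserve samples", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("fr_L,fr_R", "1.5,-2.25", "0.125,3", "-1,0.5", "2,1"), path)
  rec <- read_recording(path, "csv", fs = 400)
  expect_equal(nrow(rec$signals), 4L)
  expect_equal(rec$duration_s, 0.01)
  # values parsed exactly as written
  expect_identical(rec$signals[, 1], c(1.5, 0.125, -1, 2))
  # sidecar provides fs
  yaml::write_yaml(list(fs = 200), paste0(path, ".yaml"))
  rec2 <- read_recording(path, "csv")
  expect_equal(rec2$fs, 200)
  file.remove(paste0(path, ".yaml"))
  expect_error(read_recording(path, "csv"), "sampling rate")
})

test_that("ragged csv is a format error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), path)
  expect_error(read_recording(path, "csv", fs = 400), "ragged")
})

test_that("csv write/read round-trips a recording", {
  rec <- recording(matrix(round(rnorm(600) * 100, 6), ncol = 3), fs = 400,
                   channel_labels = c("fl", "fr", "occ"))
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path, "csv")
  back <- read_recording(path, "csv", fs = 400)
  expect_equal(back$signals, rec$signals, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$channel_labels, rec$channel_labels)
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  set.seed(11)
  fs <- 400
  rec <- recording(matrix(rnorm(3 * 2 * fs, sd = 100), ncol = 3), fs = fs,
                   channel_labels = c("frontal_L", "frontal_R", "occipital"),
                   start_time = 21 * 3600 + 15 * 60)
  path <- tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, "edf")
  expect_equal(back$fs, fs)
  expect_equal(nrow(back$signals), nrow(rec$signals))
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$start_time, rec$start_time)
  q <- (max(rec$signals) - min(rec$signals)) / 65535
  expect_lt(max(abs(back$signals - rec$signals)), 2 * q)
})

test_that("EDF handles lengths that do not divide into 1 s records", {
  rec <- recording(matrix(sin(seq_len(1800)), ncol = 2), fs = 400)
  path <- tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, "edf")
  expect_equal(nrow(back$signals), 900L)
  expect_equal(back$fs, 400)
  expect_equal(back$duration_s, 2.25)
})

test_that("interval files round-trip exactly", {
  iv <- interval_set(c(0, 10.1234567, 30), c(10.1234567, 30, 61.5),
                     c("BS", "AW", "BS"), span = 61.5)
  path <- tempfile(fileext = ".csv")
  write_intervals(iv, path)
  back <- read_intervals(path, span = 61.5)
  expect_equal(back$onset_s, iv$onset_s, tolerance = 1e-6)
  expect_equal(back$offset_s, iv$offset_s, tolerance = 1e-6)
  expect_identical(back$label, iv$label)
  # single interval writes one data row; empty set a header-only file
  write_intervals(interval_set(0, 10, "BS"), path)
  expect_equal(length(readLines(path)), 2L)
  write_intervals(interval_set(), path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_intervals(path)), 0L)
})

test_that("interval_set validation rejects malformed sets", {
  expect_error(interval_set(5, 5, "AW"), "onset_s < offset_s")
  expect_error(interval_set(c(0, 5), c(10, 12), c("BS", "BS")), "overlap")
  expect_error(interval_set(0, 20, "BS", span = 10), "span")
  expect_silent(interval_set(c(0, 5), c(10, 12), c("BS", "AW")))
})
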