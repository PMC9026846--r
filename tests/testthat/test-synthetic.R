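test_that("explicit schedules pass through to the ground truth", {
  sch <- data.frame(state = c("BS", "SWD", "BS"), duration_s = c(120, 6, 120))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 42))
  swd <- sim$truth[sim$truth$label == "SWD", ]
  expect_equal(nrow(swd), 1L)
  expect_equal(swd$duration_s, 6)
  expect_equal(swd$onset_s, 120)
  expect_true(is_tiling(sim$truth, 246))
  expect_equal(nrow(sim$recording$signals), 246 * 400)
})

test_that("fixed seed gives bit-identical recordings", {
  cfg <- simulation_config(duration_s = 60, wake_mean_s = 20,
                           nrem_mean_s = 20, n_swd = c(1, 1))
  a <- simulate_eeg(cfg, seed = 9)
  b <- simulate_eeg(cfg, seed = 9)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- simulate_eeg(cfg, seed = 10)
  expect_false(identical(a$recording$signals, c$recording$signals))
})

test_that("state-invariant violations in configs are rejected", {
  expect_error(simulation_config(swd_freq_hz = c(7, 10)), "8-10")
  expect_error(simulation_config(ma_duration_s = c(3, 20)), "3-15")
  expect_error(simulation_config(swd_duration_s = c(1, 10)), "at least 2")
  sch <- data.frame(state = c("BS", "MA", "BS"), duration_s = c(60, 20, 60))
  expect_error(simulate_eeg(simulation_config(schedule = sch)),
               "config error")
})

test_that("generated SWDs satisfy the band-energy premise (FFT oracle)", {
  # the detector's physical premise: spike-band energy relative to the
  # delta+spindle bands is at least 3x higher during a discharge than in
  # the flanking sleep
  sch <- data.frame(state = c("BS", "SWD", "BS"), duration_s = c(60, 8, 60))
  for (seed in c(1, 2, 3)) {
    sim <- simulate_eeg(simulation_config(schedule = sch, seed = seed))
    fs <- 400
    x <- sim$recording$signals[, 1]
    ratio <- function(idx) {
      seg <- x[idx]
      fft_band_power(seg, fs, c(15, 18)) /
        (fft_band_power(seg, fs, c(2.5, 4.5)) +
         fft_band_power(seg, fs, c(10.5, 12.5)))
    }
    r_swd <- ratio((60 * fs + 1):(68 * fs))
    r_bs <- ratio((30 * fs + 1):(38 * fs))
    expect_gt(r_swd / r_bs, 3)
    # morphology: duration >= 2 s and fundamental within 8-10 Hz
    f0 <- sim$schedule$f0[sim$schedule$label == "SWD"]
    expect_true(f0 >= 8 && f0 <= 10)
  }
})

test_that("SWD trains are near-synchronous across channels", {
  sch <- data.frame(state = c("BS", "SWD", "BS"), duration_s = c(30, 6, 30))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 5))
  fs <- 400
  idx <- (30 * fs + 1):(36 * fs)
  cc <- ccf(sim$recording$signals[idx, 1], sim$recording$signals[idx, 2],
            lag.max = 20, plot = FALSE)
  best <- cc$lag[which.max(cc$acf)]
  expect_lte(abs(best) / fs, 0.01)
  # occipital amplitude is reduced relative to frontal
  expect_lt(sd(sim$recording$signals[idx, 3]),
            sd(sim$recording$signals[idx, 1]))
})

test_that("scoring agreement: identity is 100%, disjoint states are 0%", {
  iv <- interval_set(c(0, 100, 160), c(100, 160, 300),
                     c("AW", "BS", "AW"), span = 300)
  r <- evaluate_scoring(iv, iv)
  expect_equal(r$agreement_pct[r$state %in% c("AW", "BS")], c(100, 100))
  expect_equal(r$precision[1:2], c(1, 1))
  flipped <- interval_set(iv$onset_s, iv$offset_s,
                          c("BS", "AW", "BS"), span = 300)
  r2 <- evaluate_scoring(flipped, iv)
  expect_equal(r2$agreement_pct[1:2], c(0, 0))
  short <- interval_set(0, 100, "AW", span = 100)
  expect_error(evaluate_scoring(short, iv), "span")
})

test_that("agreement equals the hand-computed overlap on partial matches", {
  truth <- interval_set(c(0, 60, 120), c(60, 120, 200),
                        c("BS", "AW", "BS"), span = 200)
  det <- interval_set(c(0, 45, 130), c(45, 130, 200),
                      c("BS", "AW", "BS"), span = 200)
  r <- evaluate_scoring(det, truth)
  want_bs <- naive_overlap(c(0, 120), c(60, 200), c(0, 130), c(45, 200))
  want_aw <- naive_overlap(60, 120, 45, 130)
  expect_equal(r$overlap_s[r$state == "BS"], want_bs)
  expect_equal(r$agreement_pct[r$state == "BS"], 100 * want_bs / 140)
  expect_equal(r$agreement_pct[r$state == "AW"], 100 * want_aw / 60)
})

test_that("random schedules honor the configured event counts and bounds", {
  sim <- simulate_eeg(simulation_config(duration_s = 1200, wake_mean_s = 200,
                                        nrem_mean_s = 300, n_swd = c(3, 5),
                                        seed = 77))
  sch <- sim$schedule
  n_swd <- sum(sch$label == "SWD")
  expect_true(n_swd >= 3 && n_swd <= 5)
  durs <- sch$offset_s[sch$label == "SWD"] - sch$onset_s[sch$label == "SWD"]
  expect_true(all(durs >= 2 & durs <= 10))
  mas <- sch$offset_s[sch$label == "MA"] - sch$onset_s[sch$label == "MA"]
  expect_true(all(mas >= 3 & mas <= 15))
  expect_true(is_tiling(sim$truth, 1200))
})
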