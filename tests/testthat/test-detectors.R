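test_that("parameter constructors enforce invariants", {
  expect_error(swd_detector_params(k_up = 1.2, k_down = 1.5), "k_up > k_down")
  expect_error(swd_detector_params(baseline_window = c(-1, -6)), "baseline")
  expect_error(sleep_detector_params(bs_up_mult = 0.5, bs_down_mult = 0.8),
               "bs_up_mult")
  expect_silent(swd_detector_params())
})

test_that("compute_thresholds is the scaled recording mean", {
  expect_equal(compute_thresholds(rep(10, 500)),
               c(up = 17.5, down = 15.5))
  expect_equal(compute_thresholds(numeric(5) + 0), c(up = 0, down = 0))
  set.seed(1)
  v <- runif(1000)
  expect_equal(compute_thresholds(2 * v), 2 * compute_thresholds(v))
  expect_error(compute_thresholds(numeric(0)), "empty")
})

test_that("hysteresis detects a single pulse and nothing on flat series", {
  fs <- 1
  expect_equal(nrow(hysteresis_detect(rep(3, 50), up = 1.75 * 3,
                                      down = 1.55 * 3, fs = fs)), 0L)
  out <- hysteresis_detect(c(0, 0, 2, 2, 0, 0), up = 1.5, down = 1, fs = fs)
  expect_equal(out$t_up, 2)
  expect_equal(out$t_down, 4)
  # interval still open at the end closes at the series end
  out2 <- hysteresis_detect(c(0, 2, 2), up = 1.5, down = 1, fs = fs)
  expect_equal(out2$t_down, 3)
  expect_error(hysteresis_detect(1:3, up = 1, down = 2, fs = 1), "up >= down")
})

test_that("hysteresis equals the brute-force scan oracle on random series", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    v <- cumsum(rnorm(n))
    up <- stats::quantile(v, runif(1, 0.5, 1))
    down <- up - runif(1, 0, 2)
    fs <- sample(c(1, 10, 400), 1)
    got <- hysteresis_detect(v, up = up, down = down, fs = fs)
    want <- naive_hysteresis(v, up, down, fs)
    expect_equal(got$t_up, want$t_up)
    expect_equal(got$t_down, want$t_down)
  }
})

test_that("SWD characteristic separates spike-band from delta-band content", {
  hi <- swd_characteristic(tone_recording(16.5, dur = 10))
  lo <- swd_characteristic(tone_recording(3.5, dur = 10))
  interior <- (2 * 400):(8 * 400)
  expect_gt(median(hi[interior]), 50 * median(lo[interior]))
  # direction confirmed by the raw FFT band-power oracle
  t <- (seq_len(4000) - 0.5) / 400
  r_hi <- fft_band_power(sin(2 * pi * 16.5 * t), 400, c(15, 18)) /
    (fft_band_power(sin(2 * pi * 16.5 * t), 400, c(2.5, 4.5)) +
     fft_band_power(sin(2 * pi * 16.5 * t), 400, c(10.5, 12.5)))
  r_lo <- fft_band_power(sin(2 * pi * 3.5 * t), 400, c(15, 18)) /
    (fft_band_power(sin(2 * pi * 3.5 * t), 400, c(2.5, 4.5)) +
     fft_band_power(sin(2 * pi * 3.5 * t), 400, c(10.5, 12.5)))
  expect_gt(r_hi, r_lo)
})

test_that("identical channels give the single-channel characteristic", {
  set.seed(7)
  x <- rnorm(4000, sd = 20)
  r3 <- recording(matrix(rep(x, 3), ncol = 3), fs = 400)
  r1 <- recording(matrix(x, ncol = 1), fs = 400)
  expect_equal(as.numeric(swd_characteristic(r3)),
               as.numeric(swd_characteristic(r1)), tolerance = 1e-10)
})

test_that("the characteristic is invariant under amplitude scaling", {
  set.seed(8)
  x <- matrix(rnorm(3 * 4000, sd = 15), ncol = 3)
  c1 <- swd_characteristic(recording(x, fs = 400))
  c2 <- swd_characteristic(recording(7.3 * x, fs = 400))
  expect_equal(as.numeric(c1), as.numeric(c2), tolerance = 1e-9)
})

test_that("an all-zero recording yields a zero characteristic, no crash", {
  rec <- recording(matrix(0, nrow = 2000, ncol = 3), fs = 400)
  ch <- swd_characteristic(rec)
  expect_true(all(ch == 0))
  expect_equal(nrow(detect_swd(rec)), 0L)
})

test_that("extrema validation separates spike trains from baseline-amplitude events", {
  fs <- 400
  set.seed(21)
  t_all <- (seq_len(30 * fs) - 0.5) / fs
  base <- sin(2 * pi * 7 * t_all) + rnorm(length(t_all), sd = 0.1)
  # the discharge replaces the background: spike train with peaks about
  # 8x the baseline peaks in [20, 25] s
  spk <- swdscore:::.swd_waveform(5, 9, fs, slow_frac = 0)
  x <- base
  x[(20 * fs + 1):(25 * fs)] <- 8 * spk
  rec <- recording(matrix(rep(x, 3), ncol = 3), fs = fs)
  v <- validate_swd(rec, c(20, 25))
  expect_true(v$validated)
  expect_true(v$valid)
  expect_gt(v$x_max + v$x_min, 10)
  # an event indistinguishable from baseline has ratios near 1 -> invalid
  rec2 <- recording(matrix(rep(base, 3), ncol = 3), fs = fs)
  v2 <- validate_swd(rec2, c(20, 25))
  expect_false(v2$valid)
  expect_lt(v2$x_max + v2$x_min, 3)
  # the criterion is strict: valid must equal (x_max + x_min > bound)
  expect_identical(v2$valid, (v2$x_max + v2$x_min) > 6)
  # near-threshold events on either side of the bound
  p_lo <- swd_detector_params(criterion_threshold = v$x_max + v$x_min + 1e-9)
  expect_false(validate_swd(rec, c(20, 25), p_lo)$valid)
})

test_that("validation is skipped when the baseline precedes the recording", {
  fs <- 400
  rec <- recording(matrix(rnorm(3 * 10 * fs), ncol = 3), fs = fs)
  v <- validate_swd(rec, c(2, 6))
  expect_false(v$validated)
  expect_true(is.na(v$valid))
})

test_that("detect_swd finds every injected train with >= 80% overlap", {
  sch <- data.frame(
    state = c("AW", "BS", "SWD", "BS", "SWD", "BS", "SWD", "BS", "SWD",
              "BS", "SWD", "BS"),
    duration_s = c(40, 40, 4, 30, 5, 30, 6, 30, 5, 30, 4, 40))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 101))
  truth <- sim$truth[sim$truth$label == "SWD", ]
  ev <- detect_swd(sim$recording)
  expect_equal(nrow(ev), 5L)
  expect_true(all(ev$valid))
  expect_true(all(ev$duration_s >= 2))
  for (j in seq_len(nrow(truth))) {
    ov <- pmax(0, pmin(truth$offset_s[j], ev$t_down) -
                    pmax(truth$onset_s[j], ev$t_up))
    expect_gte(max(ov) / truth$duration_s[j], 0.8)
  }
  # events are sorted and non-overlapping
  expect_true(all(diff(ev$t_up) > 0))
  expect_true(all(ev$t_up[-1] >= ev$t_down[-nrow(ev)]))
})

test_that("a recording without discharges yields no events", {
  # sleep-first background: any wake-fluctuation candidate then has an
  # in-recording baseline and fails the extrema criterion
  sch <- data.frame(state = c("BS", "AW", "BS"), duration_s = c(120, 60, 60))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 102))
  ev <- detect_swd(sim$recording)
  expect_equal(nrow(ev), 0L)
})

test_that("a baseline-amplitude sinusoidal burst is caught then rejected", {
  sch <- data.frame(state = c("AW", "BS", "ART", "BS"),
                    duration_s = c(20, 40, 3, 40))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 103))
  art <- sim$artifacts
  cand <- detect_swd(sim$recording, keep_rejected = TRUE)
  ov <- pmax(0, pmin(art$offset_s[1], cand$t_down) -
                  pmax(art$onset_s[1], cand$t_up))
  expect_true(any(ov > 0))             # energy ratio crossed the threshold
  expect_false(any(cand$valid[ov > 0])) # extrema criterion rejected it
})

test_that("sleep/wake detection recovers an alternating schedule", {
  sch <- data.frame(state = rep(c("AW", "BS"), 3), duration_s = rep(60, 6))
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 104))
  states <- detect_sleep_wake(sim$recording)
  expect_true(is_tiling(states, 360))
  agr <- evaluate_scoring(states, sim$truth, states = c("AW", "BS"))
  expect_gt(agr$agreement_pct[1], 90)
  expect_gt(agr$agreement_pct[2], 90)
  expect_equal(sum(states$label == "BS"), 3L)
  # every truth transition has a detected transition within 5 s
  tt <- sim$truth$onset_s[-1]
  dt <- states$onset_s[-1]
  for (b in tt) expect_lt(min(abs(dt - b)), 5)
})

test_that("an all-sleep recording maps to one covering BS interval", {
  sch <- data.frame(state = "BS", duration_s = 120)
  sim <- simulate_eeg(simulation_config(schedule = sch, seed = 105))
  states <- detect_sleep_wake(sim$recording,
                              params = sleep_detector_params(
                                bs_up_mult = 0.95, bs_down_mult = 0.85),
                              ma_protect = NULL)
  expect_equal(nrow(states), 1L)
  expect_equal(states$label, "BS")
  expect_equal(states$onset_s, 0)
  expect_equal(states$offset_s, 120)
})

test_that("the full scoring partitions the recording with no gaps", {
  sim <- simulate_eeg(simulation_config(duration_s = 300, wake_mean_s = 80,
                                        nrem_mean_s = 120, n_swd = c(2, 2),
                                        seed = 106))
  sc <- score_vigilance(sim$recording)
  expect_s3_class(sc, "vigilance_scoring")
  expect_true(is_tiling(sc$hypnogram, 300))
  expect_true(all(sc$hypnogram$label %in% c("AW", "BS", "SWD", "MA")))
  expect_true(all(sc$swd_events$duration_s >= 2))
  expect_output(print(sc), "Vigilance scoring")
  s <- summary(sc)
  expect_s3_class(s$overall, "sleep_metrics")
  pdf(NULL)
  expect_silent(plot(sc))
  dev.off()
})
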