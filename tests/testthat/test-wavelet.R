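test_that("wavelet_config validates bands and grid", {
  expect_error(wavelet_config(omega0 = -1), "omega0")
  expect_error(wavelet_config(bands = list(a = c(5, 4))), "lo < hi")
  expect_error(wavelet_config(freq_step = 3), "narrowest")
})

test_that("CWT localizes a pure tone in frequency (FFT band-power oracle)", {
  fs <- 400
  t <- (seq_len(20 * fs) - 0.5) / fs
  x <- sin(2 * pi * 16.5 * t)
  w <- morlet_cwt(x, freqs = c(3.5, 16.5), fs = fs)
  interior <- (2 * fs):(18 * fs)
  e_in <- mean(Mod(w[2, interior])^2)
  e_out <- mean(Mod(w[1, interior])^2)
  expect_gt(e_in / e_out, 10)
  # the independent oracle agrees on the direction
  o_in <- fft_band_power(x, fs, c(15, 18))
  o_out <- fft_band_power(x, fs, c(2.5, 4.5))
  expect_gt(o_in / o_out, 10)
})

test_that("CWT is linear and zero on zero input", {
  fs <- 400
  set.seed(1)
  x <- rnorm(2000)
  w1 <- morlet_cwt(x, freqs = c(5, 10), fs = fs)
  w2 <- morlet_cwt(2 * x, freqs = c(5, 10), fs = fs)
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
  w0 <- morlet_cwt(numeric(2000), freqs = c(5, 10), fs = fs)
  expect_true(all(Mod(w0) == 0))
  expect_error(morlet_cwt(x, freqs = 250, fs = fs), "fs/2")
})

test_that("band energy sums |W|^2 over the grid and is non-negative", {
  fs <- 400
  set.seed(2)
  x <- rnorm(4000)
  cfg <- wavelet_config()
  w <- morlet_cwt(x, freqs = band_freqs(c(2.5, 4.5), 0.25), fs = fs)
  e <- band_energy(w, c(2.5, 4.5))
  expect_length(e, length(x))
  expect_true(all(e >= 0))
  # degenerate single-frequency grid equals |W|^2 at that frequency
  e1 <- band_energy(w, c(3.5, 3.5))
  expect_equal(as.numeric(e1), Mod(w[5, ])^2, tolerance = 1e-12)
  expect_error(band_energy(w, c(30, 40)), "outside")
})

test_that("in-band tone energy dominates every disjoint band", {
  fs <- 400
  cfg <- wavelet_config()
  t <- (seq_len(10 * fs) - 0.5) / fs
  x <- sin(2 * pi * 11.5 * t)
  interior <- (2 * fs):(8 * fs)
  es <- lapply(cfg$bands, function(b) {
    w <- morlet_cwt(x, freqs = band_freqs(b, cfg$freq_step), fs = fs)
    mean(band_energy(w, b)[interior])
  })
  expect_gt(es$spindle / es$delta, 10)
  expect_gt(es$spindle / es$spike, 10)
})

test_that("quadratic amplitude scaling of energy", {
  fs <- 400
  set.seed(3)
  x <- rnorm(3000)
  b <- c(5, 10)
  w1 <- morlet_cwt(x, freqs = band_freqs(b, 0.5), fs = fs)
  w2 <- morlet_cwt(3 * x, freqs = band_freqs(b, 0.5), fs = fs)
  expect_equal(as.numeric(band_energy(w2, b)),
               9 * as.numeric(band_energy(w1, b)), tolerance = 1e-10)
})

test_that("smooth_energy reproduces constants and box-filters an impulse", {
  fs <- 400
  con <- structure(rep(4.2, 1000), fs = fs, class = "band_energy_series")
  expect_equal(as.numeric(smooth_energy(con, 0.25)), rep(4.2, 1000),
               tolerance = 1e-12)
  imp <- numeric(1001)
  imp[501] <- 1
  k <- as.integer(0.25 * fs)
  out <- smooth_energy(imp, 0.25, fs = fs)
  expect_equal(max(out), 1 / k, tolerance = 1e-12)
  expect_equal(sum(out > 0), k)
  expect_error(smooth_energy(imp, 0.001, fs = fs), "degenerate")
})

test_that("smoothing preserves the mean of interior-supported series", {
  fs <- 400
  set.seed(4)
  v <- c(numeric(200), runif(5000), numeric(200))
  out <- smooth_energy(v, 0.5, fs = fs)
  expect_equal(mean(out), mean(v), tolerance = 1e-9)
})

test_that("smoothing commutes with positive scaling and constant shifts", {
  fs <- 400
  set.seed(5)
  v <- runif(2000)
  s1 <- as.numeric(smooth_energy(7.3 * v, 0.25, fs = fs))
  s2 <- 7.3 * as.numeric(smooth_energy(v, 0.25, fs = fs))
  expect_equal(s1, s2, tolerance = 1e-12)
  s3 <- as.numeric(smooth_energy(v + 2, 0.25, fs = fs))
  expect_equal(s3, as.numeric(smooth_energy(v, 0.25, fs = fs)) + 2,
               tolerance = 1e-12)
})
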