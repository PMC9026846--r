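# Independent oracles used across tests. These are deliberately naive and
# share no code with the implementation paths they check.

# sample-by-sample state machine for dual-threshold detection
naive_hysteresis <- function(v, up, down, fs) {
  state <- 0L
  s <- NA_integer_
  t_up <- numeric(0)
  t_down <- numeric(0)
  for (i in seq_along(v)) {
    if (state == 0L && v[i] > up) {
      state <- 1L
      s <- i
    } else if (state == 1L && v[i] < down) {
      state <- 0L
      t_up <- c(t_up, (s - 1L) / fs)
      t_down <- c(t_down, (i - 1L) / fs)
    }
  }
  if (state == 1L) {
    t_up <- c(t_up, (s - 1L) / fs)
    t_down <- c(t_down, length(v) / fs)
  }
  data.frame(t_up = t_up, t_down = t_down)
}

# raw periodogram band power
fft_band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  sum(p[f >= band[1L] & f <= band[2L]])
}

# direct pairwise interval-intersection total
naive_overlap <- function(a_on, a_off, b_on, b_off) {
  tot <- 0
  for (i in seq_along(a_on))
    for (j in seq_along(b_on))
      tot <- tot + max(0, min(a_off[i], b_off[j]) - max(a_on[i], b_on[j]))
  tot
}

# small helper: recording with one pure tone per channel
tone_recording <- function(freq, dur = 20, fs = 400, amp = 50, nch = 3) {
  t <- (seq_len(dur * fs) - 0.5) / fs
  recording(matrix(rep(amp * sin(2 * pi * freq * t), nch), ncol = nch),
            fs = fs)
}
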