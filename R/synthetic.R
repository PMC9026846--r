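#' Synthetic EEG simulation configuration
#'
#' Describes a multichannel rodent epidural EEG with a known vigilance-state
#' sequence, used to validate the detectors against exact ground truth.
#' Defaults emulate a 1 h, 3-channel, 400 Hz dark-phase recording:
#' wake/sleep episodes of roughly ten minutes (about three sleep episodes
#' per hour, as seen in dark-phase rodent hypnograms), 10-20 spike-wave
#' discharges of 2-10 s with an 8-10 Hz fundamental at about eight times
#' background amplitude, and around two micro-arousals per hour of sleep.
#'
#' Spectral recipes per state: wake is low-voltage broadband (pink) noise
#' with 6-8 Hz theta; NREM sleep is high-amplitude delta (1-4 Hz) plus a
#' mid-frequency 5-9 Hz oscillation and waxing-waning 11-13 Hz spindle
#' bursts, shared across channels (synchronized EEG); micro-arousals use the
#' wake recipe. Spike-wave complexes are periodic sharp biphasic spikes
#' (Gaussian-derivative, ~25 ms wide, rich in harmonics above 15 Hz) plus a
#' phase-locked slow wave, near-synchronous across channels with reduced
#' amplitude on the occipital channel.
#'
#' @param fs sampling rate (samples/s).
#' @param n_channels number of channels (third channel is treated as
#'   occipital for SWD amplitude scaling).
#' @param duration_s recording length (s); ignored when `schedule` is given.
#' @param schedule optional explicit data frame with columns `state`
#'   (`AW`, `BS`, `SWD`, `MA`, `ART`) and `duration_s`; otherwise a random
#'   schedule is generated from the episode parameters below.
#' @param wake_mean_s,nrem_mean_s mean wake/NREM episode durations (s).
#' @param episode_jitter relative uniform jitter on episode durations.
#' @param n_swd `c(min, max)` count of SWDs to embed.
#' @param swd_duration_s `c(min, max)` SWD durations (s); minimum 2 s.
#' @param swd_freq_hz `c(min, max)` range of the instantaneous SWD
#'   fundamental (Hz), within 8-10 Hz. Each train settles to a fundamental
#'   drawn from the lower half of this range after a brief faster initial
#'   phase reaching toward the top of the range (the standard
#'   absence-seizure chirp).
#' @param swd_amp_mult spike amplitude as a multiple of the NREM background
#'   amplitude.
#' @param swd_channel_gain per-channel SWD gain (recycled/truncated to
#'   `n_channels`); default frontal 1, 1, occipital 0.7.
#' @param swd_jitter_s maximum inter-channel SWD onset jitter (s), bilateral
#'   synchrony.
#' @param ma_rate_per_h expected micro-arousals per hour of sleep.
#' @param ma_duration_s `c(min, max)` micro-arousal durations, within 3-15 s.
#' @param n_artifacts number of oscillatory artifact bursts (pure sinusoid
#'   at near-baseline amplitude) to embed in sleep, for testing the extrema
#'   rejection path.
#' @param artifact_freq_hz artifact carrier frequency (Hz).
#' @param artifact_amp_mult artifact amplitude as a multiple of the NREM
#'   background amplitude (near 1: an energy-detectable but
#'   amplitude-unremarkable burst).
#' @param artifact_duration_s `c(min, max)` artifact durations (s).
#' @param amplitudes named list of component amplitudes in microvolts:
#'   `wake_broadband`, `wake_theta`, `nrem_delta`, `nrem_mid`,
#'   `nrem_spindle`, `swd_background`, `swd_slow_frac`.
#' @param seed default RNG seed for [simulate_eeg()].
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(fs = 400, n_channels = 3, duration_s = 3600,
                              schedule = NULL,
                              wake_mean_s = 600, nrem_mean_s = 600,
                              episode_jitter = 0.5,
                              n_swd = c(10, 20),
                              swd_duration_s = c(2, 10),
                              swd_freq_hz = c(8, 10),
                              swd_amp_mult = 8,
                              swd_channel_gain = c(1, 1, 0.7),
                              swd_jitter_s = 0.01,
                              ma_rate_per_h = 2,
                              ma_duration_s = c(3, 15),
                              n_artifacts = 0,
                              artifact_freq_hz = 16.5,
                              artifact_amp_mult = 1.5,
                              artifact_duration_s = c(2, 4),
                              amplitudes = list(wake_broadband = 20,
                                                wake_theta = 15,
                                                nrem_delta = 60,
                                                nrem_mid = 35,
                                                nrem_spindle = 25,
                                                swd_background = 8,
                                                swd_slow_frac = 0.45),
                              seed = 1) {
  if (fs <= 0) stop("fs must be positive")
  if (swd_freq_hz[1L] < 8 || swd_freq_hz[2L] > 10)
    stop("config error: SWD fundamental must lie within 8-10 Hz")
  if (swd_duration_s[1L] < 2)
    stop("config error: SWD duration must be at least 2 s")
  if (ma_duration_s[1L] < 3 || ma_duration_s[2L] > 15)
    stop("config error: micro-arousal durations must lie within 3-15 s")
  gain <- rep_len(swd_channel_gain, n_channels)
  structure(list(fs = fs, n_channels = n_channels, duration_s = duration_s,
                 schedule = schedule, wake_mean_s = wake_mean_s,
                 nrem_mean_s = nrem_mean_s, episode_jitter = episode_jitter,
                 n_swd = n_swd, swd_duration_s = swd_duration_s,
                 swd_freq_hz = swd_freq_hz, swd_amp_mult = swd_amp_mult,
                 swd_channel_gain = gain, swd_jitter_s = swd_jitter_s,
                 ma_rate_per_h = ma_rate_per_h, ma_duration_s = ma_duration_s,
                 n_artifacts = n_artifacts,
                 artifact_freq_hz = artifact_freq_hz,
                 artifact_amp_mult = artifact_amp_mult,
                 artifact_duration_s = artifact_duration_s,
                 amplitudes = amplitudes, seed = seed),
            class = "simulation_config")
}

# Settled fundamental of a spike-wave train, drawn from the lower half of
# the configured frequency range; the train's brief initial phase runs up to
# the top of the range before settling (see .swd_waveform).
.draw_settle_f0 <- function(n, freq_range) {
  stats::runif(n, freq_range[1L], freq_range[1L] + 0.5 * diff(freq_range))
}

# band-limited unit-variance Gaussian noise via spectral masking
.bandlimited_noise <- function(n, fs, band) {
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  mask <- f >= band[1L] & f <= band[2L]
  z <- stats::fft(stats::rnorm(nfft))
  z[!mask] <- 0
  x <- Re(stats::fft(z, inverse = TRUE))[seq_len(n)] / nfft
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# pink (1/f amplitude) broadband noise, unit variance
.pink_noise <- function(n, fs) {
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)
  g <- 1 / sqrt(pmax(f, 1))
  g[1L] <- 0
  z <- stats::fft(stats::rnorm(nfft)) * g
  x <- Re(stats::fft(z, inverse = TRUE))[seq_len(n)] / nfft
  x / stats::sd(x)
}

# centered running mean with truncated edges (plain numeric helper)
.runmean <- function(v, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - (k - 1L) %/% 2L, 1L)
  hi <- pmin(i + k %/% 2L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# split one BS row of a tiling by an embedded event; returns the new tiling
.place_in_bs <- function(tiling, dur, label, lead, trail, f0 = NA_real_) {
  len <- tiling$offset_s - tiling$onset_s
  room <- len - lead - trail - dur
  ok <- which(tiling$label == "BS" & room > 0)
  if (!length(ok)) return(NULL)
  row <- if (length(ok) == 1L) ok else
    sample(ok, 1L, prob = room[ok])
  pos <- tiling$onset_s[row] + lead + stats::runif(1L) * room[row]
  before <- tiling[row, , drop = FALSE]
  after <- tiling[row, , drop = FALSE]
  before$offset_s <- pos
  after$onset_s <- pos + dur
  ev <- data.frame(onset_s = pos, offset_s = pos + dur, label = label,
                   f0 = f0, stringsAsFactors = FALSE)
  out <- rbind(tiling[seq_len(nrow(tiling)) < row, , drop = FALSE],
               before, ev, after,
               tiling[seq_len(nrow(tiling)) > row, , drop = FALSE])
  rownames(out) <- NULL
  out
}

.make_schedule <- function(config) {
  if (!is.null(config$schedule)) {
    sch <- config$schedule
    if (!all(c("state", "duration_s") %in% names(sch)))
      stop("explicit schedule needs columns state and duration_s")
    if (any(sch$duration_s <= 0)) stop("config error: schedule durations must be > 0")
    bad_ma <- sch$state == "MA" &
      (sch$duration_s < config$ma_duration_s[1L] |
       sch$duration_s > config$ma_duration_s[2L])
    if (any(bad_ma))
      stop("config error: micro-arousal episode outside the allowed duration range")
    if (any(sch$state == "SWD" & sch$duration_s < 2))
      stop("config error: SWD episode shorter than 2 s")
    off <- cumsum(sch$duration_s)
    tiling <- data.frame(onset_s = c(0, off[-length(off)]), offset_s = off,
                         label = sch$state,
                         f0 = ifelse(sch$state == "SWD",
                                     .draw_settle_f0(nrow(sch),
                                                     config$swd_freq_hz),
                                     NA_real_),
                         stringsAsFactors = FALSE)
    return(tiling)
  }
  # alternate wake and sleep episodes, then embed MAs, SWDs and artifacts in sleep
  on <- 0; labs <- character(0); ons <- numeric(0); offs <- numeric(0)
  state <- "AW"
  while (on < config$duration_s) {
    m <- if (state == "AW") config$wake_mean_s else config$nrem_mean_s
    d <- m * stats::runif(1L, 1 - config$episode_jitter,
                          1 + config$episode_jitter)
    d <- min(d, config$duration_s - on)
    ons <- c(ons, on); offs <- c(offs, on + d); labs <- c(labs, state)
    on <- on + d
    state <- if (state == "AW") "BS" else "AW"
  }
  tiling <- data.frame(onset_s = ons, offset_s = offs, label = labs,
                       f0 = NA_real_, stringsAsFactors = FALSE)
  total_bs <- sum(tiling$offset_s[tiling$label == "BS"] -
                  tiling$onset_s[tiling$label == "BS"])
  n_ma <- stats::rpois(1L, config$ma_rate_per_h * total_bs / 3600)
  for (i in seq_len(n_ma)) {
    d <- stats::runif(1L, config$ma_duration_s[1L], config$ma_duration_s[2L])
    t2 <- .place_in_bs(tiling, d, "MA", lead = 12, trail = 6)
    if (!is.null(t2)) tiling <- t2
  }
  n_swd <- if (config$n_swd[1L] == config$n_swd[2L]) config$n_swd[1L] else
    sample(seq(config$n_swd[1L], config$n_swd[2L]), 1L)
  for (i in seq_len(n_swd)) {
    d <- stats::runif(1L, config$swd_duration_s[1L], config$swd_duration_s[2L])
    f0 <- .draw_settle_f0(1L, config$swd_freq_hz)
    t2 <- .place_in_bs(tiling, d, "SWD", lead = 10, trail = 10, f0 = f0)
    if (!is.null(t2)) tiling <- t2
  }
  for (i in seq_len(config$n_artifacts)) {
    d <- stats::runif(1L, config$artifact_duration_s[1L],
                      config$artifact_duration_s[2L])
    t2 <- .place_in_bs(tiling, d, "ART", lead = 10, trail = 10)
    if (!is.null(t2)) tiling <- t2
  }
  tiling
}

# One spike-wave train: biphasic Gaussian-derivative spikes plus a
# phase-locked slow wave; unit spike amplitude. The instantaneous
# fundamental follows the standard absence-seizure morphology: a brief
# faster initial phase settling exponentially to the train's fundamental
# (time constant ~0.6 s), always inside the 8-10 Hz range.
.swd_waveform <- function(dur, f0, fs, sigma = 0.008, cycle_jitter = 0.004,
                          slow_frac = 0.45, f_start = NULL,
                          settle_tau = 0.6) {
  n <- as.integer(round(dur * fs))
  tau <- (seq_len(n) - 0.5) / fs
  if (is.null(f_start)) f_start <- min(10, f0 + stats::runif(1L, 0.5, 1.5))
  f_inst <- f0 + (f_start - f0) * exp(-tau / settle_tau)
  phase <- 2 * pi * cumsum(f_inst) / fs
  # spike centers where the accumulated phase crosses full cycles
  k <- floor(phase / (2 * pi))
  centers <- tau[which(diff(k) >= 1L) + 1L]
  centers <- centers + stats::rnorm(length(centers), 0, cycle_jitter)
  w <- numeric(n)
  for (c0 in centers) {
    i0 <- max(1L, as.integer(floor((c0 - 5 * sigma) * fs)))
    i1 <- min(n, as.integer(ceiling((c0 + 5 * sigma) * fs)))
    if (i1 < i0) next
    tt <- (tau[i0:i1] - c0) / sigma
    w[i0:i1] <- w[i0:i1] - tt * exp(-tt^2 / 2) / 0.6065307
  }
  # stereotyped phase relation: the sharp spike rides the crest of the slow
  # wave (spike centers fall at full-cycle phase, where cos peaks)
  w + slow_frac * cos(phase)
}

# raised-cosine edge taper weight for one event inside a length-n record
.event_weight <- function(n, fs, onset, offset, ramp = 0.1) {
  i0 <- max(1L, as.integer(floor(onset * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling(offset * fs)))
  w <- numeric(n)
  if (i1 < i0) return(w)
  w[i0:i1] <- 1
  nr <- max(1L, as.integer(ramp * fs))
  up <- seq(0, 1, length.out = nr)
  ia <- i0:min(i1, i0 + nr - 1L)
  w[ia] <- w[ia] * up[seq_along(ia)]
  ib <- max(i0, i1 - nr + 1L):i1
  w[ib] <- w[ib] * rev(up)[seq_along(ib)]
  w
}

#' Simulate a multichannel EEG with ground-truth states
#'
#' Generates a recording following a known vigilance-state schedule together
#' with the ground-truth interval set, so detector output can be scored
#' exactly. Fixed seed gives bit-identical output. By construction, SWD
#' epochs carry elevated 15-18 Hz energy relative to the 2.5-4.5 and
#' 10.5-12.5 Hz bands (the detector's physical premise); this is asserted by
#' the package's test suite via an independent FFT band-power oracle.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (defaults to the one in `config`).
#' @return List of class `synthetic_eeg` with elements `recording`
#'   ([recording()]), `truth` ([interval_set()] over `AW`/`BS`/`SWD`/`MA`
#'   tiling the recording), `artifacts` (interval set of embedded oscillatory
#'   artifacts, labeled `BS` in `truth`), `schedule` (the internal tiling
#'   with SWD fundamentals) and `config`.
#' @examples
#' sim <- simulate_eeg(simulation_config(duration_s = 60, n_swd = c(0, 0),
#'                                       wake_mean_s = 30, nrem_mean_s = 30,
#'                                       ma_rate_per_h = 0))
#' sim$truth
#' @export
simulate_eeg <- function(config = simulation_config(), seed = config$seed) {
  set.seed(seed)
  fs <- config$fs
  tiling <- .make_schedule(config)
  span <- tiling$offset_s[nrow(tiling)]
  n <- as.integer(round(span * fs))
  amp <- config$amplitudes
  nrem_sigma <- sqrt(amp$nrem_delta^2 + amp$nrem_mid^2 +
                     amp$nrem_spindle^2 + amp$wake_broadband^2)

  # state weight masks with 0.2 s ramps
  idx_of <- function(labels) {
    w <- numeric(n)
    for (r in which(tiling$label %in% labels)) {
      i0 <- max(1L, as.integer(floor(tiling$onset_s[r] * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling(tiling$offset_s[r] * fs)))
      if (i1 >= i0) w[i0:i1] <- 1
    }
    w
  }
  ramp_k <- as.integer(0.2 * fs)
  w_wake <- .runmean(idx_of(c("AW", "MA")), ramp_k)
  w_bs <- .runmean(idx_of(c("BS", "ART")), ramp_k)
  w_swd <- .runmean(idx_of("SWD"), ramp_k)

  pink_sd <- amp$wake_broadband * w_wake +
    amp$wake_broadband * 0.75 * w_bs + amp$swd_background * w_swd

  # synchronized (common) sleep components
  delta_c <- .bandlimited_noise(n, fs, c(1, 4))
  mid_c <- .bandlimited_noise(n, fs, c(5, 9))
  sp_car <- .bandlimited_noise(n, fs, c(11, 13))
  sp_env <- pmax(0, .bandlimited_noise(n, fs, c(0.2, 0.6)))
  spindle_c <- sp_car * sp_env
  s <- stats::sd(spindle_c)
  if (s > 0) spindle_c <- spindle_c / s

  swd_rows <- which(tiling$label == "SWD")
  art_rows <- which(tiling$label == "ART")
  swd_wave <- lapply(swd_rows, function(r)
    .swd_waveform(tiling$offset_s[r] - tiling$onset_s[r], tiling$f0[r], fs,
                  slow_frac = amp$swd_slow_frac))
  # per-channel onset offsets within +/- jitter/2 so that any pairwise
  # channel lag stays within the configured bilateral-synchrony bound
  swd_jit <- lapply(swd_rows, function(r)
    stats::runif(config$n_channels, -config$swd_jitter_s / 2,
                 config$swd_jitter_s / 2))

  sig <- matrix(0, nrow = n, ncol = config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    x <- .pink_noise(n, fs) * pink_sd
    x <- x + amp$wake_theta * w_wake * .bandlimited_noise(n, fs, c(6, 8))
    g <- stats::runif(1L, 0.9, 1.1)
    x <- x + w_bs * g * (amp$nrem_delta * delta_c + amp$nrem_mid * mid_c +
                         amp$nrem_spindle * spindle_c)
    for (k in seq_along(swd_rows)) {
      r <- swd_rows[k]
      on <- tiling$onset_s[r] + swd_jit[[k]][ch]
      wv <- swd_wave[[k]]
      i0 <- max(1L, as.integer(floor(on * fs)) + 1L)
      i1 <- min(n, i0 + length(wv) - 1L)
      amp_swd <- config$swd_amp_mult * nrem_sigma * config$swd_channel_gain[ch]
      ww <- .event_weight(length(wv), fs, 0, length(wv) / fs, ramp = 0.1)
      x[i0:i1] <- x[i0:i1] + amp_swd * (wv * ww)[seq_len(i1 - i0 + 1L)]
    }
    for (r in art_rows) {
      wv <- .event_weight(n, fs, tiling$onset_s[r], tiling$offset_s[r],
                          ramp = 0.1)
      tt <- (seq_len(n) - 0.5) / fs
      x <- x + config$artifact_amp_mult * nrem_sigma *
        sin(2 * pi * config$artifact_freq_hz * tt) * wv
    }
    sig[, ch] <- x
  }
  labels <- c("frontal_L", "frontal_R", "occipital",
              paste0("ch", seq_len(max(0, config$n_channels - 3)) + 3))
  rec <- recording(sig, fs = fs,
                   channel_labels = labels[seq_len(config$n_channels)])
  truth_lab <- ifelse(tiling$label == "ART", "BS", tiling$label)
  truth <- coalesce_intervals(
    interval_set(tiling$onset_s, tiling$offset_s, truth_lab, span = span))
  artifacts <- if (length(art_rows))
    interval_set(tiling$onset_s[art_rows], tiling$offset_s[art_rows],
                 rep("ART", length(art_rows)), span = span)
  else interval_set(span = span)
  structure(list(recording = rec, truth = truth, artifacts = artifacts,
                 schedule = tiling, config = config, seed = seed),
            class = "synthetic_eeg")
}

#' @export
print.synthetic_eeg <- function(x, ...) {
  cat("Synthetic EEG (seed ", x$seed, "):\n", sep = "")
  print(x$recording)
  tab <- table(x$schedule$label)
  cat("  schedule: ", paste(names(tab), tab, sep = "x", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Score detected intervals against ground truth
#'
#' For each state, the duration agreement is 100 times the total duration
#' labeled with that state by both scorers, divided by the duration labeled
#' with that state in the truth. Also reports event-level precision and
#' recall, counting a truth (detected) event as matched when same-state
#' detected (truth) intervals cover at least `overlap_frac` of it.
#'
#' @param detected,truth [interval_set()]s covering the same span.
#' @param states states to score (default `AW`, `BS`, `SWD`, `MA`).
#' @param overlap_frac event-match overlap fraction (default 0.5).
#' @return Data frame with one row per state: `state`, `truth_s`,
#'   `detected_s`, `overlap_s`, `agreement_pct`, `precision`, `recall`.
#'   `agreement_pct` is `NA` for states absent from the truth.
#' @export
evaluate_scoring <- function(detected, truth,
                             states = c("AW", "BS", "SWD", "MA"),
                             overlap_frac = 0.5) {
  span_d <- attr(detected, "span")
  span_t <- attr(truth, "span")
  if (is.null(span_d)) span_d <- max(detected$offset_s)
  if (is.null(span_t)) span_t <- max(truth$offset_s)
  if (abs(span_d - span_t) > 1e-3)
    stop("detected and truth interval sets cover different spans")
  out <- data.frame(state = states, truth_s = NA_real_, detected_s = NA_real_,
                    overlap_s = NA_real_, agreement_pct = NA_real_,
                    precision = NA_real_, recall = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(states)) {
    st <- states[i]
    a <- truth[truth$label == st, , drop = FALSE]
    b <- detected[detected$label == st, , drop = FALSE]
    out$truth_s[i] <- sum(a$offset_s - a$onset_s)
    out$detected_s[i] <- sum(b$offset_s - b$onset_s)
    ov <- 0
    ov_a <- numeric(nrow(a)); ov_b <- numeric(nrow(b))
    if (nrow(a) && nrow(b)) {
      for (j in seq_len(nrow(a))) {
        o <- pmax(0, pmin(a$offset_s[j], b$offset_s) -
                       pmax(a$onset_s[j], b$onset_s))
        ov_a[j] <- sum(o)
        ov_b <- ov_b + o
        ov <- ov + sum(o)
      }
    }
    out$overlap_s[i] <- ov
    if (out$truth_s[i] > 0)
      out$agreement_pct[i] <- 100 * ov / out$truth_s[i]
    if (nrow(a))
      out$recall[i] <- mean(ov_a >= overlap_frac * (a$offset_s - a$onset_s))
    if (nrow(b))
      out$precision[i] <- mean(ov_b >= overlap_frac * (b$offset_s - b$onset_s))
  }
  out
}
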