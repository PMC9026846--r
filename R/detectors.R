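#' SWD detector parameters
#'
#' Tunable parameters of the spike-wave discharge detector. The defaults are
#' the method's published operating point: hysteresis multipliers 1.75 (onset)
#' and 1.55 (offset) applied to the recording-mean energy-ratio
#' characteristic, a 3 s characteristic smoothing scale, a minimum event
#' duration of 2 s, a 5 s extrema baseline ending 1 s before onset, and the
#' extrema-criterion bound 6.
#'
#' @param k_up onset threshold multiplier on the recording-mean characteristic.
#' @param k_down offset threshold multiplier (must be below `k_up`).
#' @param tau_s characteristic smoothing scale in seconds; the smoothing
#'   window has total length `tau_window_mult * tau_s` (default total = tau_s,
#'   i.e. a centered +/- tau/2 window; set `tau_window_mult = 3` for a
#'   +/- 1.5 tau window).
#' @param tau_window_mult multiplier converting `tau_s` into the total
#'   smoothing-window length.
#' @param criterion_threshold extrema-criterion bound; a candidate is valid
#'   when `x_max + x_min` strictly exceeds it.
#' @param baseline_window `c(start, end)` offsets in seconds relative to
#'   event onset for the extrema baseline (default `c(-6, -1)`: 5 s ending
#'   1 s pre-onset).
#' @param min_duration_s minimum event duration in seconds.
#' @param energy_window_s integral-energy smoothing window (seconds) applied
#'   to each band energy before the ratio is formed.
#' @param extrema_mode `"mean"` (ratio of mean extremum amplitudes; duration
#'   independent, default) or `"sum"` (ratio of raw amplitude sums).
#' @param extrema_band `c(lo, hi)` Hz zero-phase band-pass applied to the raw
#'   signal before extrema are located (removes DC drift).
#' @return List of class `swd_detector_params`.
#' @export
swd_detector_params <- function(k_up = 1.75, k_down = 1.55,
                                tau_s = 3, tau_window_mult = 1,
                                criterion_threshold = 6,
                                baseline_window = c(-6, -1),
                                min_duration_s = 2,
                                energy_window_s = 0.25,
                                extrema_mode = c("mean", "sum"),
                                extrema_band = c(1, 100)) {
  if (!(k_up > k_down && k_down > 0)) stop("need k_up > k_down > 0")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (min_duration_s < 0) stop("min_duration_s must be >= 0")
  if (length(baseline_window) != 2L || baseline_window[1L] >= baseline_window[2L]
      || baseline_window[2L] > 0)
    stop("baseline_window must be c(start, end) with start < end <= 0")
  structure(list(k_up = k_up, k_down = k_down, tau_s = tau_s,
                 tau_window_mult = tau_window_mult,
                 criterion_threshold = criterion_threshold,
                 baseline_window = baseline_window,
                 min_duration_s = min_duration_s,
                 energy_window_s = energy_window_s,
                 extrema_mode = match.arg(extrema_mode),
                 extrema_band = extrema_band),
            class = "swd_detector_params")
}

#' Sleep/wake detector parameters
#'
#' Parameters of the behavioral-sleep detector operating on the 5-10 Hz
#' sleep-band characteristic. The hysteresis multipliers are calibration
#' defaults tuned on the package's synthetic-EEG suite (the detection
#' principle — elevated 5-10 Hz power marks sleep, segmented by an adaptive
#' hysteresis pair — is fixed; the multipliers are exposed because different
#' preparations may need recalibration).
#'
#' @param bs_up_mult sleep-onset multiplier on the recording-mean sleep-band
#'   characteristic.
#' @param bs_down_mult sleep-offset multiplier (below `bs_up_mult`).
#' @param smooth_window_s smoothing window for the sleep characteristic (s).
#' @param min_episode_s minimum episode length for either state (s); shorter
#'   episodes are merged into the flanking state, except candidate
#'   micro-arousals, which are preserved for [classify_arousals()].
#' @param energy_window_s integral-energy smoothing window (s).
#' @return List of class `sleep_detector_params`.
#' @export
sleep_detector_params <- function(bs_up_mult = 1.15, bs_down_mult = 0.85,
                                  smooth_window_s = 10, min_episode_s = 20,
                                  energy_window_s = 0.25) {
  if (!(bs_up_mult > bs_down_mult && bs_down_mult > 0))
    stop("need bs_up_mult > bs_down_mult > 0")
  if (min_episode_s < 0) stop("min_episode_s must be >= 0")
  structure(list(bs_up_mult = bs_up_mult, bs_down_mult = bs_down_mult,
                 smooth_window_s = smooth_window_s,
                 min_episode_s = min_episode_s,
                 energy_window_s = energy_window_s),
            class = "sleep_detector_params")
}

# ratio with a relative epsilon floor on the denominator (flat-signal safety;
# a relative floor keeps every detector decision amplitude-scale invariant)
.safe_ratio <- function(num, den, rel = 1e-12) {
  floor_ <- rel * max(den, 0)
  out <- num / pmax(den, floor_)
  out[!is.finite(out)] <- 0
  out
}

#' SWD energy-ratio characteristic
#'
#' Per channel, the smoothed spike-band energy divided by the summed smoothed
#' delta- and spindle-band energies; channel values are averaged and the
#' resulting multichannel ratio is smoothed over the detector's `tau_s`
#' scale. During a spike-wave discharge the sharp spikes pump harmonic energy
#' into the 15-18 Hz band while delta/spindle energy stays moderate, so the
#' characteristic rises well above its recording mean.
#'
#' @param rec an [recording()].
#' @param cfg a [wavelet_config()].
#' @param params an [swd_detector_params()].
#' @return Numeric series (one value per sample) of class
#'   `band_energy_series`, strictly positive wherever the denominator is.
#' @export
swd_characteristic <- function(rec, cfg = wavelet_config(),
                               params = swd_detector_params()) {
  fs <- rec$fs
  nch <- ncol(rec$signals)
  acc <- numeric(nrow(rec$signals))
  for (i in seq_len(nch)) {
    be <- .band_energies(rec$signals[, i], fs,
                         cfg$bands[c("delta", "spindle", "spike")],
                         cfg$freq_step, cfg$omega0)
    num <- smooth_energy(be$spike, params$energy_window_s, fs)
    den <- smooth_energy(be$delta, params$energy_window_s, fs) +
           smooth_energy(be$spindle, params$energy_window_s, fs)
    acc <- acc + .safe_ratio(as.numeric(num), as.numeric(den))
  }
  ratio <- structure(acc / nch, fs = fs, class = "band_energy_series")
  smooth_energy(ratio, params$tau_s * params$tau_window_mult, fs)
}

#' Adaptive hysteresis thresholds from a characteristic
#'
#' The onset/offset threshold pair is the recording-wide time average of the
#' characteristic multiplied by `k_up` and `k_down` — i.e. thresholds are
#' individual to each recording/animal, with no manual tuning.
#'
#' @param series numeric characteristic (non-empty).
#' @param k_up,k_down threshold multipliers.
#' @return Named numeric vector `c(up = ..., down = ...)`.
#' @examples
#' compute_thresholds(rep(10, 100))  # c(up = 17.5, down = 15.5)
#' @export
compute_thresholds <- function(series, k_up = 1.75, k_down = 1.55) {
  if (length(series) == 0L) stop("empty characteristic")
  m <- mean(as.numeric(series))
  c(up = k_up * m, down = k_down * m)
}

#' Dual-threshold (hysteresis) event detection
#'
#' An event opens at the first sample where the series rises strictly above
#' `up` and closes at the first subsequent sample where it falls strictly
#' below `down`; an event still open at the end of the series is closed
#' there. Returned intervals are sorted and non-overlapping.
#'
#' @param series numeric series.
#' @param up,down thresholds with `up >= down`.
#' @param fs sampling rate (taken from the series attribute when present).
#' @return Data frame with columns `t_up`, `t_down` (seconds; an interval
#'   covers the in-state samples, so `t_down` is the end of the last
#'   in-state sample).
#' @export
hysteresis_detect <- function(series, up, down, fs = attr(series, "fs")) {
  if (is.null(fs)) stop("fs must be given (or carried by the series)")
  if (up < down) stop("need up >= down")
  v <- as.numeric(series)
  sig <- rep(NA_integer_, length(v))
  sig[v > up] <- 1L
  sig[v < down] <- 0L
  known <- !is.na(sig)
  idx <- cumsum(known)
  st <- c(0L, sig[known])[idx + 1L]       # last-observation-carried-forward
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  data.frame(t_up = (starts[on] - 1L) / fs, t_down = ends[on] / fs)
}

# zero-phase band-pass of all channels, used before extrema location
.extrema_filter <- function(rec, band) {
  ny <- rec$fs / 2
  w <- pmin(pmax(band / ny, 1e-4), 0.999)
  bf <- signal::butter(2, w, type = "pass")
  apply(rec$signals, 2L, function(x) signal::filtfilt(bf, x))
}

# strict local maxima with positive value: indices and values
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(numeric(0))
  i <- which(v[2L:(n - 1L)] > v[1L:(n - 2L)] & v[2L:(n - 1L)] > v[3L:n]) + 1L
  val <- v[i]
  val[val > 0]
}

#' Validate an SWD candidate by its extrema amplitudes
#'
#' Compares the amplitudes of local signal extrema inside the candidate
#' interval against those in a pre-onset baseline window. Per channel, the
#' raw signal is zero-phase band-passed, strict local maxima (and minima, as
#' maxima of the negated signal) are located, and `x_max` (`x_min`) is the
#' ratio of the mean event-extremum amplitude to the mean baseline-extremum
#' amplitude; channel values are averaged. The candidate is valid when
#' `x_max + x_min` strictly exceeds the criterion bound (default 6 — event
#' peaks about three times baseline peaks). High-voltage spike-wave trains
#' pass easily; oscillatory artifacts of near-baseline amplitude fail even
#' when their energy ratio crossed the detection threshold.
#'
#' If the baseline window does not fit inside the recording the validation
#' is skipped and the event is accepted with `validated = FALSE`.
#'
#' @param rec an [recording()].
#' @param event numeric `c(t_up, t_down)` in seconds.
#' @param params an [swd_detector_params()].
#' @param filtered optional pre-filtered signal matrix (internal reuse).
#' @return List with `x_max`, `x_min`, `valid`, `validated`.
#' @export
validate_swd <- function(rec, event, params = swd_detector_params(),
                         filtered = NULL) {
  fs <- rec$fs
  t_up <- event[[1L]]; t_down <- event[[2L]]
  b0 <- t_up + params$baseline_window[1L]
  b1 <- t_up + params$baseline_window[2L]
  if (b0 < 0) {
    return(list(x_max = NA_real_, x_min = NA_real_,
                valid = NA, validated = FALSE))
  }
  if (is.null(filtered)) filtered <- .extrema_filter(rec, params$extrema_band)
  n <- nrow(filtered)
  si <- function(t) min(max(1L, as.integer(floor(t * fs)) + 1L), n)
  ev_idx <- si(t_up):si(t_down)
  bl_idx <- si(b0):si(b1)
  agg <- if (params$extrema_mode == "mean") {
    function(v) if (length(v)) mean(v) else 0
  } else {
    function(v) sum(v)
  }
  xmax_ch <- xmin_ch <- numeric(ncol(filtered))
  for (i in seq_len(ncol(filtered))) {
    v <- filtered[, i]
    scale_floor <- 1e-12 * max(abs(v), 0)
    ev_max <- agg(.local_maxima(v[ev_idx]))
    bl_max <- agg(.local_maxima(v[bl_idx]))
    ev_min <- agg(.local_maxima(-v[ev_idx]))
    bl_min <- agg(.local_maxima(-v[bl_idx]))
    xmax_ch[i] <- ev_max / max(bl_max, scale_floor)
    xmin_ch[i] <- ev_min / max(bl_min, scale_floor)
    if (!is.finite(xmax_ch[i])) xmax_ch[i] <- 0
    if (!is.finite(xmin_ch[i])) xmin_ch[i] <- 0
  }
  x_max <- mean(xmax_ch); x_min <- mean(xmin_ch)
  list(x_max = x_max, x_min = x_min,
       valid = (x_max + x_min) > params$criterion_threshold,
       validated = TRUE)
}

#' Detect spike-wave discharges
#'
#' Full SWD pipeline: energy-ratio characteristic, per-recording adaptive
#' thresholds, hysteresis segmentation, minimum-duration filter, and extrema
#' validation of each candidate. Only candidates passing the extrema
#' criterion (or accepted unvalidated because their baseline window precedes
#' the recording) are returned, sorted and non-overlapping.
#'
#' @param rec an [recording()].
#' @param cfg a [wavelet_config()].
#' @param params an [swd_detector_params()].
#' @param keep_rejected if TRUE, also return candidates that failed
#'   validation (flagged `valid = FALSE`).
#' @return Data frame of class `swd_events` with columns `t_up`, `t_down`,
#'   `duration_s`, `x_max`, `x_min`, `valid`, `validated`; thresholds in
#'   attribute `thresholds`.
#' @export
detect_swd <- function(rec, cfg = wavelet_config(),
                       params = swd_detector_params(),
                       keep_rejected = FALSE) {
  char <- swd_characteristic(rec, cfg, params)
  thr <- compute_thresholds(char, params$k_up, params$k_down)
  cand <- hysteresis_detect(char, thr[["up"]], thr[["down"]], fs = rec$fs)
  cand <- cand[cand$t_down - cand$t_up >= params$min_duration_s, , drop = FALSE]
  filtered <- if (nrow(cand)) .extrema_filter(rec, params$extrema_band)
  out <- data.frame(t_up = numeric(0), t_down = numeric(0),
                    duration_s = numeric(0), x_max = numeric(0),
                    x_min = numeric(0), valid = logical(0),
                    validated = logical(0))
  for (i in seq_len(nrow(cand))) {
    v <- validate_swd(rec, c(cand$t_up[i], cand$t_down[i]), params, filtered)
    out <- rbind(out, data.frame(t_up = cand$t_up[i], t_down = cand$t_down[i],
                                 duration_s = cand$t_down[i] - cand$t_up[i],
                                 x_max = v$x_max, x_min = v$x_min,
                                 valid = v$valid, validated = v$validated))
  }
  if (!keep_rejected && nrow(out))
    out <- out[is.na(out$valid) | out$valid, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  class(out) <- c("swd_events", "data.frame")
  out
}

#' @export
print.swd_events <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat("SWD events: ", nrow(x), " detected", sep = "")
  if (!is.null(thr))
    cat(" (thresholds up = ", signif(thr[["up"]], 4),
        ", down = ", signif(thr[["down"]], 4), ")", sep = "")
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

# is interval j of a tiling a candidate micro-arousal (protected from the
# short-episode merge)?
.ma_candidates <- function(iv, ma) {
  n <- nrow(iv)
  len <- iv$offset_s - iv$onset_s
  prev_bs <- c(FALSE, iv$label[-n] == "BS" &
                      len[-n] >= ma$min_preceding_sleep_s)
  iv$label == "AW" & len >= ma$min_ma_s & len <= ma$max_ma_s & prev_bs
}

.merge_short_episodes <- function(iv, min_episode_s, protect = NULL) {
  repeat {
    n <- nrow(iv)
    if (n <= 1L) return(iv)
    len <- iv$offset_s - iv$onset_s
    prot <- if (is.null(protect)) rep(FALSE, n) else .ma_candidates(iv, protect)
    short <- which(len < min_episode_s & !prot)
    if (!length(short)) return(iv)
    j <- short[which.min(len[short])]
    iv$label[j] <- if (j > 1L) iv$label[j - 1L] else iv$label[j + 1L]
    iv <- coalesce_intervals(iv)
  }
}

#' Detect behavioral sleep and wakefulness
#'
#' Computes the multichannel sleep-band (5-10 Hz) characteristic — band
#' energy per channel, integral smoothing, channel mean, then smoothing over
#' `smooth_window_s` — and segments it with adaptive hysteresis thresholds
#' (`bs_up_mult`/`bs_down_mult` times the recording-mean characteristic).
#' High-characteristic stretches are labeled `BS`, the complement `AW`, and
#' episodes of either label shorter than `min_episode_s` are merged into the
#' flanking state. Candidate micro-arousals (short wake intrusions with
#' sufficient preceding sleep) are preserved so [classify_arousals()] can
#' resolve them.
#'
#' @param rec an [recording()].
#' @param cfg a [wavelet_config()].
#' @param params a [sleep_detector_params()].
#' @param exclude optional data frame of intervals (columns `t_up`/`t_down`
#'   or `onset_s`/`offset_s`), e.g. detected SWDs, whose samples are excluded
#'   from the characteristic mean. Spike-wave trains carry large 8-10 Hz
#'   power, so leaving them in would inflate the sleep thresholds.
#' @param ma_protect a [microarousal_params()] (or NULL to merge all short
#'   episodes unconditionally).
#' @return An [interval_set()] over labels `AW`/`BS` tiling the recording.
#' @export
detect_sleep_wake <- function(rec, cfg = wavelet_config(),
                              params = sleep_detector_params(),
                              exclude = NULL,
                              ma_protect = microarousal_params()) {
  fs <- rec$fs
  n <- nrow(rec$signals)
  acc <- numeric(n)
  for (i in seq_len(ncol(rec$signals))) {
    be <- .band_energies(rec$signals[, i], fs, cfg$bands["sleep"],
                         cfg$freq_step, cfg$omega0)
    acc <- acc + as.numeric(smooth_energy(be$sleep, params$energy_window_s, fs))
  }
  char <- structure(acc / ncol(rec$signals), fs = fs,
                    class = "band_energy_series")
  char <- smooth_energy(char, params$smooth_window_s, fs)
  mask <- rep(TRUE, n)
  if (!is.null(exclude) && nrow(exclude)) {
    on <- if ("t_up" %in% names(exclude)) exclude$t_up else exclude$onset_s
    off <- if ("t_down" %in% names(exclude)) exclude$t_down else exclude$offset_s
    # pad by half the smoothing window: smoothing spreads excluded-event
    # energy beyond the event bounds, which would inflate the threshold mean
    pad <- params$smooth_window_s / 2 + 1
    for (j in seq_along(on)) {
      lo <- max(1L, as.integer(floor((on[j] - pad) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((off[j] + pad) * fs)))
      if (hi >= lo) mask[lo:hi] <- FALSE
    }
  }
  m <- mean(char[mask])
  up <- params$bs_up_mult * m
  down <- params$bs_down_mult * m
  bs <- hysteresis_detect(char, up, down, fs = fs)
  span <- n / fs
  if (nrow(bs) == 0L) {
    tiling <- interval_set(0, span, "AW", span = span)
  } else {
    bs_iv <- interval_set(bs$t_up, bs$t_down, rep("BS", nrow(bs)), span = span)
    aw_iv <- complement_intervals(bs_iv, span, label = "AW")
    tiling <- interval_set(c(bs_iv$onset_s, aw_iv$onset_s),
                           c(bs_iv$offset_s, aw_iv$offset_s),
                           c(bs_iv$label, aw_iv$label), span = span)
  }
  tiling <- .merge_short_episodes(coalesce_intervals(tiling),
                                  params$min_episode_s, protect = ma_protect)
  attr(tiling, "thresholds") <- c(up = up, down = down)
  tiling
}
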