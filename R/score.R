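#' Score vigilance states and spike-wave discharges in a recording
#'
#' The package's main entry point: runs the full automatic scoring pipeline
#' on a multichannel EEG recording and returns a classed result holding the
#' four-state hypnogram and the SWD event table.
#'
#' Pipeline: (1) SWD detection — Morlet-wavelet energy-ratio characteristic,
#' per-recording adaptive hysteresis thresholds, minimum duration, extrema
#' validation; (2) sleep/wake detection on the 5-10 Hz sleep-band
#' characteristic, with detected SWD samples excluded from the adaptive
#' threshold baseline; (3) SWD intervals overlaid on the sleep/wake tiling
#' (SWD takes precedence — discharges are a distinct state, not sleep);
#' (4) micro-arousal classification, turning qualifying brief wake
#' intrusions into `MA` and absorbing sub-scorable wake fragments.
#'
#' @param rec an [recording()].
#' @param wavelet a [wavelet_config()].
#' @param swd an [swd_detector_params()].
#' @param sleep a [sleep_detector_params()].
#' @param ma a [microarousal_params()].
#' @return Object of class `vigilance_scoring`: a list with `hypnogram`
#'   (an [interval_set()] over `AW`/`BS`/`SWD`/`MA` tiling the recording),
#'   `swd_events` (the validated event table with `x_max`/`x_min`),
#'   `thresholds` (named vector `sw_up`, `sw_down`, `bs_up`, `bs_down`),
#'   `params`, `fs`, `duration_s`, `channel_labels`, `start_time`.
#' @examples
#' \donttest{
#' sim <- simulate_eeg(simulation_config(duration_s = 300, n_swd = c(2, 2),
#'                                       wake_mean_s = 90, nrem_mean_s = 150))
#' sc <- score_vigilance(sim$recording)
#' summary(sc)
#' }
#' @seealso [detect_swd()], [detect_sleep_wake()], [classify_arousals()],
#'   [compute_metrics()], [evaluate_scoring()]
#' @export
score_vigilance <- function(rec, wavelet = wavelet_config(),
                            swd = swd_detector_params(),
                            sleep = sleep_detector_params(),
                            ma = microarousal_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- detect_swd(rec, wavelet, swd)
  tiling <- detect_sleep_wake(rec, wavelet, sleep, exclude = events,
                              ma_protect = ma)
  bs_thr <- attr(tiling, "thresholds")
  if (nrow(events)) {
    ev <- data.frame(onset_s = events$t_up, offset_s = events$t_down)
    tiling <- overlay_intervals(tiling, ev, "SWD")
  }
  hyp <- classify_arousals(tiling, ma)
  sw_thr <- attr(events, "thresholds")
  structure(list(hypnogram = hyp, swd_events = events,
                 thresholds = c(sw_up = unname(sw_thr[["up"]]),
                                sw_down = unname(sw_thr[["down"]]),
                                bs_up = unname(bs_thr[["up"]]),
                                bs_down = unname(bs_thr[["down"]])),
                 params = list(wavelet = wavelet, swd = swd, sleep = sleep,
                               ma = ma),
                 fs = rec$fs, duration_s = rec$duration_s,
                 channel_labels = rec$channel_labels,
                 start_time = rec$start_time),
            class = "vigilance_scoring")
}

#' @export
print.vigilance_scoring <- function(x, ...) {
  cat("Vigilance scoring of ", round(x$duration_s, 1), " s, ",
      length(x$channel_labels), "-channel EEG @ ", x$fs, " Hz\n", sep = "")
  tab <- tapply(x$hypnogram$duration_s, x$hypnogram$label, sum)
  for (lab in c("AW", "BS", "SWD", "MA")) {
    d <- if (lab %in% names(tab)) tab[[lab]] else 0
    cat(sprintf("  %-3s %8.1f s (%5.1f%%), %d episode(s)\n", lab, d,
                100 * d / x$duration_s, sum(x$hypnogram$label == lab)))
  }
  cat(sprintf("  SWD events: %d valid; thresholds sw = %.3g/%.3g, bs = %.3g/%.3g\n",
              nrow(x$swd_events), x$thresholds[["sw_up"]],
              x$thresholds[["sw_down"]], x$thresholds[["bs_up"]],
              x$thresholds[["bs_down"]]))
  invisible(x)
}

#' Summarize a vigilance scoring
#'
#' Computes whole-recording sleep metrics (and per-window metrics when the
#' recording has a wall-clock start time covering the dark-phase windows).
#'
#' @param object a `vigilance_scoring`.
#' @param ... unused.
#' @return A `summary.vigilance_scoring` list with the scoring, the
#'   whole-recording [compute_metrics()] row and any dark-phase window rows.
#' @export
summary.vigilance_scoring <- function(object, ...) {
  overall <- compute_metrics(object$hypnogram, c(0, object$duration_s),
                             name = "whole_recording")
  windows <- NULL
  if (!is.null(object$start_time)) {
    w <- tryCatch(
      suppressWarnings(dark_phase_windows(object$start_time,
                                          object$duration_s)),
      error = function(e) NULL)
    if (!is.null(w) && nrow(w)) {
      rows <- lapply(seq_len(nrow(w)), function(i)
        compute_metrics(object$hypnogram, c(w$start_s[i], w$end_s[i]),
                        name = w$name[i]))
      windows <- do.call(rbind, rows)
    }
  }
  structure(list(scoring = object, overall = overall, windows = windows),
            class = "summary.vigilance_scoring")
}

#' @export
print.summary.vigilance_scoring <- function(x, ...) {
  print(x$scoring)
  print(x$overall)
  if (!is.null(x$windows)) {
    cat("Dark-phase windows:\n")
    print.data.frame(x$windows, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a scored hypnogram
#'
#' Step plot of the state sequence over time, with SWD events marked.
#'
#' @param x a `vigilance_scoring`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vigilance_scoring <- function(x, ...) {
  lv <- c("AW", "MA", "BS", "SWD")
  h <- x$hypnogram
  y <- match(h$label, lv)
  graphics::plot(NA, xlim = c(0, x$duration_s), ylim = c(0.5, 4.5),
                 yaxt = "n", xlab = "time (s)", ylab = "",
                 main = "Hypnogram", ...)
  graphics::axis(2, at = seq_along(lv), labels = lv, las = 1)
  graphics::segments(h$onset_s, y, h$offset_s, y, lwd = 3,
                     col = c("goldenrod", "orange", "forestgreen",
                             "firebrick")[y])
  graphics::segments(h$onset_s[-1L], y[-nrow(h)], h$onset_s[-1L], y[-1L],
                     col = "grey60")
  invisible(x)
}
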