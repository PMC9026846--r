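# A sleep episode is a maximal run of temporally contiguous non-wake
# intervals containing at least one BS stretch: discharges and
# micro-arousals interrupt sleep but do not terminate the episode
# (otherwise every discharge would split an episode and the fragmentation
# index would scale with seizure rate instead of sleep architecture).
.count_sleep_episodes <- function(clip, tol = 1e-6) {
  if (nrow(clip) == 0L) return(0L)
  clip <- clip[order(clip$onset_s), , drop = FALSE]
  n <- 0L
  in_ep <- FALSE
  has_bs <- FALSE
  prev_off <- -Inf
  for (i in seq_len(nrow(clip))) {
    sleepish <- clip$label[i] %in% c("BS", "SWD", "MA")
    contiguous <- clip$onset_s[i] <= prev_off + tol
    if (!sleepish || !contiguous) {
      if (in_ep && has_bs) n <- n + 1L
      in_ep <- FALSE
      has_bs <- FALSE
    }
    if (sleepish) {
      in_ep <- TRUE
      if (clip$label[i] == "BS") has_bs <- TRUE
    }
    prev_off <- clip$offset_s[i]
  }
  if (in_ep && has_bs) n <- n + 1L
  n
}

#' Sleep and seizure metrics over an analysis window
#'
#' Clips a state tiling to an analysis window and computes the descriptive
#' metrics used for sleep-fragmentation analysis: per-hour SWD and sleep
#' episode counts, total sleep and micro-arousal durations, percent time
#' asleep, and the sleep fragmentation index (SFI), defined as the number of
#' sleep episodes divided by the total sleep duration in hours. A sleep
#' episode is a maximal sleep bout: spike-wave discharges and micro-arousals
#' interrupt it without terminating it, while wakefulness (or a gap) ends
#' it. Episodes straddling a window boundary count once per window they
#' intersect, with clipped durations, so duration totals are additive across
#' disjoint windows.
#'
#' @param states an [interval_set()] tiling the recording (labels among
#'   `AW`, `BS`, `SWD`, `MA`).
#' @param window `c(start_s, end_s)` in recording-relative seconds.
#' @param name optional window name carried into the result.
#' @return One-row data frame of class `sleep_metrics` with columns
#'   `window_start_s`, `window_end_s`, `window_name`, `n_swd`, `n_swd_per_h`,
#'   `n_bs_episodes`, `n_bs_episodes_per_h`, `total_bs_s`, `pct_bs`,
#'   `n_ma`, `n_ma_per_h`, `total_ma_s`, `sfi`. `sfi` is `NA` when the
#'   window contains no sleep (undefined, not zero).
#' @examples
#' s <- interval_set(c(0, 3600), c(3600, 7200), c("BS", "AW"), span = 7200)
#' compute_metrics(s, c(0, 7200))
#' @export
compute_metrics <- function(states, window, name = NA_character_) {
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("window must be c(start_s, end_s) with start < end")
  w0 <- window[1L]; w1 <- window[2L]
  hours <- (w1 - w0) / 3600
  clip <- states[states$offset_s > w0 & states$onset_s < w1, , drop = FALSE]
  clip$onset_s <- pmax(clip$onset_s, w0)
  clip$offset_s <- pmin(clip$offset_s, w1)
  clip$duration_s <- clip$offset_s - clip$onset_s
  clip <- clip[clip$duration_s > 0, , drop = FALSE]
  cnt <- function(lab) sum(clip$label == lab)
  tot <- function(lab) sum(clip$duration_s[clip$label == lab])
  n_bs <- .count_sleep_episodes(clip)
  total_bs <- tot("BS")
  out <- data.frame(
    window_start_s = w0, window_end_s = w1, window_name = name,
    n_swd = cnt("SWD"), n_swd_per_h = cnt("SWD") / hours,
    n_bs_episodes = n_bs, n_bs_episodes_per_h = n_bs / hours,
    total_bs_s = total_bs, pct_bs = 100 * total_bs / (w1 - w0),
    n_ma = cnt("MA"), n_ma_per_h = cnt("MA") / hours,
    total_ma_s = tot("MA"),
    sfi = if (total_bs > 0) n_bs / (total_bs / 3600) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("sleep_metrics", "data.frame")
  out
}

#' Dark-phase analysis windows from a wall-clock start time
#'
#' Maps the two standard dark-phase analysis windows — the beginning of the
#' dark phase (21:00-24:00) and its end (03:00-06:00) — into
#' recording-relative seconds. A window only partly covered by the recording
#' is clipped (with a warning); a window not covered at all is omitted (with
#' a warning).
#'
#' @param start_time recording start as seconds since midnight (as stored on
#'   an [recording()]), or a `"HH:MM"`/`"HH:MM:SS"` string.
#' @param duration_s recording length in seconds.
#' @return Data frame with columns `name`, `start_s`, `end_s`
#'   (recording-relative).
#' @examples
#' dark_phase_windows("20:00", 12 * 3600)
#' @export
dark_phase_windows <- function(start_time, duration_s) {
  if (is.null(start_time))
    stop("recording has no start_time; supply explicit window offsets instead")
  if (is.character(start_time)) {
    p <- as.integer(strsplit(start_time, ":", fixed = TRUE)[[1L]])
    start_time <- p[1L] * 3600 + ifelse(length(p) > 1L, p[2L] * 60, 0) +
      ifelse(length(p) > 2L, p[3L], 0)
  }
  clock <- list(dark_begin = c(21, 24) * 3600, dark_end = c(3, 6) * 3600)
  out <- data.frame(name = character(0), start_s = numeric(0),
                    end_s = numeric(0), stringsAsFactors = FALSE)
  for (nm in names(clock)) {
    hit <- FALSE
    for (day in 0:ceiling(duration_s / 86400)) {
      s <- clock[[nm]][1L] + day * 86400 - start_time
      e <- clock[[nm]][2L] + day * 86400 - start_time
      s_clip <- max(s, 0); e_clip <- min(e, duration_s)
      if (e_clip > s_clip) {
        if (s_clip > s || e_clip < e)
          warning("window '", nm, "' only partly covered by the recording; ",
                  "clipped", call. = FALSE)
        out <- rbind(out, data.frame(name = nm, start_s = s_clip,
                                     end_s = e_clip, stringsAsFactors = FALSE))
        hit <- TRUE
      }
    }
    if (!hit)
      warning("recording does not span window '", nm, "'; omitted",
              call. = FALSE)
  }
  out
}

#' Epi-phenotype cut-offs
#'
#' Rate cut-offs (SWDs per hour) for the longitudinal severity grouping in
#' [classify_epiphenotype()]. The published grouping is descriptive, not a
#' printed numeric rule, so these cut-offs are explicitly heuristic and
#' configurable.
#'
#' @param minor_max maximum early-age rate compatible with "minor" (SWDs
#'   essentially absent before the oldest age).
#' @param mild_max_early maximum earliest-age rate for "mild" (few SWDs early,
#'   then progressive increase).
#' @param severe_min_early minimum earliest-age rate for "severe" (already
#'   frequent SWDs at the youngest age).
#' @return Named list of cut-offs.
#' @export
epiphenotype_cutoffs <- function(minor_max = 0.5, mild_max_early = 3,
                                 severe_min_early = 5) {
  list(minor_max = minor_max, mild_max_early = mild_max_early,
       severe_min_early = severe_min_early)
}

#' Classify the longitudinal epi-phenotype from SWD rates
#'
#' Rule-based severity grouping of a spike-wave epilepsy trajectory from
#' SWD rates at successive ages (months):
#' \itemize{
#'   \item `none`: no SWDs at any age (non-epileptic; excluded phenotype).
#'   \item `minor`: SWDs essentially absent at the two younger ages
#'     (below `minor_max`) and present at the oldest.
#'   \item `mild`: few SWDs at the youngest age (below `mild_max_early`)
#'     with a progressive increase across ages.
#'   \item `severe`: already frequent SWDs at the youngest age
#'     (at least `severe_min_early`).
#'   \item `indeterminate`: no rule applies or a required age is missing.
#' }
#'
#' @param rates named numeric vector of SWDs/hour; names are ages in months
#'   (e.g. `c("5" = 0.9, "7" = 5.2, "9" = 9.5)`).
#' @param cutoffs an [epiphenotype_cutoffs()] list.
#' @return One of `"none"`, `"minor"`, `"mild"`, `"severe"`,
#'   `"indeterminate"`.
#' @examples
#' classify_epiphenotype(c("5" = 0, "7" = 0, "9" = 5.3))    # minor
#' classify_epiphenotype(c("5" = 0.9, "7" = 5.2, "9" = 9.5)) # mild
#' classify_epiphenotype(c("5" = 8.7, "7" = 3.5, "9" = 9.3)) # severe
#' @export
classify_epiphenotype <- function(rates, cutoffs = epiphenotype_cutoffs()) {
  if (length(rates) < 1L) stop("need rates for at least one age")
  if (all(rates == 0)) return("none")
  ages <- suppressWarnings(as.numeric(names(rates)))
  if (anyNA(ages)) stop("rates must be named by age in months")
  rates <- rates[order(ages)]
  if (length(rates) < 3L) return("indeterminate")
  r <- as.numeric(rates)
  early <- r[1L]; mid <- r[2L]; late <- r[length(r)]
  if (early < cutoffs$minor_max && mid < cutoffs$minor_max && late > 0)
    return("minor")
  if (early < cutoffs$mild_max_early && all(diff(r) > 0))
    return("mild")
  if (early >= cutoffs$severe_min_early)
    return("severe")
  "indeterminate"
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat("Sleep metrics for window [", x$window_start_s, ", ", x$window_end_s,
      "] s", if (!is.na(x$window_name)) paste0(" (", x$window_name, ")"),
      ":\n", sep = "")
  cat(sprintf("  SWDs: %d (%.2f/h)   sleep episodes: %d (%.2f/h)\n",
              x$n_swd, x$n_swd_per_h, x$n_bs_episodes, x$n_bs_episodes_per_h))
  cat(sprintf("  sleep: %.1f s (%.1f%% of window)   micro-arousals: %d, %.1f s\n",
              x$total_bs_s, x$pct_bs, x$n_ma, x$total_ma_s))
  cat("  SFI: ", if (is.na(x$sfi)) "undefined (no sleep in window)"
                 else sprintf("%.2f episodes per hour of sleep", x$sfi),
      "\n", sep = "")
  invisible(x)
}
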