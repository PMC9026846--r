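#' Micro-arousal classification parameters
#'
#' A micro-arousal is a brief waking intrusion into sleep: a wake episode of
#' 3-15 s immediately preceded by at least 10 s of uninterrupted behavioral
#' sleep and followed by sleep. Wake episodes longer than 15 s count as
#' wakefulness proper.
#'
#' @param min_ma_s minimum micro-arousal length (s).
#' @param max_ma_s maximum micro-arousal length (s).
#' @param min_preceding_sleep_s required uninterrupted sleep before (s). A
#'   spike-wave discharge interrupting the sleep run resets this requirement
#'   (SWD is not sleep).
#' @param min_following_sleep_s minimum sleep required after the candidate
#'   (s); guards against labeling a terminal awakening truncated by the
#'   recording end as a micro-arousal.
#' @param absorb_short if TRUE (default), wake fragments shorter than
#'   `min_ma_s` flanked by sleep on both sides are absorbed into sleep
#'   (below the floor of a scorable arousal).
#' @return List of class `microarousal_params`.
#' @export
microarousal_params <- function(min_ma_s = 3, max_ma_s = 15,
                                min_preceding_sleep_s = 10,
                                min_following_sleep_s = 1,
                                absorb_short = TRUE) {
  if (!(min_ma_s > 0 && min_ma_s < max_ma_s))
    stop("need 0 < min_ma_s < max_ma_s")
  if (min_preceding_sleep_s <= 0)
    stop("min_preceding_sleep_s must be positive")
  structure(list(min_ma_s = min_ma_s, max_ma_s = max_ma_s,
                 min_preceding_sleep_s = min_preceding_sleep_s,
                 min_following_sleep_s = min_following_sleep_s,
                 absorb_short = absorb_short),
            class = "microarousal_params")
}

#' Identify micro-arousals in a state tiling
#'
#' Relabels qualifying wake episodes as micro-arousals (`MA`) in a hypnogram
#' over `{AW, BS, SWD}`: an `AW` interval whose length lies in
#' `[min_ma_s, max_ma_s]`, immediately preceded by a `BS` interval of at
#' least `min_preceding_sleep_s` and immediately followed by `BS`, becomes
#' `MA`. Wake fragments shorter than `min_ma_s` flanked by `BS` are absorbed
#' into sleep; all other `AW` intervals are unchanged. The operation is
#' idempotent and preserves the tiling.
#'
#' @param states an [interval_set()] tiling the recording, labels among
#'   `AW`, `BS`, `SWD`.
#' @param params a [microarousal_params()].
#' @return An [interval_set()] over `{AW, BS, SWD, MA}`.
#' @examples
#' s <- interval_set(c(0, 30, 40), c(30, 40, 60), c("BS", "AW", "BS"),
#'                   span = 60)
#' classify_arousals(s)  # the 10 s wake intrusion becomes MA
#' @export
classify_arousals <- function(states, params = microarousal_params()) {
  span <- attr(states, "span")
  if (is.null(span)) span <- max(states$offset_s)
  if (!is_tiling(states, span))
    stop("classify_arousals needs a state tiling (no gaps or overlaps)")
  iv <- coalesce_intervals(states)
  if (params$absorb_short) {
    repeat {
      n <- nrow(iv)
      len <- iv$offset_s - iv$onset_s
      frag <- which(iv$label == "AW" & len < params$min_ma_s &
                      c(FALSE, iv$label[-n] == "BS") &
                      c(iv$label[-1L] == "BS", FALSE))
      if (!length(frag)) break
      iv$label[frag[1L]] <- "BS"
      iv <- coalesce_intervals(iv)
    }
  }
  n <- nrow(iv)
  len <- iv$offset_s - iv$onset_s
  prev_ok <- c(FALSE, iv$label[-n] == "BS" &
                      len[-n] >= params$min_preceding_sleep_s)
  next_ok <- c(iv$label[-1L] == "BS" &
                 len[-1L] >= params$min_following_sleep_s, FALSE)
  ma <- iv$label == "AW" & len >= params$min_ma_s & len <= params$max_ma_s &
    prev_ok & next_ok
  iv$label[ma] <- "MA"
  as_interval_set(iv, span = span)
}
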