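#' Wavelet analysis configuration
#'
#' Parameters of the Morlet continuous wavelet transform (CWT) used by the
#' detectors. With central parameter `omega0 = 2*pi` the wavelet scale maps
#' onto the ordinary Fourier frequency in Hz, so frequency bands can be
#' specified directly. The four default bands are the ones the detectors
#' operate on:
#' \describe{
#'   \item{`delta` (2.5-4.5 Hz)}{upper delta; SWD-ratio denominator.}
#'   \item{`spindle` (10.5-12.5 Hz)}{sleep-spindle/sigma; SWD-ratio denominator.}
#'   \item{`spike` (15-18 Hz)}{spike-harmonic band; SWD-ratio numerator.
#'     The sharp spike of each spike-wave complex carries harmonics here.}
#'   \item{`sleep` (5-10 Hz)}{mid-frequency band whose elevated power marks
#'     behavioral sleep in this preparation.}
#' }
#'
#' @param omega0 Morlet central parameter (dimensionless), default `2*pi`.
#' @param bands named list of `c(lo, hi)` frequency intervals in Hz.
#' @param freq_step spacing of the frequency grid within each band (Hz).
#'   The default 0.25 Hz puts at least 8 grid points in the narrowest band.
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(omega0 = 2 * pi,
                           bands = list(delta   = c(2.5, 4.5),
                                        spindle = c(10.5, 12.5),
                                        spike   = c(15, 18),
                                        sleep   = c(5, 10)),
                           freq_step = 0.25) {
  if (omega0 <= 0) stop("omega0 must be positive")
  if (freq_step <= 0) stop("freq_step must be positive")
  for (b in bands) {
    if (length(b) != 2L || b[1L] >= b[2L])
      stop("each band must be c(lo, hi) with lo < hi")
  }
  if (freq_step > min(vapply(bands, diff, 1)))
    stop("freq_step must not exceed the narrowest band width")
  structure(list(omega0 = omega0, bands = bands, freq_step = freq_step),
            class = "wavelet_config")
}

#' Frequency grid covering a band
#'
#' @param band `c(lo, hi)` in Hz.
#' @param freq_step grid spacing in Hz.
#' @return Numeric vector of analysis frequencies.
#' @export
band_freqs <- function(band, freq_step) seq(band[1L], band[2L], by = freq_step)

# Fourier-domain Morlet kernel at one frequency, L2 (unit-energy) normalized.
# Scale follows the standard scale<->frequency relation for the Morlet wavelet.
.cwt_kernel_hat <- function(nfft, fs, f, omega0) {
  s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)
  k <- seq_len(nfft) - 1L
  pos <- k <= nfft / 2
  w <- 2 * pi * fs * k / nfft
  H <- numeric(nfft)
  H[pos] <- sqrt(2 * pi * s * fs) * pi^(-0.25) *
    exp(-0.5 * (s * w[pos] - omega0)^2)
  H
}

#' Morlet continuous wavelet transform
#'
#' Computes CWT coefficients of one channel at the requested analysis
#' frequencies, by FFT convolution with an L2-normalized analytic Morlet
#' wavelet. One coefficient per sample per frequency.
#'
#' @param rec an [recording()] object (or a plain numeric vector, in which
#'   case `fs` must be given).
#' @param channel channel label or index (default first channel).
#' @param freqs numeric vector of analysis frequencies in Hz; all must lie
#'   strictly inside `(0, fs/2)`.
#' @param cfg a [wavelet_config()] (supplies `omega0`).
#' @param fs sampling rate, only when `rec` is a plain vector.
#' @return Complex matrix (`length(freqs)` x n samples) with attribute
#'   `freqs`. Coefficients within about one wavelet e-folding time of the
#'   recording edges are computed from zero-padded data and are edge-affected.
#' @examples
#' x <- sin(2 * pi * 16.5 * seq(0, 2, by = 1/400))
#' w <- morlet_cwt(x, freqs = c(3.5, 16.5), fs = 400)
#' @export
morlet_cwt <- function(rec, channel = 1L, freqs, cfg = wavelet_config(),
                       fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$signals[, channel]
    fs <- rec$fs
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) stop("fs must be given for plain-vector input")
  }
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("analysis frequencies must lie strictly inside (0, fs/2)")
  n <- length(x)
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(complex(real = 0, imaginary = 0), nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    H <- .cwt_kernel_hat(nfft, fs, freqs[i], cfg$omega0)
    out[i, ] <- stats::fft(xf * H, inverse = TRUE)[seq_len(n)] / nfft
  }
  attr(out, "freqs") <- freqs
  attr(out, "fs") <- fs
  out
}

#' Band-limited instantaneous wavelet energy
#'
#' Sums squared coefficient magnitudes over the frequency-grid points inside
#' a band, giving one non-negative energy value per sample.
#'
#' @param coeffs coefficient matrix from [morlet_cwt()] (must carry its
#'   `freqs` attribute).
#' @param band `c(lo, hi)` in Hz; the computed grid must cover it.
#' @return Numeric vector (class `band_energy_series`) with attributes `fs`,
#'   `band` and `smoothed = FALSE`.
#' @export
band_energy <- function(coeffs, band) {
  freqs <- attr(coeffs, "freqs")
  if (is.null(freqs)) stop("coeffs must carry a 'freqs' attribute")
  sel <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(sel)) stop("band outside the computed frequency grid")
  rows <- coeffs[sel, , drop = FALSE]
  e <- colSums(Re(rows)^2 + Im(rows)^2)
  structure(e, fs = attr(coeffs, "fs"), band = band, smoothed = FALSE,
            class = "band_energy_series")
}

#' Window-smoothed energy series
#'
#' Centered moving average over a window of total length `window_s` seconds;
#' windows are truncated at the series edges, so output length equals input
#' length and a constant series is reproduced exactly.
#'
#' @param series numeric vector (e.g. from [band_energy()]).
#' @param window_s total window length in seconds (default 0.25 s, the
#'   integral-energy smoothing used by the detectors).
#' @param fs sampling rate; taken from the series attribute when present.
#' @return Smoothed series of the same length, `smoothed` attribute set.
#' @export
smooth_energy <- function(series, window_s = 0.25, fs = attr(series, "fs")) {
  if (is.null(fs)) stop("fs must be given (or carried by the series)")
  if (window_s <= 0) stop("window_s must be positive")
  k <- as.integer(round(window_s * fs))
  if (k < 2L) stop("degenerate smoothing window: fewer than 2 samples")
  v <- as.numeric(series)
  n <- length(v)
  half_l <- (k - 1L) %/% 2L
  half_r <- k %/% 2L
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(out, fs = fs, band = attr(series, "band"),
            smoothed = TRUE, window_s = window_s,
            class = "band_energy_series")
}

#' @export
print.band_energy_series <- function(x, ...) {
  b <- attr(x, "band")
  cat("Band energy series: ", length(x), " samples @ ", attr(x, "fs"), " Hz",
      if (!is.null(b)) paste0(", band [", b[1L], ", ", b[2L], "] Hz"),
      if (isTRUE(attr(x, "smoothed")))
        paste0(", smoothed over ", attr(x, "window_s"), " s"),
      "\n", sep = "")
  invisible(x)
}

# Fast path used by the detectors: band energies for several bands of one
# channel, accumulating |W|^2 per frequency without storing the coefficient
# matrix (a 1-h recording at 400 Hz would otherwise need ~GB of memory).
.band_energies <- function(x, fs, bands, freq_step, omega0) {
  n <- length(x)
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  lapply(bands, function(b) {
    acc <- numeric(n)
    for (f in band_freqs(b, freq_step)) {
      H <- .cwt_kernel_hat(nfft, fs, f, omega0)
      W <- stats::fft(xf * H, inverse = TRUE)[seq_len(n)] / nfft
      acc <- acc + Re(W)^2 + Im(W)^2
    }
    structure(acc, fs = fs, band = b, smoothed = FALSE,
              class = "band_energy_series")
  })
}
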