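#' Multichannel EEG recording container
#'
#' Holds a signal matrix (one column per channel, amplitudes in source units,
#' typically microvolts), the sampling rate, channel labels and an optional
#' wall-clock start time used for clock-based analysis windows.
#'
#' @param signals numeric matrix (samples x channels) or vector (one channel).
#' @param fs sampling rate in samples/s (must be > 0).
#' @param channel_labels optional character vector of channel names.
#' @param start_time optional wall-clock start time in seconds since midnight.
#' @return An object of class `eeg_recording` with elements `signals`, `fs`,
#'   `duration_s`, `channel_labels`, `start_time`.
#' @examples
#' rec <- recording(matrix(rnorm(800), ncol = 2), fs = 400)
#' rec$duration_s
#' @export
recording <- function(signals, fs, channel_labels = NULL, start_time = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1L)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (ncol(signals) < 1L || nrow(signals) < 1L)
    stop("recording needs at least one channel with at least one sample")
  if (is.null(channel_labels))
    channel_labels <- if (!is.null(colnames(signals))) colnames(signals)
                      else paste0("ch", seq_len(ncol(signals)))
  if (length(channel_labels) != ncol(signals))
    stop("channel_labels length must match the number of channels")
  colnames(signals) <- channel_labels
  structure(list(signals = signals, fs = fs,
                 duration_s = nrow(signals) / fs,
                 channel_labels = channel_labels,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: ", ncol(x$signals), " channel(s) [",
      paste(x$channel_labels, collapse = ", "), "]\n", sep = "")
  cat("  fs = ", x$fs, " Hz, ", nrow(x$signals), " samples, ",
      round(x$duration_s, 3), " s\n", sep = "")
  if (!is.null(x$start_time))
    cat("  starts at ", .fmt_clock(x$start_time), " wall-clock\n", sep = "")
  invisible(x)
}

.fmt_clock <- function(sec) {
  sec <- round(sec) %% 86400
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Read an EEG recording from file
#'
#' Supports EDF/EDF+ continuous recordings and delimited text. The CSV
#' dialect is fixed: comma separator, `.` decimal, one header row of channel
#' labels, one column per channel. CSV carries no sampling rate, so `fs`
#' must be supplied either as an argument or through a YAML/JSON sidecar
#' file `<path>.yaml` / `<path>.json` containing a field `fs`. Signals are
#' never resampled or filtered on read. EDF+ annotation channels are
#' dropped; ground truth travels in separate interval files.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param fs sampling rate for csv input (ignored for EDF).
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  switch(format, edf = .read_edf(path), csv = .read_csv_recording(path, fs))
}

.read_csv_recording <- function(path, fs) {
  if (is.null(fs)) {
    for (side in paste0(path, c(".yaml", ".yml", ".json"))) {
      if (file.exists(side)) {
        cfg <- if (grepl("json$", side)) jsonlite::read_json(side)
               else yaml::read_yaml(side)
        fs <- cfg$fs
        break
      }
    }
  }
  if (is.null(fs))
    stop("sampling rate missing for csv input: pass fs= or provide a ",
         "sidecar <path>.yaml with a field 'fs'")
  # read as character first so a ragged file is a format error, not recycling
  lines <- readLines(path)
  if (length(lines) < 2L) stop("csv recording needs a header row and data")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("format error: ragged csv (rows with differing column counts)")
  m <- matrix(as.numeric(unlist(parts)), ncol = length(header), byrow = TRUE)
  if (anyNA(m)) stop("format error: non-numeric values in csv recording")
  recording(m, fs = fs, channel_labels = trimws(header))
}

#' Write an EEG recording to file
#'
#' CSV output stores amplitudes at full double precision and round-trips
#' through [read_recording()] exactly. EDF output quantizes to the format's
#' 16-bit integers over the observed amplitude range (inherent to EDF).
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (format == "csv") {
    df <- as.data.frame(rec$signals)
    names(df) <- rec$channel_labels
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    .write_edf(rec, path)
  }
  invisible(path)
}

# ---- minimal EDF/EDF+ continuous reader & writer ---------------------------
# EDF: 256-byte fixed-width ASCII header, 256 bytes per signal header block,
# then data records of little-endian int16 samples, signal-by-signal.

.ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .ascii(con, 8)                       # version
  .ascii(con, 80); .ascii(con, 80)     # patient / recording id
  .ascii(con, 8)                       # start date
  start_str <- .ascii(con, 8)          # start time hh.mm.ss
  .ascii(con, 8)                       # header bytes
  .ascii(con, 44)                      # reserved (EDF+C marker, ignored)
  n_rec <- as.integer(.ascii(con, 8))
  rec_dur <- as.numeric(.ascii(con, 8))
  ns <- as.integer(.ascii(con, 4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) .ascii(con, w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (is.na(n_rec) || n_rec < 0)
    stop("format error: EDF with unknown record count not supported")
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) stop("format error: EDF contains only annotation channels")
  if (length(unique(spr[keep])) != 1L)
    stop("format error: channels with differing sampling rates")
  sig <- vector("list", ns)
  for (i in which(keep)) sig[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) < spr[i]) stop("format error: truncated EDF data")
      if (keep[i]) sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- raw
    }
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  m <- vapply(which(keep),
              function(i) pmin[i] + (sig[[i]] - dmin[i]) * gain[i],
              numeric(n_rec * spr[which(keep)[1L]]))
  st <- NULL
  if (grepl("^\\d{2}\\.\\d{2}\\.\\d{2}$", start_str)) {
    p <- as.integer(strsplit(start_str, ".", fixed = TRUE)[[1L]])
    st <- p[1L] * 3600 + p[2L] * 60 + p[3L]
  }
  recording(m, fs = spr[keep][1L] / rec_dur,
            channel_labels = labels[keep], start_time = st)
}

.pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

.write_edf <- function(rec, path) {
  n <- nrow(rec$signals); nc <- ncol(rec$signals); fs <- rec$fs
  # 1 s records when the length divides evenly, else a single record
  if (n %% fs == 0 && fs == round(fs)) {
    rec_dur <- 1; spr <- as.integer(fs); n_rec <- as.integer(n / fs)
  } else {
    rec_dur <- n / fs; spr <- n; n_rec <- 1L
  }
  pmin <- apply(rec$signals, 2L, min); pmax <- apply(rec$signals, 2L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  st <- if (is.null(rec$start_time)) 0 else round(rec$start_time) %% 86400
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X", 80); wr("swdscore", 80)
  wr("01.01.00", 8)
  wr(sprintf("%02d.%02d.%02d", st %/% 3600, (st %% 3600) %/% 60, st %% 60), 8)
  wr(256 + 256 * nc, 8); wr("", 44); wr(n_rec, 8)
  wr(format(rec_dur, digits = 7), 8); wr(nc, 4)
  for (lab in rec$channel_labels) wr(substr(lab, 1, 16), 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(formatC(pmin[i], digits = 7, width = 8), 8)
  for (i in seq_len(nc)) wr(formatC(pmax[i], digits = 7, width = 8), 8)
  for (i in seq_len(nc)) wr(-32768, 8)
  for (i in seq_len(nc)) wr(32767, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(spr, 8)
  for (i in seq_len(nc)) wr("", 32)
  # re-read the header's rounded physical bounds so file scaling is self-consistent
  pmin_h <- as.numeric(formatC(pmin, digits = 7, width = 8))
  pmax_h <- as.numeric(formatC(pmax, digits = 7, width = 8))
  dig <- vapply(seq_len(nc), function(i) {
    v <- round((rec$signals[, i] - pmin_h[i]) / (pmax_h[i] - pmin_h[i]) * 65535 - 32768)
    as.integer(pmin(pmax(v, -32768), 32767))
  }, integer(n))
  dig <- matrix(dig, nrow = n)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nc))
      writeBin(dig[idx, i], con, size = 2L, endian = "little")
  }
  invisible(path)
}
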