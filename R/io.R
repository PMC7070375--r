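#' Read a single-channel signal from CSV
#'
#' Expects a header `time_s,value`. The sampling rate is inferred from the
#' median time step; `t0` is the first time stamp.
#'
#' @param path CSV file path.
#' @return a [timed_signal()].
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("CSV must have columns time_s,value", call. = FALSE)
  }
  if (nrow(df) < 2L) stop_degenerate("need at least two samples")
  dt <- stats::median(diff(df$time_s))
  timed_signal(df$value, sampling_rate = 1 / dt, t0 = df$time_s[1L])
}

#' Write a single-channel signal to CSV
#'
#' Columns `time_s,value`, mirroring [read_signal_csv()].
#'
#' @param x a [timed_signal()] (or [envelope()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  utils::write.csv(data.frame(time_s = signal_times(x), value = x$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth annotations to CSV
#'
#' Columns `event_type,onset_s,peak_s`; event types `S1`, `S2`, `extra`,
#' `R` (R rows carry the peak time only).
#'
#' @param truth a `ground_truth` from [generate_pcg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  df <- rbind(
    data.frame(event_type = "S1", onset_s = truth$s1_onsets, peak_s = truth$s1_peak_times),
    data.frame(event_type = "S2", onset_s = truth$s2_onsets, peak_s = truth$s2_peak_times),
    if (length(truth$extra_event_times))
      data.frame(event_type = "extra", onset_s = NA_real_, peak_s = truth$extra_event_times),
    data.frame(event_type = "R", onset_s = NA_real_, peak_s = truth$r_peak_times)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting uncompressed PCM (8/16/32-bit
#' integer) and IEEE float (32/64-bit) mono data; unknown chunks are
#' skipped. Integer samples are scaled to [-1, 1].
#'
#' @param path WAV file path.
#' @return a [timed_signal()] with `t0 = 0`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file", call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)   # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk", call. = FALSE)
  if (fmt$channels != 1L) stop("only mono WAV supported", call. = FALSE)

  n <- length(data_raw) %/% (fmt$bits / 8)
  samples <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n, size = fmt$bits / 8, endian = "little")
  } else if (fmt$audio_format == 1L) {
    if (fmt$bits == 8L) {
      (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
    } else {
      readBin(data_raw, "integer", n, size = fmt$bits / 8, endian = "little") /
        2^(fmt$bits - 1)
    }
  } else stop("unsupported WAV encoding", call. = FALSE)
  timed_signal(samples, fmt$sample_rate, t0 = 0)
}

#' Write a mono WAV file
#'
#' Writes 16-bit PCM (default; samples are clipped to [-1, 1] and scaled)
#' or 32-bit IEEE float.
#'
#' @param x a [timed_signal()].
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  fs <- round(x$sampling_rate)
  n <- length(x$samples)
  bits <- if (format == "pcm16") 16L else 32L
  bytes <- bits %/% 8L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (format == "pcm16") 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(c(as.integer(bytes), bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    v <- pmax(pmin(x$samples, 1), -1)
    writeBin(as.integer(round(v * 32767)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x$samples), con, 4, endian = "little")
  }
  invisible(path)
}

#' Export a peak series to CSV
#'
#' Columns `time_s,amplitude`.
#'
#' @param peaks a [peak_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(data.frame(time_s = peaks$times, amplitude = peaks$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}
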