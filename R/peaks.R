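#' Ordered series of envelope peaks
#'
#' @param times peak times in seconds, strictly increasing.
#' @param amplitudes peak amplitudes in envelope units.
#' @return object of class `peak_series`; the derived field `deltas` holds
#'   the inter-peak distances `times[i+1] - times[i]` in seconds.
#' @export
peak_series <- function(times = numeric(0), amplitudes = numeric(0)) {
  stopifnot(length(times) == length(amplitudes))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("peak times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), amplitudes = as.numeric(amplitudes),
                 deltas = diff(as.numeric(times))),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks", length(x$times)))
  if (length(x$times) > 1L) {
    cat(sprintf(", min spacing %.3f s", min(x$deltas)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.peak_series <- function(x) length(x$times)

#' Peak-detection configuration
#'
#' The threshold multiplier `n` scales the mean of the envelope over the
#' current analysis segment (peaks must exceed `mean * n` to be kept); which
#' of `n_normal` / `n_high` applies is decided by the heart-rate regime.
#' Defaults are envelope-method specific: the STFT envelope is smoother, so
#' its multipliers are lower.
#'
#' @param n_normal threshold multiplier at normal heart rates.
#' @param n_high threshold multiplier at increased heart rates (> 80 bpm).
#' @param min_separation minimum distance between retained peaks in seconds;
#'   the default 0.150 s approximates the maximal length of a heart sound,
#'   which lets the detector collapse split sounds to one peak.
#' @return a list of class `peak_config`.
#' @export
peak_config <- function(n_normal = 1.9, n_high = 1.3, min_separation = 0.150) {
  stopifnot(n_normal > 0, n_high > 0, min_separation > 0)
  structure(list(n_normal = n_normal, n_high = n_high,
                 min_separation = min_separation),
            class = "peak_config")
}

#' Method-specific default peak configuration
#'
#' HT: `n_normal = 1.9`, `n_high = 1.3`; STFT: `n_normal = 1`,
#' `n_high = 0.6`.
#'
#' @param method `"HT"` or `"STFT"`.
#' @return a [peak_config()].
#' @export
default_peak_config <- function(method = c("HT", "STFT")) {
  method <- match.arg(method)
  if (method == "HT") peak_config(1.9, 1.3) else peak_config(1.0, 0.6)
}

#' Local maxima of an envelope
#'
#' A local maximum is a sample where the gradient (first difference) changes
#' sign from positive to negative; plateau maxima yield their first sample.
#' Signal endpoints are never peaks.
#'
#' @param env an [envelope()] with at least 3 values.
#' @return a [peak_series()].
#' @export
local_maxima <- function(env) {
  v <- env$values
  if (length(v) < 3L) stop_degenerate("envelope too short for peak detection")
  r <- rle(v)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_peak <- logical(m)
  if (m >= 3L) {
    k <- 2L:(m - 1L)
    is_peak[k] <- r$values[k] > r$values[k - 1L] & r$values[k] > r$values[k + 1L]
  }
  idx <- starts[is_peak]
  peak_series(env$t0 + (idx - 1L) / env$sampling_rate, v[idx])
}

#' Amplitude-threshold envelope peaks
#'
#' Keeps peaks whose amplitude is strictly larger than
#' `mean(env$values) * n`, the mean being taken over the full envelope of
#' the current analysis segment.
#'
#' @param peaks a [peak_series()].
#' @param env the [envelope()] the peaks came from.
#' @param n threshold multiplier (> 0).
#' @return the filtered [peak_series()].
#' @export
apply_threshold <- function(peaks, env, n) {
  stopifnot(n > 0)
  keep <- peaks$amplitudes > mean(env$values) * n
  peak_series(peaks$times[keep], peaks$amplitudes[keep])
}

#' Enforce a minimum peak separation
#'
#' Greedy resolution by descending amplitude: the globally largest remaining
#' peak is kept and all peaks strictly closer than `min_separation` to it are
#' suppressed; ties in amplitude are broken in favour of the earlier peak.
#' This implements the rule that only the global maximum within the length
#' of one heart sound survives, collapsing split sounds to a single peak.
#' The operation is idempotent.
#'
#' @param peaks a sorted [peak_series()].
#' @param min_separation minimum allowed spacing in seconds.
#' @return the thinned [peak_series()].
#' @export
enforce_separation <- function(peaks, min_separation = 0.150) {
  n <- length(peaks$times)
  if (n <= 1L) return(peaks)
  ord <- order(-peaks$amplitudes, peaks$times)
  keep <- logical(n)
  blocked <- logical(n)
  for (j in ord) {
    if (blocked[j]) next
    keep[j] <- TRUE
    close_by <- abs(peaks$times - peaks$times[j]) < min_separation
    close_by[j] <- FALSE
    blocked[close_by] <- TRUE
  }
  peak_series(peaks$times[keep], peaks$amplitudes[keep])
}
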