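#' Uniformly sampled waveform
#'
#' The basic container used throughout phonoseg: a numeric sample vector
#' together with its sampling rate and the absolute time of the first sample.
#' PCG audio, the reference ECG and envelope curves are all carried as
#' `timed_signal` objects so that every cross-channel comparison can happen
#' in absolute seconds, regardless of sampling rate.
#'
#' @param samples numeric vector of finite samples.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds from recording start.
#' @return an object of class `timed_signal`.
#' @export
timed_signal <- function(samples, sampling_rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate, t0 = as.numeric(t0)),
    class = "timed_signal"
  )
}

#' @export
print.timed_signal <- function(x, ...) {
  cat(sprintf("<timed_signal> %d samples @ %g Hz, t0 = %.4f s, duration = %.3f s\n",
              length(x$samples), x$sampling_rate, x$t0, signal_duration(x)))
  invisible(x)
}

#' Duration of a timed signal in seconds
#' @param x a `timed_signal`.
#' @return duration in seconds (n / sampling_rate).
#' @export
signal_duration <- function(x) length(x$samples) / x$sampling_rate

#' Sample times of a timed signal
#' @param x a `timed_signal`.
#' @return numeric vector of absolute times, `t0 + (i - 1) / sampling_rate`.
#' @export
signal_times <- function(x) {
  x$t0 + (seq_along(x$samples) - 1L) / x$sampling_rate
}

#' Crop a timed signal to a time interval
#'
#' Keeps the samples whose times fall inside `[from, to]` (inclusive),
#' preserving absolute time in `t0`.
#'
#' @param x a `timed_signal`.
#' @param from,to interval bounds in absolute seconds.
#' @return the cropped `timed_signal`.
#' @export
crop_signal <- function(x, from = -Inf, to = Inf) {
  i0 <- max(1L, ceiling((from - x$t0) * x$sampling_rate - 1e-9) + 1L)
  i1 <- min(length(x$samples), floor((to - x$t0) * x$sampling_rate + 1e-9) + 1L)
  if (i1 < i0) stop("empty crop interval", call. = FALSE)
  timed_signal(x$samples[i0:i1], x$sampling_rate,
               t0 = x$t0 + (i0 - 1L) / x$sampling_rate)
}

#' @export
plot.timed_signal <- function(x, ...) {
  graphics::plot(signal_times(x), x$samples, type = "l",
                 xlab = "time [s]", ylab = "amplitude", ...)
  invisible(x)
}

## internal: degenerate-input error helper with a stable condition class
stop_degenerate <- function(msg) {
  stop(structure(class = c("phonoseg_degenerate_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_estimation_failure <- function(msg) {
  stop(structure(class = c("phonoseg_estimation_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
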