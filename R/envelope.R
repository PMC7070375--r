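#' Envelope container
#'
#' Nonnegative amplitude contour of the PCG, produced either by the
#' analytic-signal (Hilbert) method or by the per-frame maximum of the STFT
#' power spectral density. An envelope is itself a `timed_signal` (its
#' sampling rate differs between methods: equal to the PCG rate for HT, one
#' sample per STFT hop for STFT).
#'
#' @param values nonnegative numeric vector.
#' @param sampling_rate envelope sampling rate in Hz.
#' @param t0 time of the first envelope value in seconds.
#' @param method `"HT"` or `"STFT"`.
#' @return object of classes `envelope` and `timed_signal` (field `values`
#'   aliases `samples`).
#' @export
envelope <- function(values, sampling_rate, t0 = 0, method = c("HT", "STFT")) {
  method <- match.arg(method)
  if (length(values) && any(values < -1e-12)) {
    stop("envelope values must be nonnegative", call. = FALSE)
  }
  out <- timed_signal(pmax(values, 0), sampling_rate, t0)
  out$values <- out$samples
  out$method <- method
  class(out) <- c("envelope", "timed_signal")
  out
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope:%s> %d values @ %g Hz, t0 = %.4f s\n",
              x$method, length(x$values), x$sampling_rate, x$t0))
  invisible(x)
}

#' Hilbert-transform envelope
#'
#' Computes the discrete analytic signal of `x` by the frequency-domain
#' method (zeroing negative frequencies, doubling positive ones) over the
#' whole segment, and returns its magnitude
#' `sqrt(x^2 + H(x)^2)` -- the envelope curve of the PCG. Appropriate for
#' narrowband signals such as heart sounds.
#'
#' @param x a [timed_signal()] (finite, nonempty).
#' @return an [envelope()] with the same length and sampling rate as `x`.
#' @export
hilbert_envelope <- function(x) {
  v <- x$samples
  if (!length(v)) stop_degenerate("empty signal")
  if (any(!is.finite(v))) stop("non-finite samples", call. = FALSE)
  envelope(Mod(analytic_signal(v)), x$sampling_rate, x$t0, method = "HT")
}

## analytic signal via FFT: X(f<0) = 0, X(f>0) doubled, DC (and Nyquist for
## even N) kept
analytic_signal <- function(v) {
  n <- length(v)
  if (n == 1L) return(as.complex(v))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(v) * h, inverse = TRUE) / n
}

#' STFT configuration
#'
#' @param window_len analysis window length in samples (default 128).
#' @param overlap window overlap as a fraction in `[0, 1)` (default
#'   0.96875, i.e. a hop of 4 samples -- 1 ms at 4 kHz).
#' @return a list of class `stft_config`. The window shape is fixed to
#'   Hamming, which suits non-stationary audio such as the PCG.
#' @export
stft_config <- function(window_len = 128, overlap = 0.96875) {
  window_len <- as.integer(window_len)
  stopifnot(window_len >= 2, overlap >= 0, overlap < 1)
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  structure(list(window_len = window_len, overlap = overlap, hop = hop),
            class = "stft_config")
}

#' Short-time Fourier transform (spectrogram)
#'
#' Hamming-windowed frames at a hop of `window_len * (1 - overlap)` samples;
#' power is the squared magnitude of the Fourier coefficients (linear units;
#' any dB scaling is display-only). Frames are centred (frame time = window
#' centre, in absolute seconds) and incomplete frames at the signal edges
#' are dropped rather than zero-padded, so no fabricated low-power frames
#' bias downstream envelope statistics.
#'
#' @param x a [timed_signal()] with at least `window_len` samples.
#' @param cfg an [stft_config()].
#' @return a list of class `spectrogram`: `power` (frames x bins matrix),
#'   `frame_times` (s), `bin_freqs` (Hz), `hop_interval` (s).
#' @export
stft <- function(x, cfg = stft_config()) {
  v <- x$samples
  b <- cfg$window_len
  if (length(v) < b) stop_degenerate("signal shorter than one STFT window")
  hop <- cfg$hop
  starts <- seq.int(1L, length(v) - b + 1L, by = hop)
  w <- as.numeric(signal::hamming(b))
  frames <- matrix(v[outer(0:(b - 1L), starts, "+")], nrow = b) * w
  coefs <- stats::mvfft(frames)
  nbin <- b %/% 2L + 1L
  power <- t(Mod(coefs[seq_len(nbin), , drop = FALSE])^2)
  structure(list(
    power = power,
    frame_times = x$t0 + (starts - 1L + (b - 1L) / 2) / x$sampling_rate,
    bin_freqs = (seq_len(nbin) - 1L) * x$sampling_rate / b,
    hop_interval = hop / x$sampling_rate
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, frame spacing %.4g s\n",
              nrow(x$power), ncol(x$power), x$hop_interval))
  invisible(x)
}

#' STFT envelope
#'
#' Takes, for each time frame, the maximum of the power spectral density
#' over all frequency bins. Heart sounds concentrate spectral power, so the
#' per-frame maximum traces an envelope similar to (but smoother than) the
#' Hilbert envelope.
#'
#' @param spec a [stft()] spectrogram.
#' @return an [envelope()] sampled at one value per hop interval.
#' @export
stft_envelope <- function(spec) {
  if (!nrow(spec$power)) stop_degenerate("empty spectrogram")
  vals <- apply(spec$power, 1L, max)
  envelope(vals, sampling_rate = 1 / spec$hop_interval,
           t0 = spec$frame_times[1L], method = "STFT")
}

#' Extract the PCG envelope by the configured method
#'
#' Convenience front-end: HT dispatches to [hilbert_envelope()], STFT to
#' [stft()] + [stft_envelope()].
#'
#' @param x a [timed_signal()].
#' @param method `"HT"` or `"STFT"`.
#' @param stft_cfg an [stft_config()] (STFT only).
#' @return an [envelope()].
#' @export
extract_envelope <- function(x, method = c("HT", "STFT"), stft_cfg = stft_config()) {
  method <- match.arg(method)
  if (method == "HT") hilbert_envelope(x) else stft_envelope(stft(x, stft_cfg))
}
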