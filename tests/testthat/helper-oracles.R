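# Independent oracles: deliberately naive implementations used only to
# cross-check the package's FFT-based routines on small inputs.

# O(N^2) autocorrelation of the mean-removed vector, normalised at lag 0
direct_acf <- function(v, maxlag) {
  v <- v - mean(v)
  n <- length(v)
  r <- vapply(0:maxlag, function(k) {
    sum(v[seq_len(n - k)] * v[seq_len(n - k) + k])
  }, numeric(1))
  r / r[1L]
}

# discrete Hilbert envelope via explicit circular convolution with the
# kernel that the analytic-signal frequency response implies
direct_hilbert_env <- function(v) {
  n <- length(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  kern <- stats::fft(h, inverse = TRUE) / n   # time-domain kernel
  z <- complex(length.out = n)
  for (t in seq_len(n)) {
    idx <- ((t - seq_len(n)) %% n) + 1L
    z[t] <- sum(v * kern[idx])
  }
  Mod(z)
}

# naive per-frame discrete Fourier sum for the STFT power
naive_stft_power <- function(v, fs, window_len, overlap) {
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  w <- as.numeric(signal::hamming(window_len))
  starts <- seq.int(1L, length(v) - window_len + 1L, by = hop)
  nbin <- window_len %/% 2L + 1L
  p <- matrix(0, length(starts), nbin)
  for (j in seq_along(starts)) {
    fr <- v[starts[j]:(starts[j] + window_len - 1L)] * w
    for (m in seq_len(nbin)) {
      p[j, m] <- Mod(sum(fr * exp(-2i * pi * (m - 1) * (0:(window_len - 1)) / window_len)))^2
    }
  }
  p
}

# quadrature demodulation oracle for the envelope of an AM tone at carrier fc
quadrature_envelope <- function(v, fs, fc) {
  t <- (seq_along(v) - 1) / fs
  i <- v * cos(2 * pi * fc * t)
  q <- v * sin(2 * pi * fc * t)
  lp <- signal::butter(4, (fc / 2) / (fs / 2), type = "low")
  2 * sqrt(as.numeric(signal::filtfilt(lp, i))^2 +
           as.numeric(signal::filtfilt(lp, q))^2)
}

# cardiac timing fixture used by the rule-trace tests: cycle 1 s (60 bpm),
# systole 300 ms, bounds sys [125, 475] ms / dia [525, 875] ms
fixture_timing <- function() derive_bounds(60, 300)

# convenience: synthetic recording + reference ECG
make_recording <- function(...) {
  cfg <- synth_config(...)
  g <- generate_pcg(cfg)
  list(pcg = g$pcg, truth = g$truth, ecg = generate_ecg(g$truth, cfg), cfg = cfg)
}
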