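#' Band-pass filter configuration
#'
#' The analysis band-pass is a cascade of a Butterworth high-pass (cutoff
#' `f_lower`, order `order_hp`) and low-pass (cutoff `f_upper`, order
#' `order_lp`), reflecting that the two sections have distinct orders.
#' Defaults depend on the envelope method in use; see
#' [default_filter_config()].
#'
#' @param f_lower high-pass cutoff in Hz.
#' @param f_upper low-pass cutoff in Hz.
#' @param order_hp,order_lp Butterworth orders (>= 1).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(f_lower = 40, f_upper = 190,
                          order_hp = 4, order_lp = 10) {
  stopifnot(f_lower > 0, f_upper > f_lower, order_hp >= 1, order_lp >= 1)
  structure(list(f_lower = f_lower, f_upper = f_upper,
                 order_hp = as.integer(order_hp), order_lp = as.integer(order_lp)),
            class = "filter_config")
}

#' Method-specific default filter configurations
#'
#' The optimized passbands: 40--190 Hz for the Hilbert-transform envelope and
#' 20--120 Hz for the STFT envelope, with high-pass order 4 and low-pass
#' order 10 for both.
#'
#' @param method `"HT"` or `"STFT"`.
#' @return a [filter_config()].
#' @export
default_filter_config <- function(method = c("HT", "STFT")) {
  method <- match.arg(method)
  if (method == "HT") filter_config(40, 190, 4, 10)
  else filter_config(20, 120, 4, 10)
}

#' Band-pass filter a PCG
#'
#' Applies the high-pass/low-pass Butterworth cascade. `mode = "causal"`
#' filters forward only (real-time semantics; the constant group delay is
#' common to all PCG-derived events and absorbed by the evaluation tolerance
#' window); `mode = "zero-phase"` uses forward-backward filtering for offline
#' analysis.
#'
#' @param pcg a [timed_signal()].
#' @param cfg a [filter_config()].
#' @param mode `"causal"` (default) or `"zero-phase"`.
#' @return the filtered signal, same length, rate and `t0`.
#' @export
bandpass <- function(pcg, cfg = filter_config(), mode = c("causal", "zero-phase")) {
  mode <- match.arg(mode)
  nyq <- pcg$sampling_rate / 2
  if (cfg$f_upper >= nyq) {
    stop("`f_upper` must be below the Nyquist frequency", call. = FALSE)
  }
  hp <- signal::butter(cfg$order_hp, cfg$f_lower / nyq, type = "high")
  lp <- signal::butter(cfg$order_lp, cfg$f_upper / nyq, type = "low")
  apply_f <- if (mode == "causal") {
    function(flt, x) as.numeric(signal::filter(flt, x))
  } else {
    function(flt, x) as.numeric(signal::filtfilt(flt, x))
  }
  y <- apply_f(lp, apply_f(hp, pcg$samples))
  timed_signal(y, pcg$sampling_rate, pcg$t0)
}

#' Segmentation configuration
#'
#' @param discard_prefix seconds discarded from the start of the recording
#'   (the synchronization prefix; default 8 s).
#' @param n_segments number of equal-duration analysis segments (default 5).
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(discard_prefix = 8, n_segments = 5) {
  stopifnot(discard_prefix >= 0, n_segments >= 1)
  structure(list(discard_prefix = discard_prefix,
                 n_segments = as.integer(n_segments)),
            class = "segmentation_config")
}

#' Split a recording into equal analysis segments
#'
#' Drops the first `discard_prefix` seconds and divides the remainder into
#' `n_segments` contiguous, non-overlapping segments of equal length (within
#' one sample). `t0` of each segment preserves absolute time.
#'
#' @param signal a [timed_signal()].
#' @param cfg a [segmentation_config()].
#' @return a list of `timed_signal` segments.
#' @export
segment_signal <- function(signal, cfg = segmentation_config()) {
  fs <- signal$sampling_rate
  n <- length(signal$samples)
  i_start <- round(cfg$discard_prefix * fs) + 1L
  if (i_start > n) stop_degenerate("signal duration must exceed `discard_prefix`")
  idx <- i_start:n
  bounds <- round(seq(0, length(idx), length.out = cfg$n_segments + 1L))
  lapply(seq_len(cfg$n_segments), function(k) {
    sel <- idx[(bounds[k] + 1L):bounds[k + 1L]]
    timed_signal(signal$samples[sel], fs, t0 = signal$t0 + (sel[1L] - 1L) / fs)
  })
}

#' Synchronize a PCG/ECG pair
#'
#' `mode = "knock_artifact"` locates the triple-knock transients present in
#' both channels within the first `search_window` seconds (short-time energy
#' over 50 ms frames, threshold 5 x median frame energy, at least three
#' super-threshold clusters) and aligns the centroids of the first clusters.
#' `mode = "fixed_offset"` shifts the ECG clock by a known `offset`.
#'
#' @param pcg,ecg `timed_signal` pair.
#' @param mode `"knock_artifact"` or `"fixed_offset"`.
#' @param offset known offset in seconds (PCG time minus ECG time); required
#'   for `fixed_offset`.
#' @param search_window seconds from the start of each channel searched for
#'   the knock pattern.
#' @return list with elements `pcg`, `ecg` (time-aligned, cropped to the
#'   common interval) and `offset` (the applied shift in seconds).
#' @export
synchronize <- function(pcg, ecg, mode = c("knock_artifact", "fixed_offset"),
                        offset = NULL, search_window = 8) {
  mode <- match.arg(mode)
  if (!length(pcg$samples) || !length(ecg$samples)) {
    stop_degenerate("both signals must be nonempty")
  }
  if (mode == "fixed_offset") {
    if (is.null(offset)) stop("`offset` required for mode = 'fixed_offset'", call. = FALSE)
  } else {
    cp <- knock_centroid(pcg, search_window)
    ce <- knock_centroid(ecg, search_window)
    offset <- cp - ce
  }
  ecg_shifted <- timed_signal(ecg$samples, ecg$sampling_rate, ecg$t0 + offset)
  from <- max(pcg$t0, ecg_shifted$t0)
  to <- min(pcg$t0 + signal_duration(pcg),
            ecg_shifted$t0 + signal_duration(ecg_shifted))
  list(pcg = crop_signal(pcg, from, to),
       ecg = crop_signal(ecg_shifted, from, to),
       offset = offset)
}

## centroid time of the first knock cluster, or sync-failure error
knock_centroid <- function(x, search_window, frame_len = 0.050) {
  xs <- crop_signal(x, x$t0, x$t0 + search_window)
  fs <- xs$sampling_rate
  flen <- max(1L, round(frame_len * fs))
  nf <- floor(length(xs$samples) / flen)
  if (nf < 3L) stop_estimation_failure("signal too short for knock detection")
  e <- vapply(seq_len(nf), function(k) {
    sum(xs$samples[((k - 1L) * flen + 1L):(k * flen)]^2)
  }, numeric(1))
  ## knocks dwarf heart sounds (~100x the energy), so require both the
  ## 5 x median floor and a share of the strongest frame -- otherwise the
  ## first S1 would masquerade as the first knock
  thr <- max(5 * stats::median(e), 0.3 * max(e))
  hot <- e > thr & e > 0
  if (!any(hot)) stop_estimation_failure("knock pattern not found")
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  clusters <- which(r$values)
  if (length(clusters) < 3L) stop_estimation_failure("knock pattern not found (need >= 3 transients)")
  ## sample-level energy centroid over the first cluster's span (padded by
  ## one frame) -- frame-level centroids would quantize to ~25 ms
  f0 <- starts[clusters[1L]]; f1 <- ends[clusters[1L]]
  i0 <- max(1L, (f0 - 2L) * flen + 1L)
  i1 <- min(length(xs$samples), (f1 + 1L) * flen)
  seg <- xs$samples[i0:i1]^2
  tt <- xs$t0 + (i0:i1 - 1L) / fs
  sum(tt * seg) / sum(seg)
}
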