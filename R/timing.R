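## package-wide timing constants
ACF_SEARCH_WINDOW_S <- 1.5    # lag window after lag 0 searched for the cycle
ACF_MIN_CYCLE_S <- 0.25       # just above the cycle length at the 200 bpm cap
SYS_TOLERANCE_MS <- 175       # 150 ms max sound length + 25 ms systolic SD

#' Analytic timing constants of the classifier
#'
#' Returns the fixed constants of the timing model: the ACF cycle-search
#' window (1.5 s), the implied lower heart-rate bound (60 / 1.5 = 40 bpm)
#' and the systolic tolerance (175 ms, the sum of the 150 ms maximal heart
#' sound duration and the 25 ms standard deviation of the systolic length).
#'
#' @return named list with `acf_search_window_s`, `hr_lower_bound_bpm`,
#'   `sys_tolerance_ms`.
#' @export
timing_constants <- function() {
  list(acf_search_window_s = ACF_SEARCH_WINDOW_S,
       hr_lower_bound_bpm = 60 / ACF_SEARCH_WINDOW_S,
       sys_tolerance_ms = SYS_TOLERANCE_MS)
}

#' Autocorrelation of an envelope
#'
#' Full-signal autocorrelation of the mean-removed envelope, computed by the
#' FFT (Wiener--Khinchin) method and normalised so the lag-0 value is 1.
#' Lags run to half the signal duration by default; [dispatch()] requests a
#' slightly longer range (up to 3.2 s) so that [estimate_cycle()] can check
#' the second harmonic of every candidate cycle. The quasi-periodic envelope
#' produces periodic ACF maxima with decaying amplitude; major maxima mark
#' full-cycle overlap, minor maxima the S1/S2 (systole) offset.
#'
#' @param env an [envelope()] (or any `timed_signal`).
#' @param max_lag_s maximum lag in seconds; default half the duration, and
#'   never more than 80 percent of it (the estimate has too little overlap
#'   beyond that).
#' @return object of class `acf_curve` with `lags` (s), `values`,
#'   `sampling_rate` and `signal_duration`.
#' @export
autocorrelate <- function(env, max_lag_s = NULL) {
  v <- if (!is.null(env$values)) env$values else env$samples
  if (!length(v)) stop_degenerate("empty envelope")
  v <- v - mean(v)
  if (all(abs(v) < 1e-15)) stop_degenerate("constant envelope has no autocorrelation")
  n <- length(v)
  dur <- n / env$sampling_rate
  maxlag <- if (is.null(max_lag_s)) n %/% 2L
            else min(n - 1L, floor(min(max_lag_s, 0.8 * dur) * env$sampling_rate))
  nfft <- stats::nextn(2L * n, 2)
  sp <- stats::fft(c(v, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(sp)^2, inverse = TRUE)) / nfft
  vals <- r[seq_len(maxlag + 1L)] / r[1L]
  structure(list(lags = (0:maxlag) / env$sampling_rate,
                 values = vals,
                 sampling_rate = env$sampling_rate,
                 signal_duration = dur),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("<acf_curve> lags 0..%.3f s (%d points)\n",
              max(x$lags), length(x$lags)))
  invisible(x)
}

## local maxima (plateau -> first sample) of a plain numeric vector
local_max_idx <- function(v) {
  r <- rle(v)
  m <- length(r$values)
  if (m < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 2L:(m - 1L)
  starts[k][r$values[k] > r$values[k - 1L] & r$values[k] > r$values[k + 1L]]
}

#' Estimate the average heart cycle from the ACF
#'
#' The average heart cycle is the distance between the first two major ACF
#' maxima; the second major maximum is found by a global maximum search over
#' the local maxima within 1.5 s of lag after lag 0 (which bounds the
#' detectable heart rate below at 40 bpm). Lags shorter than 0.25 s -- the
#' cycle length just above the 200 bpm upper rate -- are excluded so the
#' lag-0 main lobe and the systole minor maximum at high rates cannot be
#' mistaken for the cycle.
#'
#' On short segments with cycle-to-cycle variation (jitter, split sounds)
#' the raw global maximum is fragile in two ways: the systole minor maximum
#' can narrowly beat the cycle peak, and a sub-multiple of the rate (the
#' 2- or 3-cycle peak) can win when consecutive cycles happen to correlate
#' poorly. The search therefore scores each candidate maximum by the mean
#' of its own value (corrected, with a cap, for the finite-length ACF's
#' triangular decay) and the strongest raw local ACF maximum within ten
#' percent of the candidate lag around its double, and returns the
#' smallest lag whose score reaches 85 percent of the best: a true cycle
#' and its sub-multiples share the same harmonic comb and score alike, so
#' the shortest wins, while the systole minor maximum has no peak at twice
#' its lag and drops out.
#'
#' @param acf an [autocorrelate()] result spanning at least 1.5 s of lag.
#' @return list with `cycle` (ms) and `heart_rate` (bpm).
#' @export
estimate_cycle <- function(acf) {
  if (max(acf$lags) < ACF_SEARCH_WINDOW_S) {
    stop_degenerate("ACF must span at least 1.5 s of lag")
  }
  dur <- if (!is.null(acf$signal_duration)) acf$signal_duration else 2 * max(acf$lags)
  idx <- local_max_idx(acf$values)
  idx <- idx[acf$lags[idx] >= ACF_MIN_CYCLE_S &
             acf$lags[idx] <= ACF_SEARCH_WINDOW_S &
             acf$values[idx] >= 0.05]       # ignore numerically tiny ripples
  if (!length(idx)) {
    stop_estimation_failure("no cycle maximum within the 1.5 s ACF search window (heart rate below 40 bpm or aperiodic signal)")
  }
  all_max <- local_max_idx(acf$values)
  m_lag <- acf$lags[all_max]
  m_val <- acf$values[all_max]
  lag <- acf$lags[idx]
  ## candidate value corrected (capped) for triangular decay; the harmonic
  ## term is left raw -- its natural decay is what makes the true cycle beat
  ## its own sub-multiples under the smallest-lag rule
  h1 <- acf$values[idx] * pmin(1 / (1 - lag / dur), 1.6)
  h2 <- vapply(lag, function(L) {
    near <- abs(m_lag - 2 * L) <= 0.1 * L
    if (!any(near)) 0 else max(m_val[near])
  }, numeric(1))
  score <- (h1 + h2) / 2
  best <- min(which(score >= 0.85 * max(score)))
  cycle_ms <- lag[best] * 1000
  list(cycle = cycle_ms, heart_rate = 60000 / cycle_ms)
}

#' Systolic length from the ACF minor maximum
#'
#' The distance between the first major ACF maximum (lag 0) and the first
#' minor maximum corresponds to the average systolic length. The minor
#' maximum is taken as the highest interior local maximum at a lag strictly
#' below half the cycle (minor maxima occur symmetrically before and after
#' mid-cycle; the first one is the S1-to-S2 offset).
#'
#' @param acf an [autocorrelate()] result.
#' @param cycle cycle length in ms (from [estimate_cycle()]).
#' @return systolic length in ms, or `NA` with a warning when no interior
#'   maximum exists (caller should fall back to [systole_empirical()]).
#' @export
systole_from_acf <- function(acf, cycle) {
  lo <- 0.1
  hi <- cycle / 2000
  idx <- local_max_idx(acf$values)
  idx <- idx[acf$lags[idx] > lo & acf$lags[idx] < hi & acf$values[idx] >= 0.05]
  if (!length(idx)) {
    warning("no minor ACF maximum below half a cycle; falling back to the empirical systole formula")
    return(NA_real_)
  }
  best <- idx[which.max(acf$values[idx])]
  acf$lags[best] * 1000
}

#' Empirical systolic length
#'
#' The systolic length decreases linearly with heart rate:
#' `SYS = -1.14 * HR + 371.55` ms above 80 bpm and
#' `SYS = -6.58 * HR + 766.44` ms otherwise (the boundary HR = 80 uses the
#' low-rate branch; the two branches disagree there).
#'
#' @param heart_rate heart rate in bpm, within the supported range [40, 200].
#' @return systolic length in ms.
#' @export
systole_empirical <- function(heart_rate) {
  if (!is.finite(heart_rate) || heart_rate < 40 || heart_rate > 200) {
    stop("heart rate outside the supported range [40, 200] bpm", call. = FALSE)
  }
  if (heart_rate > 80) -1.14 * heart_rate + 371.55
  else -6.58 * heart_rate + 766.44
}

#' Derive cycle timing and tolerance bounds
#'
#' Completes the timing model for one analysis segment: the diastole is the
#' remainder of the cycle (`DIA = 60000/HR - SYS`), the systolic bounds are
#' `SYS -/+ 175 ms` (maximal heart-sound duration 150 ms plus 25 ms systolic
#' standard deviation), and the diastolic bounds follow by conservation
#' (`DIAmax = cycle - SYSmin`, `DIAmin = cycle - SYSmax`). The regime is
#' `increased` for heart rates strictly above 80 bpm, else `normal`.
#'
#' @param heart_rate heart rate in bpm.
#' @param sys systolic length in ms (must be below the cycle length).
#' @param sys_method how `sys` was obtained (`"empirical"` or `"acf"`).
#' @return object of class `cardiac_timing` with fields `heart_rate`,
#'   `cycle`, `sys`, `dia`, `sys_min`, `sys_max`, `dia_min`, `dia_max`
#'   (all ms), `sys_method` and `regime`.
#' @export
derive_bounds <- function(heart_rate, sys, sys_method = c("empirical", "acf")) {
  sys_method <- match.arg(sys_method)
  cycle <- 60000 / heart_rate
  if (!is.finite(sys) || sys >= cycle) {
    stop("systolic length must be finite and below the cycle length", call. = FALSE)
  }
  structure(list(
    heart_rate = heart_rate,
    cycle = cycle,
    sys = sys,
    dia = cycle - sys,
    sys_min = sys - SYS_TOLERANCE_MS,
    sys_max = sys + SYS_TOLERANCE_MS,
    dia_min = cycle - (sys + SYS_TOLERANCE_MS),
    dia_max = cycle - (sys - SYS_TOLERANCE_MS),
    sys_method = sys_method,
    regime = if (heart_rate > 80) "increased" else "normal"
  ), class = "cardiac_timing")
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat(sprintf("<cardiac_timing> HR %.1f bpm (%s regime), SYS %.1f ms [%.1f, %.1f], DIA %.1f ms [%.1f, %.1f], method %s\n",
              x$heart_rate, x$regime, x$sys, x$sys_min, x$sys_max,
              x$dia, x$dia_min, x$dia_max, x$sys_method))
  invisible(x)
}
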