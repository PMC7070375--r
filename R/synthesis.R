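#' Configuration for the synthetic PCG/ECG generator
#'
#' The generator emulates the statistical structure the classification
#' algorithm assumes: quasi-periodic S1/S2 tone bursts in the 20--200 Hz
#' heart-sound band, a systole that shortens linearly with heart rate
#' (the same empirical relation used by [systole_empirical()]), per-cycle
#' timing jitter, optional split sounds and S3 extra peaks, additive white
#' noise, and an R-peak train synchronous with the S1 onsets.
#'
#' Defaults: S1 carrier 60 Hz / S2 carrier 90 Hz (S2 slightly higher-pitched,
#' both inside the heart-sound band and inside the default analysis
#' passbands), S1 100 ms / S2 80 ms, cycle-length jitter SD 10 ms.
#' `amp_ratio_s1_s2 = NULL` resolves to 1.0 at normal rates (<= 80 bpm) and
#' 2.0 at increased rates, where S1 is physiologically louder than S2.
#'
#' @param sampling_rate_pcg PCG sampling rate in Hz.
#' @param sampling_rate_ecg ECG sampling rate in Hz.
#' @param duration recording duration in seconds.
#' @param heart_rate mean heart rate in beats per minute, within [40, 200].
#' @param hr_jitter_sd per-cycle cycle-length jitter SD in ms.
#' @param s1_center_freq,s2_center_freq burst carrier frequencies in Hz
#'   (must lie within 20--200 Hz).
#' @param s1_duration,s2_duration burst durations in ms.
#' @param amp_ratio_s1_s2 S1:S2 amplitude ratio; `NULL` = auto by heart rate.
#' @param split_probability probability that a sound is rendered split.
#' @param split_gap gap between split sub-bursts in ms.
#' @param s3_probability probability of an S3 extra sound per cycle.
#' @param s3_amplitude S3 amplitude as a fraction of the S2 amplitude.
#' @param noise_sd additive white-noise SD as a fraction of the S1 amplitude.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_pcg = 4000, sampling_rate_ecg = 500,
                         duration = 60, heart_rate = 60, hr_jitter_sd = 10,
                         s1_center_freq = 60, s2_center_freq = 90,
                         s1_duration = 100, s2_duration = 80,
                         amp_ratio_s1_s2 = NULL,
                         split_probability = 0, split_gap = 40,
                         s3_probability = 0, s3_amplitude = 0.35,
                         noise_sd = 0, seed = 1L) {
  if (is.null(amp_ratio_s1_s2)) {
    amp_ratio_s1_s2 <- if (heart_rate > 80) 2.0 else 1.0
  }
  cfg <- list(
    sampling_rate_pcg = sampling_rate_pcg, sampling_rate_ecg = sampling_rate_ecg,
    duration = duration, heart_rate = heart_rate, hr_jitter_sd = hr_jitter_sd,
    s1_center_freq = s1_center_freq, s2_center_freq = s2_center_freq,
    s1_duration = s1_duration, s2_duration = s2_duration,
    amp_ratio_s1_s2 = amp_ratio_s1_s2,
    split_probability = split_probability, split_gap = split_gap,
    s3_probability = s3_probability, s3_amplitude = s3_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$heart_rate >= 40, cfg$heart_rate <= 200,
    cfg$duration > 0, cfg$s1_duration > 0, cfg$s2_duration > 0,
    cfg$split_gap > 0, cfg$hr_jitter_sd >= 0,
    cfg$split_probability >= 0, cfg$split_probability <= 1,
    cfg$s3_probability >= 0, cfg$s3_probability <= 1,
    cfg$noise_sd >= 0, cfg$amp_ratio_s1_s2 > 0,
    cfg$sampling_rate_pcg > 0, cfg$sampling_rate_ecg > 0
  )
  for (f in c(cfg$s1_center_freq, cfg$s2_center_freq)) {
    if (f < 20 || f > 200) {
      stop("sound carrier frequencies must lie in the 20-200 Hz heart-sound band",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

## run `expr` under `seed` without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Gaussian-tapered sinusoid added in place; sigma = dur/6 so +-3 sigma spans
## the nominal duration and the burst is smooth and band-limited.
add_burst <- function(samples, fs, t0, peak_time, dur_ms, freq, amp) {
  dur <- dur_ms / 1000
  sigma <- dur / 6
  i0 <- max(1L, floor((peak_time - dur / 2 - t0) * fs) + 1L)
  i1 <- min(length(samples), ceiling((peak_time + dur / 2 - t0) * fs) + 1L)
  if (i1 < i0) return(samples)
  tt <- t0 + (i0:i1 - 1L) / fs - peak_time
  samples[i0:i1] <- samples[i0:i1] +
    amp * exp(-tt^2 / (2 * sigma^2)) * cos(2 * pi * freq * tt)
  samples
}

## render one heart sound, possibly as two split sub-bursts
add_sound <- function(samples, fs, t0, peak_time, dur_ms, freq, amp,
                      split = FALSE, split_gap_ms = 40) {
  if (!split) {
    return(add_burst(samples, fs, t0, peak_time, dur_ms, freq, amp))
  }
  gap <- split_gap_ms / 1000
  samples <- add_burst(samples, fs, t0, peak_time - gap / 2, dur_ms / 2, freq,
                       0.9 * amp)
  add_burst(samples, fs, t0, peak_time + gap / 2, dur_ms / 2, freq, 0.7 * amp)
}

#' Generate a synthetic phonocardiogram with known ground truth
#'
#' Cycle lengths are drawn as `60000 / heart_rate + N(0, hr_jitter_sd)` ms;
#' within each cycle the systolic length is recomputed from the empirical
#' linear heart-rate relation ([systole_empirical()]) at the instantaneous
#' rate, so the synthetic timing matches the classifier's assumptions.
#' S1 starts each cycle, S2 starts one systole later; each sound is a
#' Gaussian-tapered tone burst whose peak sits at the centre of the sound.
#' Each R-peak time equals the corresponding S1 onset.
#'
#' @param config a [synth_config()].
#' @return a list with elements `pcg` (a [timed_signal()], with the config
#'   attached as attribute `synth_config`) and `truth` (class `ground_truth`:
#'   S1/S2 onsets and peak times, extra-event times, R-peak times and
#'   per-cycle true systole/diastole lengths in ms).
#' @export
generate_pcg <- function(config = synth_config()) {
  validate_synth_config(config)
  fs <- config$sampling_rate_pcg
  nominal_ms <- 60000 / config$heart_rate
  if (config$duration * 1000 < nominal_ms) {
    stop_degenerate("duration too short to contain one full heart cycle")
  }
  n_max <- ceiling(config$duration * 1000 / nominal_ms) + 2L

  dat <- with_local_seed(config$seed, {
    cyc <- nominal_ms + stats::rnorm(n_max, 0, config$hr_jitter_sd)
    cyc <- pmax(cyc, 60000 / 200)          # never faster than 200 bpm
    list(cycles = cyc,
         split1 = stats::runif(n_max) < config$split_probability,
         split2 = stats::runif(n_max) < config$split_probability,
         s3     = stats::runif(n_max) < config$s3_probability,
         noise  = if (config$noise_sd > 0)
           stats::rnorm(round(config$duration * fs)) else NULL)
  })

  start <- 0.1                             # lead-in before the first S1
  onsets <- start + cumsum(c(0, dat$cycles[-n_max])) / 1000
  keep <- onsets + dat$cycles / 1000 <= config$duration
  if (!any(keep)) stop_degenerate("duration too short to contain one full heart cycle")
  onsets <- onsets[keep]
  cycles <- dat$cycles[keep]
  n_cyc <- length(onsets)

  inst_hr <- pmin(pmax(60000 / cycles, 40), 200)
  sys_ms <- vapply(inst_hr, systole_empirical, numeric(1))
  dia_ms <- cycles - sys_ms

  s1_amp <- config$amp_ratio_s1_s2
  s2_amp <- 1.0
  s1_peaks <- onsets + config$s1_duration / 2000
  s2_onsets <- onsets + sys_ms / 1000
  s2_peaks <- s2_onsets + config$s2_duration / 2000

  n <- round(config$duration * fs)
  x <- numeric(n)
  extra <- numeric(0)
  for (i in seq_len(n_cyc)) {
    x <- add_sound(x, fs, 0, s1_peaks[i], config$s1_duration,
                   config$s1_center_freq, s1_amp,
                   split = dat$split1[i], split_gap_ms = config$split_gap)
    x <- add_sound(x, fs, 0, s2_peaks[i], config$s2_duration,
                   config$s2_center_freq, s2_amp,
                   split = dat$split2[i], split_gap_ms = config$split_gap)
    if (dat$s3[i]) {
      t3 <- s2_peaks[i] + 0.160            # S3 sits ~160 ms after the S2 peak
      if (t3 < config$duration) {
        x <- add_burst(x, fs, 0, t3, 60, 50, config$s3_amplitude * s2_amp)
        extra <- c(extra, t3)
      }
    }
  }
  if (config$noise_sd > 0) x <- x + config$noise_sd * s1_amp * dat$noise

  truth <- structure(list(
    s1_onsets = onsets, s1_peak_times = s1_peaks,
    s2_onsets = s2_onsets, s2_peak_times = s2_peaks,
    extra_event_times = extra, r_peak_times = onsets,
    true_sys_lengths = sys_ms, true_dia_lengths = dia_ms
  ), class = "ground_truth")

  pcg <- timed_signal(x, fs, t0 = 0)
  attr(pcg, "synth_config") <- config
  list(pcg = pcg, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cycles, %d extra events; mean SYS %.1f ms, mean DIA %.1f ms\n",
              length(x$s1_onsets), length(x$extra_event_times),
              mean(x$true_sys_lengths), mean(x$true_dia_lengths)))
  invisible(x)
}

#' Generate a synthetic reference ECG from ground truth
#'
#' Places an R-wave-like spike (narrow Gaussian) at each ground-truth R-peak
#' time; spike maxima coincide with the R-peak times to within one ECG sample.
#'
#' @param truth a `ground_truth` from [generate_pcg()].
#' @param config the matching [synth_config()].
#' @return a [timed_signal()] at `config$sampling_rate_ecg`.
#' @export
generate_ecg <- function(truth, config = synth_config()) {
  fs <- config$sampling_rate_ecg
  n <- round(config$duration * fs)
  x <- numeric(n)
  for (r in truth$r_peak_times) {
    x <- add_r_spike(x, fs, r)
  }
  timed_signal(x, fs, t0 = 0)
}

## narrow biphasic-free R spike: 5 ms-SD Gaussian, unit amplitude
add_r_spike <- function(x, fs, peak_time, amp = 1) {
  sd <- 0.005
  i0 <- max(1L, floor((peak_time - 4 * sd) * fs) + 1L)
  i1 <- min(length(x), ceiling((peak_time + 4 * sd) * fs) + 1L)
  if (i1 < i0) return(x)
  tt <- (i0:i1 - 1L) / fs - peak_time
  x[i0:i1] <- x[i0:i1] + amp * exp(-tt^2 / (2 * sd^2))
  x
}

#' Inject artifacts into a synthetic PCG
#'
#' Post-hoc modification of a generated recording: split an S1 or S2 into two
#' sub-bursts, add an S3 extra sound within the diastole, or add white noise.
#' Ground-truth S1/S2 onset and peak times are unchanged for splits (the
#' envelope peak may move within the sound's extent); `extra_event_times`
#' gains the injected S3 times.
#'
#' @param pcg the PCG `timed_signal` from [generate_pcg()] (must carry its
#'   `synth_config` attribute).
#' @param truth the matching `ground_truth`.
#' @param kind one of `"split_s1"`, `"split_s2"`, `"s3"`, `"white_noise"`.
#' @param params list of kind-specific parameters: `cycles` (indices of
#'   cycles to modify; default all), `gap_ms` (splits; default the config's
#'   `split_gap`), `offset_ms` (S3 offset after the S2 peak; default 160),
#'   `amplitude` (S3, fraction of S2 amplitude; default config), `sd`
#'   (white noise, fraction of S1 amplitude), `seed` (white noise).
#' @return list with modified `pcg` and `truth`.
#' @export
inject_artifacts <- function(pcg, truth, kind, params = list()) {
  config <- attr(pcg, "synth_config")
  if (is.null(config)) stop("`pcg` must carry its synth_config attribute", call. = FALSE)
  kind <- match.arg(kind, c("split_s1", "split_s2", "s3", "white_noise"))
  fs <- pcg$sampling_rate
  x <- pcg$samples
  cycles <- params$cycles %||% seq_along(truth$s1_onsets)
  s1_amp <- config$amp_ratio_s1_s2

  if (kind %in% c("split_s1", "split_s2")) {
    gap <- params$gap_ms %||% config$split_gap
    if (kind == "split_s1") {
      peaks <- truth$s1_peak_times; dur <- config$s1_duration
      freq <- config$s1_center_freq; amp <- s1_amp
    } else {
      peaks <- truth$s2_peak_times; dur <- config$s2_duration
      freq <- config$s2_center_freq; amp <- 1.0
    }
    for (i in cycles) {
      # subtract the original burst, re-render as two sub-bursts
      x <- add_burst(x, fs, pcg$t0, peaks[i], dur, freq, -amp)
      x <- add_sound(x, fs, pcg$t0, peaks[i], dur, freq, amp,
                     split = TRUE, split_gap_ms = gap)
    }
  } else if (kind == "s3") {
    offset <- (params$offset_ms %||% 160) / 1000
    amp <- (params$amplitude %||% config$s3_amplitude) * 1.0
    for (i in cycles) {
      t3 <- truth$s2_peak_times[i] + offset
      if (t3 < pcg$t0 + signal_duration(pcg)) {
        x <- add_burst(x, fs, pcg$t0, t3, 60, 50, amp)
        truth$extra_event_times <- sort(c(truth$extra_event_times, t3))
      }
    }
  } else { # white_noise
    sd <- params$sd %||% config$noise_sd
    if (sd > 0) {
      seed <- params$seed %||% (config$seed + 1L)
      x <- x + with_local_seed(seed, stats::rnorm(length(x), 0, sd * s1_amp))
    }
  }

  out <- timed_signal(x, fs, t0 = pcg$t0)
  attr(out, "synth_config") <- config
  list(pcg = out, truth = truth)
}

#' Inject a triple-knock synchronization artifact into a PCG/ECG pair
#'
#' Emulates the synchronization procedure of knocking three times on the ECG
#' electrodes before the recording proper: sharp, high-amplitude transients
#' are added to both channels at the same true times (so a deliberate
#' inter-channel offset is preserved and can be recovered by
#' [synchronize()]).
#'
#' @param pcg,ecg `timed_signal` pair.
#' @param times knock times in seconds (absolute, on the PCG clock).
#' @param amplitude knock amplitude relative to each channel's maximum.
#' @return list with modified `pcg` and `ecg`.
#' @export
inject_knocks <- function(pcg, ecg, times = c(2, 2.8, 3.6), amplitude = 10) {
  amp_p <- amplitude * max(abs(pcg$samples), 1e-12)
  amp_e <- amplitude * max(abs(ecg$samples), 1e-12)
  xp <- pcg$samples
  xe <- ecg$samples
  for (tk in times) {
    xp <- add_burst(xp, pcg$sampling_rate, pcg$t0, tk, 30, 120, amp_p)
    xe <- add_r_spike(xe, ecg$sampling_rate, tk - ecg$t0, amp_e)
  }
  pcg_out <- timed_signal(xp, pcg$sampling_rate, pcg$t0)
  attr(pcg_out, "synth_config") <- attr(pcg, "synth_config")
  list(pcg = pcg_out, ecg = timed_signal(xe, ecg$sampling_rate, ecg$t0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
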