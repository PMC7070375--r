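#' Run configuration for the full pipeline
#'
#' Bundles every tunable of the processing chain. Method-specific defaults
#' (filter band, threshold multipliers) follow the optimized parameter set
#' for the chosen envelope method; explicit `filter` / `peaks` arguments
#' override them.
#'
#' @param method envelope method, `"HT"` (default) or `"STFT"`.
#' @param filter a [filter_config()]; default per method.
#' @param stft an [stft_config()] (used by the STFT method only).
#' @param peaks a [peak_config()]; default per method.
#' @param segmentation a [segmentation_config()].
#' @param eval an [eval_config()].
#' @param sys_method systolic-length estimator, `"empirical"` or `"acf"`.
#' @param filter_mode `"causal"` (real-time semantics) or `"zero-phase"`.
#' @param sync_mode PCG/ECG alignment, `"fixed_offset"` or
#'   `"knock_artifact"`.
#' @param sync_offset offset in seconds for `fixed_offset` mode.
#' @param seed integer seed for any randomised step.
#' @return a list of class `run_config`.
#' @export
run_config <- function(method = c("HT", "STFT"),
                       filter = NULL, stft = stft_config(), peaks = NULL,
                       segmentation = segmentation_config(),
                       eval = eval_config(),
                       sys_method = c("empirical", "acf"),
                       filter_mode = c("causal", "zero-phase"),
                       sync_mode = c("fixed_offset", "knock_artifact"),
                       sync_offset = 0, seed = 1L) {
  method <- match.arg(method)
  structure(list(
    method = method,
    filter = filter %||% default_filter_config(method),
    stft = stft,
    peaks = peaks %||% default_peak_config(method),
    segmentation = segmentation,
    eval = eval,
    sys_method = match.arg(sys_method),
    filter_mode = match.arg(filter_mode),
    sync_mode = match.arg(sync_mode),
    sync_offset = sync_offset,
    seed = as.integer(seed)
  ), class = "run_config")
}

## overlay flat parameter names (as used by grid_optimize / config files /
## CLI flags) onto a run_config
merge_run_config <- function(base, params) {
  cfg <- base
  for (nm in names(params)) {
    val <- params[[nm]]
    if (is.null(val)) next
    switch(nm,
      method = { cfg$method <- val },
      n_normal = { cfg$peaks$n_normal <- val },
      n_high = { cfg$peaks$n_high <- val },
      min_separation = { cfg$peaks$min_separation <- val },
      f_lower = { cfg$filter$f_lower <- val },
      f_upper = { cfg$filter$f_upper <- val },
      order_hp = { cfg$filter$order_hp <- as.integer(val) },
      order_lp = { cfg$filter$order_lp <- as.integer(val) },
      window_len = { cfg$stft <- stft_config(val, cfg$stft$overlap) },
      overlap = { cfg$stft <- stft_config(cfg$stft$window_len, val) },
      discard_prefix = { cfg$segmentation$discard_prefix <- val },
      n_segments = { cfg$segmentation$n_segments <- as.integer(val) },
      tolerance_window = { cfg$eval$tolerance_window <- val },
      sys_method = { cfg$sys_method <- val },
      filter_mode = { cfg$filter_mode <- val },
      sync_mode = { cfg$sync_mode <- val },
      sync_offset = { cfg$sync_offset <- val },
      seed = { cfg$seed <- as.integer(val) },
      warning(sprintf("unknown run_config parameter '%s' ignored", nm))
    )
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Flat keys (`method`, `n_normal`, `n_high`, `f_lower`, `f_upper`,
#' `order_hp`, `order_lp`, `window_len`, `overlap`, `discard_prefix`,
#' `n_segments`, `tolerance_window`, `sys_method`, `filter_mode`,
#' `sync_mode`, `sync_offset`, `seed`) override the method defaults.
#'
#' @param path YAML file path.
#' @param base the [run_config()] to overlay onto; its method is replaced
#'   first when the file sets one (so method defaults resolve correctly).
#' @return a [run_config()].
#' @export
read_run_config <- function(path, base = NULL) {
  params <- yaml::read_yaml(path)
  if (!is.null(params$method) && is.null(base)) {
    base <- run_config(method = params$method)
  }
  merge_run_config(base %||% run_config(), params)
}

#' Run the full detection/classification chain on one recording
#'
#' Preprocessing (band-pass, optional PCG/ECG synchronization, prefix
#' discard, equal-duration segmentation), envelope extraction, per-segment
#' heart-rate estimation and S1/S2 classification, and -- when a reference
#' ECG is supplied -- R-peak referenced scoring. Per-segment counts are
#' summed over the recording before the metrics are computed
#' (micro-averaging). Events within one tolerance window of the retained
#' interval's edges whose counterpart falls outside the analysed interval
#' are excluded from the counts (standard event-scoring practice at record
#' boundaries). Per-segment estimation failures are warnings, not errors;
#' the run continues.
#'
#' @param pcg PCG input: a [timed_signal()] or a path to a WAV/CSV file.
#' @param ecg optional ECG reference: a [timed_signal()] or CSV/WAV path.
#' @param config a [run_config()].
#' @return a list of class `phonoseg_run`: `events` (pooled
#'   [classified_sounds()]), `timing` (per-segment data frame), `segments`
#'   (per-segment dispatch results), `counts` and `metrics` (when an ECG was
#'   given), `r_peaks`, and `config`.
#' @export
run_pipeline <- function(pcg, ecg = NULL, config = run_config()) {
  pcg <- as_timed_signal(pcg)
  if (!is.null(ecg)) ecg <- as_timed_signal(ecg)

  filtered <- bandpass(pcg, config$filter, mode = config$filter_mode)

  if (!is.null(ecg)) {
    syn <- if (config$sync_mode == "knock_artifact") {
      tryCatch(synchronize(filtered, ecg, "knock_artifact",
                           search_window = config$segmentation$discard_prefix),
               phonoseg_estimation_failure = function(e) {
                 warning("knock synchronization failed; falling back to fixed offset 0")
                 synchronize(filtered, ecg, "fixed_offset", offset = 0)
               })
    } else {
      synchronize(filtered, ecg, "fixed_offset", offset = config$sync_offset)
    }
    filtered <- syn$pcg
    ecg <- syn$ecg
  }

  segs <- segment_signal(filtered, config$segmentation)
  results <- lapply(segs, function(s) {
    tryCatch({
      env <- extract_envelope(s, config$method, config$stft)
      dispatch(env, peak_cfg = config$peaks, sys_method = config$sys_method)
    }, error = function(e) {
      warning(sprintf("segment at t0=%.2f s failed: %s", s$t0, conditionMessage(e)))
      list(classified = classified_sounds(), timing = NULL, peaks = peak_series())
    })
  })

  events <- do.call(rbind, lapply(results, `[[`, "classified"))
  events <- classified_sounds(events$time, events$amplitude, events$label, events$rule)
  events <- dedup_boundary_events(events, config$peaks$min_separation)

  timing_df <- do.call(rbind, lapply(seq_along(results), function(k) {
    tm <- results[[k]]$timing
    if (is.null(tm)) return(NULL)
    data.frame(segment = k, t0 = segs[[k]]$t0, hr_bpm = tm$heart_rate,
               sys_ms = tm$sys, dia_ms = tm$dia,
               sys_min = tm$sys_min, sys_max = tm$sys_max,
               dia_min = tm$dia_min, dia_max = tm$dia_max,
               regime = tm$regime, method = tm$sys_method,
               stringsAsFactors = FALSE)
  }))

  out <- list(events = events, timing = timing_df, segments = results,
              counts = NULL, metrics = NULL, r_peaks = NULL, config = config)

  if (!is.null(ecg)) {
    lo <- segs[[1L]]$t0
    hi <- segs[[length(segs)]]$t0 + signal_duration(segs[[length(segs)]])
    r_times <- detect_r_peaks(ecg)
    r_times <- r_times[r_times >= lo & r_times <= hi]
    counts <- match_s1(events, r_times, config$eval)
    tw <- config$eval$tolerance_window
    edge <- function(x) x < lo + tw | x > hi - tw
    counts$fn <- counts$fn - sum(edge(counts$unmatched_r))
    counts$fp <- counts$fp - sum(edge(counts$unmatched_s1))
    out$counts <- counts
    out$metrics <- compute_metrics(counts)
    out$r_peaks <- r_times
  }
  class(out) <- "phonoseg_run"
  out
}

#' @export
print.phonoseg_run <- function(x, ...) {
  cat(sprintf("<phonoseg_run> method %s, %d segments, %d events\n",
              x$config$method, length(x$segments), nrow(x$events)))
  if (!is.null(x$timing)) {
    cat(sprintf("  mean HR %.1f bpm; regimes: %s\n",
                mean(x$timing$hr_bpm),
                paste(unique(x$timing$regime), collapse = "/")))
  }
  if (!is.null(x$metrics)) {
    cat("  "); print(x$metrics)
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `annotations.csv` (time_s, amplitude, label, rule),
#' `timing.csv` (per-segment cardiac timing) and, when metrics exist,
#' `metrics.json`.
#'
#' @param run a `phonoseg_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- data.frame(time_s = run$events$time, amplitude = run$events$amplitude,
                    label = run$events$label, rule = run$events$rule)
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  if (!is.null(run$timing)) {
    utils::write.csv(run$timing, file.path(dir, "timing.csv"), row.names = FALSE)
  }
  if (!is.null(run$metrics)) {
    jsonlite::write_json(
      c(unclass(run$metrics),
        list(tp = run$counts$tp, fp = run$counts$fp,
             fn = run$counts$fn, tn = run$counts$tn)),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

## A sound that straddles a segment boundary appears twice: truncated in one
## segment, whole in the next. Re-apply the minimum-separation rule across
## the pooled events (removed events excluded), keeping the larger amplitude;
## genuine adjacent sounds are always at least SYSmin apart, so only
## boundary duplicates are affected.
dedup_boundary_events <- function(events, min_separation) {
  cand <- which(events$label != "removed")
  if (length(cand) <= 1L) return(events)
  ord <- cand[order(-events$amplitude[cand], events$time[cand])]
  keep <- logical(nrow(events))
  keep[events$label == "removed"] <- TRUE
  blocked <- logical(nrow(events))
  for (j in ord) {
    if (blocked[j]) next
    keep[j] <- TRUE
    near <- cand[abs(events$time[cand] - events$time[j]) < min_separation]
    blocked[setdiff(near, j)] <- TRUE
  }
  classified_sounds(events$time[keep], events$amplitude[keep],
                    events$label[keep], events$rule[keep])
}

## coerce a path or timed_signal to a timed_signal
as_timed_signal <- function(x) {
  if (inherits(x, "timed_signal")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.wav$", x, ignore.case = TRUE)) return(read_wav(x))
    return(read_signal_csv(x))
  }
  stop("expected a timed_signal or a WAV/CSV file path", call. = FALSE)
}
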