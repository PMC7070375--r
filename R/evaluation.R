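#' Evaluation configuration
#'
#' @param tolerance_window width of the tolerance window in seconds placed
#'   symmetrically around each reference R-peak (default 0.150 s, i.e.
#'   +/- 75 ms -- the approximate maximal duration of a heart sound).
#' @return a list of class `eval_config`.
#' @export
eval_config <- function(tolerance_window = 0.150) {
  stopifnot(tolerance_window > 0)
  structure(list(tolerance_window = tolerance_window), class = "eval_config")
}

#' Detect R-peaks in a reference ECG
#'
#' Band-passes the ECG to the QRS band (5--30 Hz, zero-phase so the R-peak
#' time is preserved), squares it, thresholds at a fraction of the rolling
#' maximum (2 s blocks) and keeps local maxima with a 250 ms refractory
#' period (largest peak wins inside the refractory window).
#'
#' @param ecg a [timed_signal()].
#' @param frac threshold as a fraction of the block-wise maximum.
#' @param refractory refractory period in seconds.
#' @return numeric vector of R-peak times in seconds (empty, with a
#'   warning, for a flat signal).
#' @export
detect_r_peaks <- function(ecg, frac = 0.4, refractory = 0.250) {
  v <- ecg$samples
  if (!length(v) || stats::sd(v) == 0) {
    warning("flat ECG signal; no R-peaks detected")
    return(numeric(0))
  }
  fs <- ecg$sampling_rate
  bp <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  sq <- as.numeric(signal::filtfilt(bp, v))^2

  block <- max(1L, round(2 * fs))
  nb <- ceiling(length(sq) / block)
  thr <- numeric(length(sq))
  for (k in seq_len(nb)) {
    i0 <- (k - 1L) * block + 1L
    i1 <- min(length(sq), k * block)
    thr[i0:i1] <- frac * max(sq[i0:i1])
  }
  thr <- pmax(thr, 0.01 * max(sq))         # floor against noise-only blocks

  idx <- local_max_idx(sq)
  idx <- idx[sq[idx] > thr[idx]]
  if (!length(idx)) return(numeric(0))
  ## greedy refractory: largest first
  ord <- idx[order(-sq[idx])]
  kept <- numeric(0)
  for (j in ord) {
    tj <- ecg$t0 + (j - 1L) / fs
    if (!length(kept) || all(abs(kept - tj) >= refractory)) kept <- c(kept, tj)
  }
  sort(kept)
}

#' Confusion counts for S1 classification against R-peak references
#'
#' Each reference R-peak spawns a tolerance window `[r - TW/2, r + TW/2]`.
#' Matching is one-to-one and greedy in time order: an S1-labelled event
#' inside the earliest unconsumed window is a true positive and consumes
#' that window; an S1 outside every window is a false positive; unconsumed
#' windows are false negatives; detected events labelled not-S1 that lie
#' outside every window are true negatives.
#'
#' @param classified a [classified_sounds()] (or data frame with `time` and
#'   `label`).
#' @param r_times sorted reference R-peak times in seconds.
#' @param cfg an [eval_config()].
#' @return a list of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn`, plus `matched_r` / `unmatched_s1` (times, for edge handling by
#'   callers).
#' @export
match_s1 <- function(classified, r_times, cfg = eval_config()) {
  tw <- cfg$tolerance_window / 2
  r_times <- sort(r_times)
  s1 <- sort(classified$time[classified$label == "S1"])
  others <- classified$time[classified$label != "S1"]

  consumed <- logical(length(r_times))
  matched_s1 <- logical(length(s1))
  for (k in seq_along(s1)) {
    cand <- which(!consumed & abs(r_times - s1[k]) <= tw)
    if (length(cand)) {
      consumed[cand[1L]] <- TRUE
      matched_s1[k] <- TRUE
    }
  }
  in_any_window <- function(times) {
    if (!length(times) || !length(r_times)) return(rep(FALSE, length(times)))
    vapply(times, function(tt) any(abs(r_times - tt) <= tw), logical(1))
  }
  tn <- sum(!in_any_window(others))
  structure(list(
    tp = sum(matched_s1),
    fp = sum(!matched_s1),
    fn = sum(!consumed),
    tn = tn,
    matched_r = r_times[consumed],
    unmatched_r = r_times[!consumed],
    unmatched_s1 = s1[!matched_s1]
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Sensitivity (= recall) `tp/(tp+fn)`, specificity `tn/(fp+tn)`, accuracy
#' `(tp+tn)/(tp+tn+fp+fn)`, precision `tp/(tp+fp)` and the F1-score
#' `2*recall*precision/(precision+recall)`. Any 0/0 is reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/fn/tn).
#' @return a list of class `s1_metrics` with the five fractions.
#' @export
compute_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, fp + tn)
    acc <- ratio(tp + tn, tp + tn + fp + fn)
    prec <- ratio(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                   precision = prec, f1 = f1), class = "s1_metrics")
  })
}

#' @export
print.s1_metrics <- function(x, ...) {
  cat(sprintf("<s1_metrics> sensitivity=%.3f specificity=%.3f accuracy=%.3f precision=%.3f F1=%.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$precision, x$f1))
  invisible(x)
}

#' F1-driven parameter grid search
#'
#' Exhaustively evaluates every row of `grid` (columns name [run_config()]
#' fields, e.g. `n_normal`, `n_high`, `f_lower`, `f_upper`, `order_hp`,
#' `order_lp`, `window_len`, `overlap`) over a corpus of recordings with
#' reference ECGs, scoring each grid point by the mean F1 across the corpus.
#' `n_high` only acts at increased heart rates, so it is selected separately
#' by the mean F1 over the high-heart-rate recordings (those whose segments
#' are majority `increased` regime), holding the other parameters at the
#' overall optimum.
#'
#' @param corpus list of recordings, each a list with elements `pcg` and
#'   `ecg` ([timed_signal()]s or file paths).
#' @param grid data frame of parameter combinations (one row per point).
#' @param base_config the [run_config()] supplying unvaried parameters.
#' @return list with `best` (the winning parameter row), `table` (the grid
#'   with `mean_f1` and `mean_f1_high` columns) and `best_f1`.
#' @export
grid_optimize <- function(corpus, grid, base_config = run_config()) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  if (!nrow(grid)) stop("empty grid", call. = FALSE)

  eval_point <- function(row) {
    cfg <- merge_run_config(base_config, as.list(row))
    f1 <- rep(NA_real_, length(corpus))
    high <- rep(FALSE, length(corpus))
    for (j in seq_along(corpus)) {
      res <- run_pipeline(corpus[[j]]$pcg, corpus[[j]]$ecg, cfg)
      # a run that classifies nothing has undefined F1; for optimization
      # purposes that is the worst possible score
      f1[j] <- if (is.na(res$metrics$f1)) 0 else res$metrics$f1
      regimes <- vapply(res$segments, function(s)
        if (is.null(s$timing)) NA_character_ else s$timing$regime, character(1))
      high[j] <- mean(regimes == "increased", na.rm = TRUE) > 0.5
    }
    c(mean_f1 = mean(f1, na.rm = TRUE),
      mean_f1_high = if (any(high)) mean(f1[high], na.rm = TRUE) else NA_real_)
  }

  scores <- t(vapply(seq_len(nrow(grid)), function(i) eval_point(grid[i, , drop = FALSE]),
                     numeric(2)))
  table <- cbind(grid, scores)

  best_i <- which.max(scores[, "mean_f1"])
  best <- table[best_i, , drop = FALSE]
  if ("n_high" %in% names(grid) && length(unique(grid$n_high)) > 1L &&
      any(!is.na(scores[, "mean_f1_high"]))) {
    others <- setdiff(names(grid), "n_high")
    same <- rep(TRUE, nrow(grid))
    for (cn in others) same <- same & grid[[cn]] == grid[[cn]][best_i]
    cand <- which(same & !is.na(scores[, "mean_f1_high"]))
    if (length(cand)) {
      best_h <- cand[which.max(scores[cand, "mean_f1_high"])]
      best$n_high <- grid$n_high[best_h]
    }
  }
  list(best = best, table = table, best_f1 = scores[best_i, "mean_f1"])
}
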