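#' Classified heart-sound events
#'
#' @param time,amplitude,label,rule parallel vectors; `label` one of
#'   `"S1"`, `"S2"`, `"removed"`, `"unclassified"`; `rule` names the rule
#'   that produced the label (`eq12`..`eq18`, `pairing`, or `NA`).
#' @return a `data.frame` of class `classified_sounds`, ordered by time.
#' @export
classified_sounds <- function(time = numeric(0), amplitude = numeric(0),
                              label = character(0), rule = character(0)) {
  df <- data.frame(time = time, amplitude = amplitude,
                   label = label, rule = rule, stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("classified_sounds", "data.frame")
  df
}

#' @export
print.classified_sounds <- function(x, ...) {
  counts <- table(factor(x$label, levels = c("S1", "S2", "removed", "unclassified")))
  cat(sprintf("<classified_sounds> %d events: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  NextMethod()
}

## bounds in seconds plus the interval predicates used by every rule
rule_env <- function(timing) {
  list(
    sys_min = timing$sys_min / 1000, sys_max = timing$sys_max / 1000,
    dia_min = timing$dia_min / 1000, dia_max = timing$dia_max / 1000
  )
}

#' Classify peaks at increased heart rates (> 80 bpm)
#'
#' At increased rates the S1 amplitude exceeds the S2 amplitude, so a
#' left-to-right scan over the inter-peak distances suffices:
#' if `dx_i < SYSmax` and `y_i > y_{i+1}`, peak i is S1 and peak i+1 is S2;
#' if `dx_i > SYSmax` the S2 was missed and peak i is S1 alone. A pair,
#' once labelled, is consumed (the scan resumes two peaks further) so an S2
#' is never reused as the next pair's S1. A trailing peak with no successor
#' is S1 when its preceding gap exceeds `SYSmax`, or when its amplitude
#' exceeds its predecessor's (the amplitude premise identifies an S1 whose
#' S2 lies beyond the end of the segment); otherwise it stays unclassified.
#'
#' @param peaks a deduplicated [peak_series()].
#' @param timing a [derive_bounds()] result with `regime == "increased"`.
#' @return a [classified_sounds()].
#' @export
classify_increased <- function(peaks, timing) {
  n <- length(peaks$times)
  lab <- rep("unclassified", n)
  rul <- rep(NA_character_, n)
  if (n < 2L) {
    if (n) warning("fewer than 2 peaks; nothing can be classified")
    return(classified_sounds(peaks$times, peaks$amplitudes, lab, rul))
  }
  b <- rule_env(timing)
  d <- peaks$deltas
  y <- peaks$amplitudes
  i <- 1L
  while (i <= n) {
    if (i < n) {
      if (d[i] < b$sys_max && y[i] > y[i + 1L]) {
        lab[i] <- "S1"; rul[i] <- "eq12"
        lab[i + 1L] <- "S2"; rul[i + 1L] <- "eq12"
        i <- i + 2L
        next
      }
      if (d[i] > b$sys_max) {
        lab[i] <- "S1"; rul[i] <- "eq13"
      }
      i <- i + 1L
    } else {
      if (d[i - 1L] > b$sys_max) {
        lab[i] <- "S1"; rul[i] <- "eq13"
      } else if (y[i] > y[i - 1L]) {
        lab[i] <- "S1"; rul[i] <- "pairing"
      }
      i <- i + 1L
    }
  }
  classified_sounds(peaks$times, peaks$amplitudes, lab, rul)
}

#' Remove extra peaks at normal heart rates
#'
#' Extra peaks (S3, S4, artefacts) produce invalid diastoles and must be
#' removed before classification. Two left-to-right passes over the
#' inter-peak distances `dx`, with `dx` recomputed after every removal and
#' out-of-range index conditions evaluating false:
#'
#' Pass 1 (invalid diastole): a too-short `dx_i` flanked by a valid systole
#' before (`SYSmin < dx_{i-1} < SYSmax`) and either a valid systole at
#' `dx_{i+2}` (both neighbours intact) or a valid diastole at `dx_{i-2}`
#' plus valid systole at `dx_{i-1}` (the following S2 missing) drops the
#' right peak of `dx_i`. In the intact-neighbour case the removal must
#' restore a valid diastole (`DIAmin < dx_i + dx_{i+1} < DIAmax`) -- extra
#' peaks split a diastole in two, so deleting the extra merges the halves
#' back; without this check the rule could consume a true S2 when an
#' unremovable extra peak near a segment boundary mimics a systolic gap.
#' Pass 1 runs in two sweeps: gaps below `SYSmin` (too short to be even a
#' systole, hence unambiguously extra) are removed first; gaps that also
#' fit the systolic bounds are only reconsidered once the clear cases are
#' gone, so an ambiguous gap is never destroyed while a clearer culprit
#' exists.
#'
#' Pass 2 (extra peak shortly before an S1, whose preceding gap looks like
#' a valid diastole): `SYSmin < dx_{i-1} < SYSmax` and
#' `DIAmin < dx_i < DIAmax` with a valid systole at `dx_{i+2}` (or, with
#' one S2 missing, at `dx_{i+3}`) drops the right peak of `dx_i` --
#' provided that peak's own following gap is below `SYSmin`, i.e. the
#' candidate really does sit shortly before the next sound; a peak whose
#' following gap is a plausible systole or cycle is never deleted.
#'
#' @param peaks a deduplicated [peak_series()].
#' @param timing a [derive_bounds()] result with `regime == "normal"`.
#' @return list with `peaks` (the surviving [peak_series()]) and `removed`
#'   (a [classified_sounds()] of the removed events and the rule that
#'   removed each).
#' @export
remove_extra_peaks <- function(peaks, timing) {
  b <- rule_env(timing)
  sysv <- function(x) !is.na(x) && x > b$sys_min && x < b$sys_max
  diav <- function(x) !is.na(x) && x > b$dia_min && x < b$dia_max
  t <- peaks$times
  y <- peaks$amplitudes
  rm_t <- numeric(0); rm_y <- numeric(0); rm_r <- character(0)

  drop_peak <- function(j, rule) {
    rm_t <<- c(rm_t, t[j]); rm_y <<- c(rm_y, y[j]); rm_r <<- c(rm_r, rule)
    t <<- t[-j]; y <<- y[-j]
  }
  gap <- function(i) {
    if (i < 1L || i > length(t) - 1L) NA_real_ else t[i + 1L] - t[i]
  }

  ## pass 1: invalid diastoles (extra peak inside the diastole); two sweeps --
  ## gaps below SYSmin are unambiguously extra and go first, gaps that also
  ## fit the systolic bounds are only removed once the clear cases are gone
  for (sweep in 1:2) {
    i <- 1L
    while (i <= length(t) - 1L) {
      di <- gap(i)
      ambiguous <- sysv(di)
      if (!is.na(di) && di < b$dia_min && (sweep == 2L || !ambiguous)) {
        if (sysv(gap(i - 1L)) && sysv(gap(i + 2L)) && diav(di + gap(i + 1L))) {
          drop_peak(i + 1L, "eq14"); next
        }
        if (diav(gap(i - 2L)) && sysv(gap(i - 1L))) {
          drop_peak(i + 1L, "eq15"); next
        }
      }
      i <- i + 1L
    }
  }

  ## pass 2: extra peak shortly before an S1 (valid-looking diastole)
  i <- 1L
  while (i <= length(t) - 1L) {
    di <- gap(i)
    if (sysv(gap(i - 1L)) && diav(di) && isTRUE(gap(i + 1L) < b$sys_min)) {
      if (sysv(gap(i + 2L))) { drop_peak(i + 1L, "eq16"); next }
      if (sysv(gap(i + 3L))) { drop_peak(i + 1L, "eq17"); next }
    }
    i <- i + 1L
  }

  list(peaks = peak_series(t, y),
       removed = classified_sounds(rm_t, rm_y,
                                   rep("removed", length(rm_t)), rm_r))
}

#' Classify peaks at normal heart rates
#'
#' Expects the peak list to have passed through [remove_extra_peaks()], so
#' the remaining inter-peak distances are correct systoles, diastoles and
#' heart cycles. A peak flanked on both sides by gaps exceeding `SYSmax`
#' (two consecutive S2 missing) is labelled S1 directly. The remaining
#' peaks are paired: a gap within the systolic bounds labels its left peak
#' S1 and its right peak S2; a gap within the diastolic bounds labels its
#' left peak S2 and its right peak S1. Systolic pairing runs before
#' diastolic pairing because the systolic length varies less than the
#' diastolic one, and within the systolic pass, gaps corroborated by an
#' adjacent valid diastole are paired first -- an unremovable extra peak at
#' a segment boundary can mimic a systolic gap, and the chain-consistent
#' gaps must claim their peaks before it does. Earlier labels win every
#' conflict, and a pairing that contradicts an existing label (e.g. a
#' systole whose right peak is already S1) is skipped entirely. Leftover
#' peaks stay unclassified.
#'
#' @param peaks a [peak_series()] after extra-peak removal.
#' @param timing a [derive_bounds()] result with `regime == "normal"`.
#' @return a [classified_sounds()].
#' @export
classify_normal <- function(peaks, timing) {
  n <- length(peaks$times)
  lab <- rep("unclassified", n)
  rul <- rep(NA_character_, n)
  if (n == 0L) return(classified_sounds())
  b <- rule_env(timing)
  d <- peaks$deltas
  sysv <- function(x) x > b$sys_min & x < b$sys_max
  diav <- function(x) x > b$dia_min & x < b$dia_max

  if (n >= 3L) {
    for (j in 2L:(n - 1L)) {
      if (d[j - 1L] > b$sys_max && d[j] > b$sys_max) {
        lab[j] <- "S1"; rul[j] <- "eq18"
      }
    }
  }
  if (n >= 2L) {
    pair <- function(i, left, right) {
      ok_l <- lab[i] %in% c("unclassified", left)
      ok_r <- lab[i + 1L] %in% c("unclassified", right)
      if (ok_l && ok_r) {
        if (lab[i] == "unclassified") { lab[i] <<- left; rul[i] <<- "pairing" }
        if (lab[i + 1L] == "unclassified") { lab[i + 1L] <<- right; rul[i + 1L] <<- "pairing" }
      }
    }
    sys_gaps <- which(sysv(d))
    has_dia_neighbour <- vapply(sys_gaps, function(i) {
      (i > 1L && diav(d[i - 1L])) || (i < n - 1L && diav(d[i + 1L]))
    }, logical(1))
    for (i in sys_gaps[has_dia_neighbour]) pair(i, "S1", "S2")
    for (i in sys_gaps[!has_dia_neighbour]) pair(i, "S1", "S2")
    for (i in which(diav(d))) pair(i, "S2", "S1")
  }
  classified_sounds(peaks$times, peaks$amplitudes, lab, rul)
}

#' Per-segment detection and classification pipeline
#'
#' Runs the full per-segment chain on one envelope: autocorrelation, heart
#' rate and regime estimation, regime-specific threshold selection, peak
#' detection (gradient local maxima, amplitude threshold, 150 ms minimum
#' separation), timing bounds (empirical formula by default, ACF systole on
#' request with empirical fallback), and the regime-specific classifier
#' (with extra-peak removal at normal rates). When the heart rate cannot be
#' estimated the segment yields unclassified-only output with a warning.
#'
#' @param env an [envelope()] for one analysis segment.
#' @param peak_cfg a [peak_config()]; default chosen by the envelope method.
#' @param sys_method `"empirical"` (default) or `"acf"`.
#' @return list with `classified` (a [classified_sounds()], removed events
#'   included), `timing` (a `cardiac_timing` or `NULL`) and `peaks`
#'   (the deduplicated [peak_series()]).
#' @export
dispatch <- function(env, peak_cfg = NULL, sys_method = c("empirical", "acf")) {
  sys_method <- match.arg(sys_method)
  if (is.null(peak_cfg)) peak_cfg <- default_peak_config(env$method)

  est <- tryCatch({
    acf <- autocorrelate(env, max_lag_s = 3.2)
    estimate_cycle(acf)
  }, error = function(e) e)

  if (inherits(est, "error")) {
    warning(sprintf("heart-rate estimation failed (%s); segment left unclassified",
                    conditionMessage(est)))
    pk <- tryCatch(
      enforce_separation(local_maxima(env), peak_cfg$min_separation),
      error = function(e) peak_series()
    )
    return(list(
      classified = classified_sounds(pk$times, pk$amplitudes,
                                     rep("unclassified", length(pk$times)),
                                     rep(NA_character_, length(pk$times))),
      timing = NULL, peaks = pk
    ))
  }

  hr <- min(max(est$heart_rate, 40), 200)
  n_thr <- if (hr > 80) peak_cfg$n_high else peak_cfg$n_normal

  pk <- local_maxima(env)
  pk <- apply_threshold(pk, env, n_thr)
  pk <- enforce_separation(pk, peak_cfg$min_separation)

  sys <- if (sys_method == "acf") {
    s <- systole_from_acf(autocorrelate(env), est$cycle)
    if (is.na(s) || s >= 60000 / hr) systole_empirical(hr) else s
  } else {
    systole_empirical(hr)
  }
  timing <- derive_bounds(hr, sys, sys_method = sys_method)

  if (timing$regime == "increased") {
    cls <- classify_increased(pk, timing)
  } else {
    rmv <- remove_extra_peaks(pk, timing)
    cls <- classify_normal(rmv$peaks, timing)
    cls <- classified_sounds(c(cls$time, rmv$removed$time),
                             c(cls$amplitude, rmv$removed$amplitude),
                             c(cls$label, rmv$removed$label),
                             c(cls$rule, rmv$removed$rule))
  }
  list(classified = cls, timing = timing, peaks = pk)
}
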