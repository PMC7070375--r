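# fixture timing: 60 bpm, SYS 300 ms -> sys in (125, 475), dia in (525, 875)

test_that("increased-rate pairing labels by gap and relative amplitude", {
  tm <- derive_bounds(100, 275)            # sys_max = 450 ms
  tm$sys_max <- 450
  cls <- classify_increased(
    peak_series(c(0, 0.30, 0.80, 1.10, 1.60), c(1.0, 0.5, 1.0, 0.5, 1.0)), tm)
  expect_identical(cls$label, c("S1", "S2", "S1", "S2", "S1"))

  # missing S2: the lone S1 is recognised by its long following gap
  cls2 <- classify_increased(
    peak_series(c(0, 0.80, 1.10, 1.60), c(1.0, 1.0, 0.5, 1.0)), tm)
  expect_identical(cls2$label, c("S1", "S1", "S2", "S1"))
  expect_identical(cls2$rule[1], "eq13")

  single <- suppressWarnings(classify_increased(peak_series(1, 1), tm))
  expect_identical(single$label, "unclassified")
})

test_that("pairs are consumed: an S2 is never reused as the next S1", {
  tm <- derive_bounds(100, 275)
  tm$sys_max <- 450
  # descending amplitudes would chain-pair without consumption
  cls <- classify_increased(
    peak_series(c(0, 0.30, 0.60), c(1.0, 0.8, 0.6)), tm)
  expect_identical(cls$label[1:2], c("S1", "S2"))
  expect_false(cls$label[3] == "S2" && cls$label[2] == "S1")
})

test_that("extra peaks inside invalid diastoles are removed (Fig 7 patterns)", {
  tm <- fixture_timing()

  # extra peak mid-diastole between two intact cycles
  r1 <- remove_extra_peaks(
    peak_series(c(0, 0.30, 0.55, 1.00, 1.30), c(1, 1, 0.3, 1, 1)), tm)
  expect_equal(r1$removed$time, 0.55)
  expect_identical(r1$removed$rule, "eq14")
  expect_equal(r1$peaks$times, c(0, 0.30, 1.00, 1.30))

  # extra peak whose following S2 is missing
  r2 <- remove_extra_peaks(
    peak_series(c(0, 0.30, 1.00, 1.30, 1.55, 2.30), c(1, 1, 1, 1, 0.3, 1)), tm)
  expect_equal(r2$removed$time, 1.55)
  expect_identical(r2$removed$rule, "eq15")

  # nothing to remove: output equals input
  clean <- peak_series(c(0, 0.30, 1.00, 1.30, 2.00, 2.30),
                       c(1, 1, 1, 1, 1, 1))
  r3 <- remove_extra_peaks(clean, tm)
  expect_identical(r3$peaks$times, clean$times)
  expect_equal(nrow(r3$removed), 0)
})

test_that("extra peaks shortly before S1 are removed (Fig 8 patterns)", {
  tm <- fixture_timing()

  # valid-looking diastole ending at the extra peak, intact systoles around
  r1 <- remove_extra_peaks(
    peak_series(c(0, 0.30, 0.90, 1.00, 1.30), c(1, 1, 0.3, 1, 1)), tm)
  expect_equal(r1$removed$time, 0.90)
  expect_identical(r1$removed$rule, "eq16")
  expect_equal(r1$peaks$times, c(0, 0.30, 1.00, 1.30))

  # same but with the next S2 missing: systole check skips one position
  r2 <- remove_extra_peaks(
    peak_series(c(0, 0.30, 0.90, 1.00, 2.00, 2.30), c(1, 1, 0.3, 1, 1, 1)), tm)
  expect_equal(r2$removed$time, 0.90)
  expect_identical(r2$removed$rule, "eq17")
  expect_equal(r2$peaks$times, c(0, 0.30, 1.00, 2.00, 2.30))
})

test_that("removal never deletes a peak flanked by valid systoles", {
  tm <- fixture_timing()
  set.seed(33)
  for (rep in 1:20) {
    n_cyc <- sample(3:6, 1)
    onsets <- cumsum(c(0.2, rep(1, n_cyc - 1)))
    times <- sort(c(onsets, onsets + 0.30))
    pk <- peak_series(times, rep(c(1, 0.9), n_cyc))
    out <- remove_extra_peaks(pk, tm)
    expect_equal(nrow(out$removed), 0)
    expect_identical(out$peaks$times, pk$times)
  }
})

test_that("normal-rate classification labels clean and deficient trains", {
  tm <- fixture_timing()

  onsets <- cumsum(c(0, rep(1, 4)))
  clean <- peak_series(sort(c(onsets, onsets + 0.30)), rep(1, 10))
  cls <- classify_normal(clean, tm)
  expect_identical(cls$label, rep(c("S1", "S2"), 5))
  expect_equal(sum(cls$label == "unclassified"), 0)

  # S2 of cycles 2 and 3 absent: their S1 found via double-long gaps
  times <- c(0, 0.30, 1.00, 2.00, 3.00, 3.30)
  cls2 <- classify_normal(peak_series(times, rep(1, 6)), tm)
  expect_identical(cls2$label, c("S1", "S2", "S1", "S1", "S1", "S2"))
  expect_identical(cls2$rule[3], "eq18")

  expect_equal(nrow(classify_normal(peak_series(), tm)), 0)
})

test_that("labelled S1-S2 intervals always lie within the systolic bounds", {
  tm <- fixture_timing()
  set.seed(44)
  for (rep in 1:20) {
    times <- sort(runif(sample(4:10, 1), 0, 6))
    times <- times[c(TRUE, diff(times) >= 0.150)]
    if (length(times) < 2) next
    cls <- classify_normal(peak_series(times, runif(length(times), 0.5, 1)), tm)
    lab <- cls$label
    for (i in seq_len(nrow(cls) - 1)) {
      if (lab[i] == "S1" && lab[i + 1] == "S2") {
        gap <- cls$time[i + 1] - cls$time[i]
        expect_gt(gap, tm$sys_min / 1000)
        expect_lt(gap, tm$sys_max / 1000)
      }
    }
  }
})

test_that("per-segment dispatch classifies generator output end to end", {
  # increased rate, clean: every true S1 peak has a matching S1 label
  g <- generate_pcg(synth_config(duration = 20, heart_rate = 110, seed = 19))
  env <- hilbert_envelope(bandpass(g$pcg, default_filter_config("HT")))
  d <- dispatch(env)
  expect_identical(d$timing$regime, "increased")
  s1 <- d$classified$time[d$classified$label == "S1"]
  truth_in <- g$truth$s1_peak_times[g$truth$s1_peak_times > 0.3 &
                                    g$truth$s1_peak_times < 19.7]
  expect_true(all(vapply(truth_in, function(tt) any(abs(s1 - tt) < 0.075),
                         logical(1))))

  # normal rate with an S3 every cycle: extras removed, S1 intact
  g2 <- generate_pcg(synth_config(duration = 20, heart_rate = 60,
                                  s3_probability = 1, seed = 23))
  env2 <- hilbert_envelope(bandpass(g2$pcg, default_filter_config("HT")))
  d2 <- dispatch(env2)
  expect_identical(d2$timing$regime, "normal")
  expect_gt(sum(d2$classified$label == "removed"), 10)
  s1 <- d2$classified$time[d2$classified$label == "S1"]
  truth_in <- g2$truth$s1_peak_times[g2$truth$s1_peak_times > 0.3 &
                                     g2$truth$s1_peak_times < 19.7]
  expect_true(all(vapply(truth_in, function(tt) any(abs(s1 - tt) < 0.075),
                         logical(1))))

  # silent segment: estimation failure surfaces as unclassified output
  silent <- envelope(rep(0, 8000), 4000, 0, "HT")
  expect_warning(d3 <- dispatch(silent), "unclassified")
  expect_true(all(d3$classified$label %in% "unclassified"))
  expect_null(d3$timing)
})
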