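test_that("generated timing follows the empirical systole relation", {
  g <- generate_pcg(synth_config(duration = 20, heart_rate = 60, noise_sd = 0,
                                 split_probability = 0, s3_probability = 0,
                                 seed = 4))
  n <- length(g$truth$s1_onsets)
  expect_true(n >= 19 && n <= 20)
  expect_equal(mean(diff(g$truth$s1_onsets)), 1.0, tolerance = 0.02)
  # mean systole near -6.58*60 + 766.44 = 371.64 ms, within 3*sd/sqrt(n)
  expect_lt(abs(mean(g$truth$true_sys_lengths) - 371.64),
            3 * 10 / sqrt(n) + 1)
  # conservation per cycle
  cycles <- diff(g$truth$s1_onsets) * 1000
  expect_equal(g$truth$true_sys_lengths[seq_along(cycles)] +
               g$truth$true_dia_lengths[seq_along(cycles)], cycles,
               tolerance = 1e-9)
})

test_that("ground truth is internally consistent and bounded", {
  g <- generate_pcg(synth_config(duration = 25, heart_rate = 75, seed = 9,
                                 s3_probability = 0.3))
  tr <- g$truth
  expect_identical(tr$r_peak_times, tr$s1_onsets)
  ev <- sort(c(tr$s1_peak_times, tr$s2_peak_times))
  expect_identical(ev, as.numeric(rbind(tr$s1_peak_times, tr$s2_peak_times)))
  all_t <- c(tr$s1_onsets, tr$s2_onsets, tr$s1_peak_times, tr$s2_peak_times,
             tr$extra_event_times)
  expect_true(all(all_t >= 0 & all_t <= 25))
})

test_that("amplitude ratio scales S1 against S2 envelope peaks", {
  g <- generate_pcg(synth_config(duration = 15, heart_rate = 60, noise_sd = 0,
                                 amp_ratio_s1_s2 = 2.0, seed = 2))
  env <- hilbert_envelope(g$pcg)
  idx_of <- function(tt) round(tt * env$sampling_rate) + 1L
  s1_amp <- env$values[idx_of(g$truth$s1_peak_times)]
  s2_amp <- env$values[idx_of(g$truth$s2_peak_times)]
  expect_equal(mean(s1_amp / s2_amp), 2.0, tolerance = 0.05)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_pcg(synth_config(duration = 10, noise_sd = 0.2, seed = 11))
  b <- generate_pcg(synth_config(duration = 10, noise_sd = 0.2, seed = 11))
  expect_identical(a$pcg$samples, b$pcg$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_pcg(synth_config(duration = 10, noise_sd = 0.2, seed = 12))
  expect_false(identical(a$pcg$samples, c$pcg$samples))
})

test_that("degenerate durations and invalid configs are rejected", {
  expect_error(generate_pcg(synth_config(duration = 0.5, heart_rate = 60)),
               class = "phonoseg_degenerate_input")
  expect_error(synth_config(heart_rate = 30))
  expect_error(synth_config(s1_center_freq = 10), "20-200")
  expect_error(synth_config(split_probability = 1.5))
})

test_that("synthetic ECG spikes coincide with R-peak times", {
  rec <- make_recording(duration = 12, heart_rate = 60, seed = 5)
  fs <- rec$ecg$sampling_rate
  for (r in rec$truth$r_peak_times) {
    i0 <- round((r - 0.05) * fs) + 1L
    i1 <- round((r + 0.05) * fs) + 1L
    imax <- i0 - 1L + which.max(rec$ecg$samples[i0:i1])
    expect_lt(abs((imax - 1) / fs - r), 1 / fs + 1e-9)
  }
  # spikes at 1.0 and 2.0 s land near samples 500 and 1000 (0-based)
  tr <- structure(list(r_peak_times = c(1, 2)), class = "ground_truth")
  e <- generate_ecg(tr, synth_config(duration = 3))
  expect_equal(which.max(e$samples[400:600]) + 399L, 501L, tolerance = 1)
  expect_equal(which.max(e$samples[900:1100]) + 899L, 1001L, tolerance = 1)
})

test_that("artifact injection modifies waveform and truth as declared", {
  rec <- make_recording(duration = 15, heart_rate = 60, seed = 6)

  # split_s2 on one cycle: that sound becomes two sub-bursts
  sp <- inject_artifacts(rec$pcg, rec$truth, "split_s2",
                         list(cycles = 3, gap_ms = 60))
  env <- hilbert_envelope(sp$pcg)
  t2 <- rec$truth$s2_peak_times[3]
  win <- env$values[round((t2 - 0.08) * 4000):round((t2 + 0.08) * 4000)]
  pk <- local_maxima(envelope(win, 4000, 0, "HT"))
  expect_gte(length(pk$times), 2)
  expect_identical(sp$truth$s2_peak_times, rec$truth$s2_peak_times)

  # s3 injection adds one envelope peak inside that diastole
  s3 <- inject_artifacts(rec$pcg, rec$truth, "s3", list(cycles = 2))
  expect_length(s3$truth$extra_event_times, 1)
  t3 <- s3$truth$extra_event_times[1]
  env0 <- hilbert_envelope(rec$pcg)
  env3 <- hilbert_envelope(s3$pcg)
  i3 <- round(t3 * 4000) + 1L
  expect_gt(env3$values[i3], env0$values[i3] + 0.1)

  # zero-sd white noise leaves the waveform unchanged
  nz <- inject_artifacts(rec$pcg, rec$truth, "white_noise", list(sd = 0))
  expect_identical(nz$pcg$samples, rec$pcg$samples)

  expect_error(inject_artifacts(rec$pcg, rec$truth, "hum"))
})
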