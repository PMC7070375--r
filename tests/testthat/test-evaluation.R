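test_that("R-peak detection round-trips the synthetic ECG", {
  rec <- make_recording(duration = 14, heart_rate = 60, seed = 31)
  r <- detect_r_peaks(rec$ecg)
  expect_length(r, length(rec$truth$r_peak_times))
  expect_lt(max(abs(r - rec$truth$r_peak_times)), 0.002)

  expect_warning(z <- detect_r_peaks(timed_signal(numeric(2000), 500)), "flat")
  expect_length(z, 0)

  # two spikes 100 ms apart: refractory keeps one
  fs <- 500
  x <- numeric(3 * fs)
  for (tt in c(1.0, 1.1)) {
    i <- round(tt * fs) + 1L
    x[(i - 5):(i + 5)] <- dnorm(-5:5, sd = 2)
  }
  expect_length(detect_r_peaks(timed_signal(x, fs)), 1)
})

test_that("tolerance-window matching produces the documented counts", {
  cfg <- eval_config(0.150)
  cls <- function(times, labels) classified_sounds(times, rep(1, length(times)),
                                                   labels, rep(NA, length(times)))
  c1 <- match_s1(cls(c(1.00, 2.00), c("S1", "S1")), c(1.01, 2.02), cfg)
  expect_equal(c(c1$tp, c1$fp, c1$fn), c(2, 0, 0))

  c2 <- match_s1(cls(1.00, "S1"), c(1.20, 2.00), cfg)
  expect_equal(c(c2$tp, c2$fp, c2$fn), c(0, 1, 2))

  c3 <- match_s1(cls(numeric(0), character(0)), numeric(0), cfg)
  expect_equal(c(c3$tp, c3$fp, c3$fn, c3$tn), c(0, 0, 0, 0))

  # one-to-one: two S1 inside one window yield one tp, one fp
  c4 <- match_s1(cls(c(1.00, 1.05), c("S1", "S1")), 1.02, cfg)
  expect_equal(c(c4$tp, c4$fp, c4$fn), c(1, 1, 0))

  # non-S1 events outside every window are true negatives
  c5 <- match_s1(cls(c(1.00, 1.40), c("S1", "S2")), 1.00, cfg)
  expect_equal(c5$tn, 1)
})

test_that("matching accounts for every reference window", {
  set.seed(51)
  for (rep in 1:20) {
    r <- sort(runif(sample(0:15, 1), 0, 20))
    s <- sort(runif(sample(0:15, 1), 0, 20))
    cc <- match_s1(classified_sounds(s, rep(1, length(s)),
                                     rep("S1", length(s)), rep(NA, length(s))),
                   r, eval_config())
    expect_equal(cc$tp + cc$fn, length(r))
    expect_equal(cc$tp + cc$fp, length(s))
  }
})

test_that("metrics follow their defining ratios and handle 0/0 as undefined", {
  m <- compute_metrics(list(tp = 9, fp = 1, fn = 1, tn = 9))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$f1, 0.9)

  # harmonic-mean identity at a published-style operating point
  f1 <- 2 * 0.951 * 0.965 / (0.951 + 0.965)
  expect_equal(f1, 0.958, tolerance = 0.0015)
  mm <- compute_metrics(list(tp = 951, fp = 34, fn = 49, tn = 0))
  expect_equal(mm$f1, 2 * mm$precision * mm$sensitivity /
                 (mm$precision + mm$sensitivity))

  z <- compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(is.na(z$sensitivity) && is.na(z$precision) && is.na(z$f1))
})

test_that("grid search scores points by mean F1 and prefers the signal band", {
  rec <- make_recording(duration = 20, heart_rate = 60, noise_sd = 0.3, seed = 41)
  corpus <- list(list(pcg = rec$pcg, ecg = rec$ecg))
  base <- run_config("HT")

  one <- grid_optimize(corpus, data.frame(n_normal = 1.9), base)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$best$n_normal, 1.9)
  expect_true(is.finite(one$best_f1))

  # cutoffs bracketing the 60/90 Hz sound band beat cutoffs excluding it
  grid <- data.frame(f_lower = c(40, 300), f_upper = c(190, 500))
  two <- suppressWarnings(grid_optimize(corpus, grid, base))
  expect_equal(two$best$f_lower, 40)
  expect_gt(two$table$mean_f1[1], two$table$mean_f1[2])

  again <- suppressWarnings(grid_optimize(corpus, grid, base))
  expect_identical(two$table$mean_f1, again$table$mean_f1)

  expect_error(grid_optimize(list(), grid), "empty corpus")
  expect_error(grid_optimize(corpus, data.frame()), "empty grid")
})
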