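# independent reference for the timing equations, coded separately from the
# package implementation
ref_sys <- function(hr) if (hr > 80) -1.14 * hr + 371.55 else -6.58 * hr + 766.44
ref_bounds <- function(hr, sys) {
  cyc <- 60 * 1000 / hr
  list(dia = cyc - sys, sys_min = sys - 175, sys_max = sys + 175,
       dia_max = cyc - (sys - 175), dia_min = cyc - (sys + 175))
}

test_that("ACF of a periodic envelope peaks at multiples of the period", {
  fs <- 100
  v <- numeric(10 * fs)
  v[seq(1, length(v), by = fs)] <- 1        # impulse train, period 1 s
  a <- autocorrelate(envelope(v, fs, 0, "HT"))
  pk <- a$lags[a$values > 0.5]
  expect_true(all(abs(pk - round(pk)) < 1e-9))
  expect_true(all(c(0, 1, 2) %in% round(pk)))
  expect_equal(a$values[1], 1)
  expect_true(all(a$values <= 1 + 1e-12))
})

test_that("white-noise ACF is a delta at lag zero", {
  set.seed(5)
  a <- autocorrelate(timed_signal(rnorm(4000), 1000))
  expect_equal(a$values[1], 1)
  expect_lt(max(abs(a$values[-(1:2)])), 0.1)
})

test_that("FFT autocorrelation equals the direct O(N^2) sum", {
  set.seed(8)
  v <- rnorm(500)
  a <- autocorrelate(timed_signal(v, 500))
  ref <- direct_acf(v, length(a$lags) - 1L)
  expect_lt(max(abs(a$values - ref)) / max(abs(ref)), 1e-9)
})

test_that("constant envelope has no autocorrelation", {
  expect_error(autocorrelate(envelope(rep(2, 100), 100, 0, "HT")),
               class = "phonoseg_degenerate_input")
})

test_that("cycle estimation recovers the generator's heart rate", {
  for (hr in c(60, 100)) {
    g <- generate_pcg(synth_config(duration = 20, heart_rate = hr, seed = hr))
    env <- hilbert_envelope(bandpass(g$pcg, default_filter_config("HT")))
    est <- estimate_cycle(autocorrelate(env, max_lag_s = 3.2))
    expect_lt(abs(est$cycle - 60000 / hr), if (hr == 60) 20 else 15)
    expect_lt(abs(est$heart_rate - hr), 1.5)
  }
})

test_that("a period beyond the 1.5 s search window is an estimation failure", {
  fs <- 100
  v <- rep(0, 12 * fs)
  centres <- seq(0.8, 11, by = 1.6) * fs    # period 1.6 s -> under 40 bpm
  for (c0 in centres) v[(c0 - 5):(c0 + 5)] <- dnorm(-5:5, sd = 2)
  expect_error(estimate_cycle(autocorrelate(envelope(v, fs, 0, "HT"))),
               class = "phonoseg_estimation_failure")
})

test_that("systole from the ACF minor maximum matches burst spacing", {
  fs <- 200
  v <- numeric(10 * fs)
  gauss <- dnorm(seq(-0.05, 0.05, by = 1 / fs), sd = 0.015)
  stamp <- function(at) {
    i <- round(at * fs) + 1L
    v[i:(i + length(gauss) - 1L)] <<- v[i:(i + length(gauss) - 1L)] + gauss
  }
  for (k in 0:8) { stamp(k + 0.2); stamp(k + 0.5) }   # bursts 0.3 s apart
  a <- autocorrelate(envelope(v, fs, 0, "HT"))
  est <- estimate_cycle(a)
  expect_equal(est$cycle, 1000, tolerance = 0.02)
  expect_equal(systole_from_acf(a, est$cycle), 300, tolerance = 0.05)

  # single burst per cycle: no minor maximum, fallback signalled
  v2 <- numeric(10 * fs)
  v <- v2
  for (k in 0:8) stamp(k + 0.2)
  a2 <- autocorrelate(envelope(v, fs, 0, "HT"))
  expect_warning(s <- systole_from_acf(a2, 1000), "empirical")
  expect_true(is.na(s))
})

test_that("empirical systole matches the linear relation on both branches", {
  expect_equal(systole_empirical(100), 257.55)
  expect_equal(systole_empirical(60), 371.64)
  expect_equal(systole_empirical(80), 240.04)  # boundary uses low-rate branch
  expect_error(systole_empirical(30), "range")
  expect_error(systole_empirical(250), "range")
  # strictly decreasing within each branch
  lo <- vapply(seq(40, 80, by = 2), systole_empirical, numeric(1))
  hi <- vapply(seq(81, 200, by = 2), systole_empirical, numeric(1))
  expect_true(all(diff(lo) < 0) && all(diff(hi) < 0))
})

test_that("timing bounds obey the tolerance and conservation identities", {
  tm <- derive_bounds(60, 371.64)
  expect_equal(tm$dia, 628.36)
  expect_equal(tm$sys_min, 196.64)
  expect_equal(tm$sys_max, 546.64)
  expect_equal(tm$dia_min, 453.36)
  expect_equal(tm$dia_max, 803.36)
  expect_identical(tm$regime, "normal")

  tm2 <- derive_bounds(120, systole_empirical(120))
  expect_equal(tm2$sys, 234.75)
  expect_equal(tm2$dia, 265.25)
  expect_identical(tm2$regime, "increased")

  expect_identical(derive_bounds(80, systole_empirical(80))$regime, "normal")

  set.seed(17)
  for (hr in runif(100, 40, 200)) {
    sys <- ref_sys(hr)
    tm <- derive_bounds(hr, sys)
    rb <- ref_bounds(hr, sys)
    expect_equal(tm$sys_max - tm$sys_min, 350)
    expect_lt(abs(tm$sys + tm$dia - 60000 / hr), 1e-6)
    expect_lt(abs(tm$sys_min + tm$dia_max - 60000 / hr), 1e-6)
    expect_lt(abs(tm$sys_max + tm$dia_min - 60000 / hr), 1e-6)
    for (f in c("dia", "sys_min", "sys_max", "dia_min", "dia_max")) {
      expect_equal(tm[[f]], rb[[f]])
    }
  }
  expect_error(derive_bounds(60, 1200), "below the cycle")
})
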