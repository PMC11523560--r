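test_that("median window is the largest odd sample count in the duration", {
  expect_identical(median_window_samples(0.5, 3000), 1499L)
  expect_identical(median_window_samples(0.5, 100), 49L)
  expect_identical(median_window_samples(1.0, 3001), 3001L)
  expect_error(median_window_samples(0.0001, 100), "shorter")
})

make_burst_emg <- function(rate = 2000, dur = 4, f = 120, seed = 2) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / rate)[-1]
  env <- exp(-((t - dur / 2)^2) / 0.5)     # symmetric burst
  x <- env * sin(2 * pi * f * t) + rnorm(length(t), 0, 0.01)
  raw_emg(cbind(bra = x, tri = x, bic = x, brd = x), rate)
}

test_that("the envelope chain is DC-invariant, bounded, and 300 long", {
  raw <- make_burst_emg()
  settings <- envelope_settings()
  env <- emg_envelope(raw, settings)
  peaks <- apply(env$values, 2, max)
  out <- process_emg(raw, settings, subject_peak = peaks)
  expect_equal(nrow(out$values), 300)
  expect_true(all(out$values >= 0 & out$values <= 1))
  # the peak-defining trial reaches 1 after normalization by its own peak
  expect_equal(max(out$values), 1, tolerance = 1e-9)

  shifted <- raw_emg(raw$signals + 5, raw$rate)
  out2 <- process_emg(shifted, settings, subject_peak = peaks)
  expect_equal(out$values, out2$values, tolerance = 1e-8)
})

test_that("sub-band content is suppressed relative to in-band content", {
  rate <- 3000
  t <- seq(0, 4, by = 1 / rate)[-1]
  lo <- sin(2 * pi * 1 * t)     # below the 10 Hz bandpass edge
  hi <- sin(2 * pi * 100 * t)   # inside the band
  raw <- raw_emg(cbind(bra = lo, tri = hi, bic = hi, brd = hi), rate)
  env <- emg_envelope(raw, envelope_settings())
  mid <- seq(floor(0.25 * nrow(env$values)), floor(0.75 * nrow(env$values)))
  expect_lt(mean(env$values[mid, "bra"]), 0.01 * mean(env$values[mid, "tri"]))
})

test_that("positive scaling commutes with envelope extraction", {
  raw <- make_burst_emg()
  env1 <- emg_envelope(raw, envelope_settings())
  env3 <- emg_envelope(raw_emg(3 * raw$signals, raw$rate),
                       envelope_settings())
  expect_equal(env3$values, 3 * env1$values, tolerance = 1e-8)
})

test_that("zero-phase filtering leaves a symmetric burst's peak in place", {
  # a causal 4th-order 5 Hz lowpass would lag by tens of milliseconds; the
  # forward-backward filter must keep the burst peak within a few samples
  # (rectification ripple limits argmax resolution)
  raw <- make_burst_emg(seed = 7)
  env <- emg_envelope(raw, envelope_settings())
  n <- nrow(raw$signals)
  # the running median flattens the peak into a plateau; its center is the
  # latency estimate
  v <- env$values[, 1]
  plateau <- which(v > max(v) - 1e-12)
  expect_lte(abs(mean(plateau) - (n + 1) / 2), 10)
})

test_that("signals shorter than the median window are rejected", {
  short <- raw_emg(matrix(rnorm(400 * 4), 400, 4), 3000)
  expect_error(emg_envelope(short, envelope_settings()), "median")
})

test_that("SAD window selection follows the table and the elbow rule", {
  const <- rep(1, 500)
  sel <- select_smoothing_window(const)
  expect_identical(as.integer(sel), 5L)
  tab <- attr(sel, "sad_table")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$window, seq(5, 50, by = 5))
  expect_true(all(tab$sad == 0))

  set.seed(1)
  for (i in 1:20) {
    noise <- rnorm(5000)
    sadtab <- attr(select_smoothing_window(noise), "sad_table")
    expect_true(all(diff(sadtab$sad) < 0))  # variance-of-mean shrinks
  }

  # a signal already smooth at small windows trips the elbow before 25
  smooth <- sin(seq(0, 2 * pi, length.out = 2000))
  sel2 <- select_smoothing_window(smooth)
  expect_lte(as.integer(sel2), 25L)
  expect_error(select_smoothing_window(rnorm(10), candidates = 20), "smaller")
})

test_that("moving average has the textbook impulse response and bounds", {
  const <- activation_trace(1:300, matrix(0.7, 300, 1))
  expect_equal(prepare_for_simulation(const)$values,
               const$values, tolerance = 1e-12)

  x <- rep(0, 300)
  x[150] <- 1
  sm <- moving_average(x, 25)
  expect_equal(sm[138:162], rep(1 / 25, 25), tolerance = 1e-12)
  expect_true(all(abs(sm[-(138:162)]) < 1e-12))

  set.seed(2)
  act <- activation_trace(1:300, matrix(runif(300), 300, 1))
  out <- prepare_for_simulation(act)
  expect_lte(max(out$values), max(act$values))
  expect_error(prepare_for_simulation(act, window = 0), "at least 1")
})

test_that("raw EMG CSV round-trips with its rate", {
  raw <- make_burst_emg(rate = 500, dur = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_emg_csv(raw, path)
  back <- read_raw_emg_csv(path)
  expect_equal(back$rate, 500)
  expect_equal(back$signals, raw$signals, tolerance = 1e-6)
})
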