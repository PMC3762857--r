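test_that("trial files round-trip field-by-field", {
  set.seed(7)
  st <- generate_walking(gait_profile(seed = 7), duration_s = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(st$trial, path)
  back <- read_trial(path)
  for (ch in c("gyro", "fsr_heel", "fsr_m1", "fsr_m5")) {
    expect_equal(back[[ch]]$rate_hz, st$trial[[ch]]$rate_hz)
    expect_equal(back[[ch]]$values, st$trial[[ch]]$values, tolerance = 1e-9)
  }
  expect_equal(back$meta$task, st$trial$meta$task)
})

test_that("a 60 s 200 Hz trial writes 12000 FSR rows", {
  st <- generate_walking(gait_profile(seed = 3), duration_s = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(st$trial, path)
  rows <- readLines(path)
  rows <- rows[!startsWith(rows, "#")]
  expect_equal(length(rows) - 1L, 12000L)  # minus the column header
})

test_that("read_trial rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,gyro_y,fsr_h,fsr_m1", "0,1,0,0"), path)
  expect_error(read_trial(path), "format error.*fsr_m5")
  writeLines(c("time,gyro_y,fsr_h,fsr_m1,fsr_m5",
               "0,1,0,0,0", "0.01,1,0,0,0", "0.005,1,0,0,0"), path)
  expect_error(read_trial(path), "data error.*time")
  writeLines(character(0), path)
  expect_error(read_trial(path), "data error|empty")
  expect_error(read_trial(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("gait_trial enforces channel invariants", {
  g <- sampled_signal(rnorm(50), 50, units = "deg/s")
  f <- function(n, r = 200) sampled_signal(runif(n), r, units = "V")
  expect_error(gait_trial(g, f(196), f(196), f(100)), "length")
  expect_error(gait_trial(g, f(196), f(196, 100), f(196)), "rate")
  expect_error(gait_trial(g, f(500), f(500), f(500)), "span")
  expect_s3_class(gait_trial(g, f(197), f(197), f(197)), "gait_trial")
})

test_that("resample_to preserves constants, ramps and endpoints", {
  const <- sampled_signal(rep(3.2, 51), 50)
  up <- resample_to(const, 200)
  expect_equal(up$rate_hz, 200)
  expect_true(all(up$values == 3.2))

  ramp <- sampled_signal(seq(0, 1, length.out = 51), 50)  # 1 s ramp
  up <- resample_to(ramp, 200)
  expect_equal(length(up), 201L)
  expect_identical(up$values[1], 0)
  expect_identical(up$values[201], 1)
  expect_equal(up$values, seq(0, 1, length.out = 201), tolerance = 1e-12)

  expect_error(resample_to(sampled_signal(1, 50), 200), "single-sample")
})

test_that("resampled 2 Hz sine stays within the linear-interpolation bound", {
  f <- 2; rate <- 50
  t50 <- seq(0, 1, by = 1 / rate)
  s <- sampled_signal(sin(2 * pi * f * t50), rate)
  up <- resample_to(s, 200)
  t200 <- signal_times(up)
  bound <- (2 * pi * f / rate)^2 / 8  # max curvature error of linear interp
  expect_lt(max(abs(up$values - sin(2 * pi * f * t200))), bound)
})

test_that("double resampling is exact on signals linear in time", {
  for (rates in list(c(200, 50), c(120, 80), c(75, 300))) {
    lin <- sampled_signal(2.5 * (0:100) / 100 - 1, 100)
    back <- resample_to(resample_to(lin, rates[1]), 100)
    expect_equal(back$values[seq_along(lin$values)], lin$values, tolerance = 1e-10)
  }
})

test_that("lowpass has unit DC gain and preserves zeros in both modes", {
  for (mode in c("zero_phase", "causal")) {
    const <- sampled_signal(rep(-4.7, 400), 200)
    expect_equal(lowpass(const, 15, mode)$values, rep(-4.7, 400), tolerance = 1e-9)
    zeros <- sampled_signal(rep(0, 400), 200)
    expect_identical(lowpass(zeros, 15, mode)$values, rep(0, 400))
  }
  expect_error(lowpass(sampled_signal(rnorm(10), 200), 100), "Nyquist")
})

test_that("zero-phase attenuation at 24 Hz matches the squared Butterworth response", {
  # digital Butterworth closed form (bilinear transform prewarps the axis):
  # |H(f)|^2 = 1 / (1 + (tan(pi f/fs) / tan(pi fc/fs))^(2n));
  # the forward-backward pass applies |H|^2 to the amplitude
  rate <- 200; fc <- 15; f <- 24; n_ord <- 4
  t <- seq(0, 10, by = 1 / rate)
  s <- sampled_signal(sin(2 * pi * f * t), rate)
  y <- lowpass(s, fc, "zero_phase", order = n_ord)$values
  idx <- 401:1600  # steady-state region, an integer number of periods
  # project onto the in-phase quadrature (zero-phase filter keeps phase)
  amp <- 2 * mean(y[idx] * sin(2 * pi * f * t[idx]))
  expected <- 1 / (1 + (tan(pi * f / rate) / tan(pi * fc / rate))^(2 * n_ord))
  expect_equal(amp, expected, tolerance = 1e-6)
  # quadrature leakage would indicate phase distortion
  expect_lt(abs(2 * mean(y[idx] * cos(2 * pi * f * t[idx]))), 1e-9)
})

test_that("lowpass is linear and zero_phase introduces no lag", {
  set.seed(11)
  x <- sampled_signal(rnorm(600), 200)
  y <- sampled_signal(rnorm(600), 200)
  lhs <- lowpass(sampled_signal(2 * x$values - 3 * y$values, 200), 15)$values
  rhs <- 2 * lowpass(x, 15)$values - 3 * lowpass(y, 15)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)

  t <- seq(0, 3, by = 1 / 200)  # band-limited (< 15 Hz) test signal
  s <- sampled_signal(sin(2 * pi * 4 * t) + 0.5 * sin(2 * pi * 9 * t), 200)
  out <- lowpass(s, 15)$values
  cc <- stats::ccf(s$values, out, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("streaming causal filter equals the batch causal filter", {
  set.seed(5)
  x <- rnorm(300)
  batch <- lowpass(sampled_signal(x, 200), 15, "causal")$values
  step <- lowpass_stream(15, 200)
  streamed <- vapply(x, step, numeric(1))
  expect_equal(streamed, batch, tolerance = 1e-12)
})
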