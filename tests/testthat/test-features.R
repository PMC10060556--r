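sine_ts <- function(m = 10, a = 1, T = 0.8, rate = 1000, n_cycles = 3) {
  t <- seq(0, n_cycles * T, by = 1 / rate)
  timeseries(t, m + a * sin(2 * pi * t / T), "Pa")
}

test_that("cycle features of degenerate and sinusoidal cycles are exact", {
  t <- seq(0, 2, by = 1e-3)
  const <- timeseries(t, rep(10, length(t)), "Pa")
  cf <- extract_cycle(const, 0.5, 0.8)
  expect_equal(cf$maximum, 10); expect_equal(cf$minimum, 10)
  expect_equal(cf$amplitude, 0); expect_equal(cf$PI, 0)
  expect_equal(cf$RI, 0); expect_equal(cf$MMR, 1)
  expect_equal(cf$min_to_max_time, 0)

  cf <- extract_cycle(sine_ts(), 0.8, 0.8)
  expect_equal(cf$PI, 0.2, tolerance = 1e-4)
  expect_equal(cf$RI, 2 / 11, tolerance = 1e-4)
  expect_equal(cf$MMR, 1.1, tolerance = 1e-4)
  expect_equal(cf$min_to_max_time, 0.4, tolerance = 2e-3)
  expect_equal(cf$mean, 10, tolerance = 1e-5)
})

test_that("min-to-max time wraps when the maximum precedes the minimum", {
  # phase chosen so the cycle window catches the max first
  t <- seq(0, 3.2, by = 1e-3)
  v <- 10 + sin(2 * pi * (t + 0.25) / 0.8)
  ts <- timeseries(t, v, "Pa")
  cf <- extract_cycle(ts, 0.8, 0.8)
  # rising limb is still half a period
  expect_equal(cf$min_to_max_time, 0.4, tolerance = 2e-3)
})

test_that("PI = RI * MMR on analytic and simulated cycles", {
  cf <- extract_cycle(sine_ts(m = 7, a = 2.3), 0.8, 0.8)
  expect_equal(cf$PI, cf$RI * cf$MMR, tolerance = 1e-12)
  sim <- normal_sim()
  f <- features(sim)
  expect_equal(f$PI, f$RI * f$MMR, tolerance = 1e-10)
})

test_that("features are scale-equivariant and respond to offsets correctly", {
  base <- sine_ts(m = 12, a = 3)
  cf0 <- extract_cycle(base, 0.8, 0.8)
  for (k in c(0.5, 2, 7.3)) {
    scaled <- timeseries(base$t, k * base$v, "Pa")
    cf <- extract_cycle(scaled, 0.8, 0.8)
    expect_equal(cf$maximum, k * cf0$maximum, tolerance = 1e-12)
    expect_equal(cf$mean, k * cf0$mean, tolerance = 1e-12)
    expect_equal(cf$amplitude, k * cf0$amplitude, tolerance = 1e-12)
    expect_equal(cf$PI, cf0$PI, tolerance = 1e-12)
    expect_equal(cf$RI, cf0$RI, tolerance = 1e-12)
    expect_equal(cf$MMR, cf0$MMR, tolerance = 1e-12)
    expect_equal(cf$min_to_max_time, cf0$min_to_max_time)
  }
  for (off in c(1, 10)) {
    shifted <- timeseries(base$t, base$v + off, "Pa")
    cf <- extract_cycle(shifted, 0.8, 0.8)
    expect_equal(cf$amplitude, cf0$amplitude, tolerance = 1e-12)
    expect_equal(cf$min_to_max_time, cf0$min_to_max_time)
    expect_lt(cf$PI, cf0$PI)
    expect_lt(cf$RI, cf0$RI)
    expect_lt(cf$MMR, cf0$MMR)
  }
})

test_that("feature extraction errors on bad windows and non-positive means", {
  ts <- sine_ts(n_cycles = 1)
  expect_error(extract_cycle(ts, 0.5, 0.8), "cover")
  neg <- timeseries(ts$t, ts$v - 100, "Pa")
  expect_error(extract_cycle(neg, 0, 0.8), "non-positive")
})

test_that("features are robust to the sampling rate", {
  # smooth pulse-like waveform: fundamental plus damped harmonics
  mk <- function(rate) {
    t <- seq(0, 2.4, by = 1 / rate)
    v <- 2000 + 300 * sin(2 * pi * t / 0.8) + 90 * sin(4 * pi * t / 0.8 + 1) +
      25 * sin(6 * pi * t / 0.8 + 2)
    timeseries(t, v, "Pa")
  }
  f1 <- extract_cycle(mk(1000), 0.8, 0.8)
  f2 <- extract_cycle(mk(2000), 0.8, 0.8)
  for (nm in c("maximum", "minimum", "mean", "amplitude", "PI", "RI", "MMR")) {
    expect_lt(abs(f1[[nm]] - f2[[nm]]) / abs(f2[[nm]]), 5e-3)
  }
  expect_lt(abs(f1$min_to_max_time - f2$min_to_max_time), 1.5e-3)
})

test_that("relative difference tables follow their contract", {
  cf1 <- extract_cycle(sine_ts(), 0.8, 0.8)
  rd <- relative_difference_table(list(a = cf1, b = cf1))
  expect_equal(rd$rel_diff_pct, rep(0, 4))
  expect_setequal(rd$feature, c("min_to_max_time", "PI", "RI", "MMR"))
  cf2 <- cf1; cf2$PI <- 0.101; cf1$PI <- 0.100
  rd <- relative_difference_table(list(a = cf1, b = cf2), features = "PI")
  expect_equal(rd$rel_diff_pct, 1, tolerance = 1e-9)
})
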