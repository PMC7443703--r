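test_that("notch filter attenuates line frequencies and spares the passband", {
  fs <- 2400
  t <- seq(1 / fs, 30, by = 1 / fs)
  x50 <- sin(2 * pi * 50 * t)
  expect_lt(stats::sd(notch_filter(x50, 50, 50, fs = fs)) / stats::sd(x50),
            0.03)
  x12 <- sin(2 * pi * 12 * t)
  y12 <- notch_filter(x12, 50, 550, fs = fs)
  expect_lt(abs(20 * log10(stats::sd(y12) / stats::sd(x12))), 0.5)
  # ripple just outside +/- 1 Hz of a notch centre
  x <- sin(2 * pi * 51.2 * t)
  expect_lt(abs(20 * log10(stats::sd(notch_filter(x, 50, 550, fs = fs)) /
                             stats::sd(x))), 0.5)
  expect_message(notch_filter(x50, 50, 5000, fs = fs), "Nyquist")
  expect_error(notch_filter(x50, 1300, 1300, fs = fs), "Nyquist")
})

test_that("notch filter applies per channel on recordings", {
  arr <- small_arr()
  fs <- 1200
  t <- seq(1 / fs, 30, by = 1 / fs)
  dat <- rbind(sin(2 * pi * 50 * t), sin(2 * pi * 20 * t))
  dat <- dat[rep(1:2, 16), ] * 1e-12
  rec <- recording(dat, fs, arr, "dsmw")
  out <- notch_filter(rec, 50, 50)
  expect_s3_class(out, "recording")
  expect_lt(stats::sd(out$data[1, ]), 0.03 * stats::sd(dat[1, ]))
  expect_gt(stats::sd(out$data[2, ]), 0.99 * stats::sd(dat[2, ]))
})

test_that("downsampling is anti-aliased, length-exact and ratio-checked", {
  fs <- 19200
  t <- seq(1 / fs, 4, by = 1 / fs)
  x <- sin(2 * pi * 500 * t)
  y <- downsample(x, 2400, fs = fs)
  expect_equal(length(y), length(x) %/% 8)
  amp <- stats::sd(y) * sqrt(2)
  expect_equal(amp, 1, tolerance = 0.01)   # 500 < 0.4 * 2400
  expect_error(downsample(x, 7000, fs = fs), "integer multiple")
  # identity when rates match
  arr <- small_arr()
  rec <- recording(matrix(rnorm(32 * 100), 32), 100, arr, "dsmw")
  expect_identical(downsample(rec, 100), rec)
})

test_that("Welch PSD: scaling, window count and peak concentration", {
  fs <- 100
  expect_equal(welch_psd(rnorm(216 * fs), fs = fs)$n_windows,
               2 * 216 / 4 - 1)
  set.seed(11)
  w <- welch_psd(rnorm(120 * fs), fs = fs)
  df <- w$freqs[2] - w$freqs[1]
  expect_equal(df, 0.25)
  expect_equal(sum(w$power) * df, 1, tolerance = 0.05)  # Parseval
  expect_equal(drop(welch_psd(numeric(1000), fs = 100)$power),
               rep(0, 201))
  t <- seq(1 / fs, 60, by = 1 / fs)
  s <- welch_psd(sin(2 * pi * 12 * t), fs = fs)
  pk <- which.max(drop(s$power))
  expect_equal(s$freqs[pk], 12)
  expect_gt(sum(s$power[1, (pk - 1):(pk + 1)]) / sum(s$power), 0.95)
  expect_error(welch_psd(rnorm(100), fs = 100), "shorter")
  # per-window power: mean over windows equals the estimate
  wk <- welch_psd(matrix(rnorm(2 * 3000), 2), fs = 100, keep_windows = TRUE)
  expect_equal(apply(wk$per_window_power, 1:2, mean), wk$power)
})

test_that("band log power averages log10 power over the selected bins", {
  sp <- structure(
    list(freqs = seq(0, 50, by = 0.25),
         power = matrix(1, 2, 201), n_windows = 10),
    class = "spectrum_estimate")
  expect_equal(band_log_power(sp, c(1, 15))$pi, c(0, 0))
  sp$power[] <- 100
  expect_equal(band_log_power(sp, c(1, 15))$pi, c(2, 2))
  # union band excludes the gap's bins exactly
  movement <- band_spec(c(1, 15), exclude = c(11.5, 12.5))
  n_full <- band_log_power(sp, band_spec(c(1, 15)))$n_bins
  n_gap <- band_log_power(sp, band_spec(c(11.5, 12.5)))$n_bins
  expect_equal(band_log_power(sp, movement)$n_bins, n_full - n_gap)
  # channel-order invariance
  sp$power <- rbind(10^seq(-1, 1, length.out = 201),
                    10^seq(1, -1, length.out = 201))
  pi1 <- band_log_power(sp, c(5, 20))$pi
  sp$power <- sp$power[2:1, ]
  expect_equal(band_log_power(sp, c(5, 20))$pi, pi1[2:1])
  expect_error(band_log_power(sp, c(60, 70)), "overlap")
})
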