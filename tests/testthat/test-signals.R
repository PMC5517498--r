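test_that("recordings enforce their invariants", {
  expect_error(recording(matrix(c(1, NaN), 1), fs = 500), "NaN")
  expect_error(recording(matrix(c(1, Inf), 1), fs = 500), "NaN")
  expect_error(recording(matrix(1:4, 2), fs = 0), "positive")

  rec <- recording(seq_len(500) * 1.0, fs = 500)
  expect_equal(duration(rec), 1.0)
  expect_equal(n_channels(rec), 1L)
  expect_equal(rec$channel_labels, "ch01")

  expect_equal(ms_to_samples(300, 500), 150L)
  expect_equal(ms_to_samples(50, 500), 25L)
  expect_equal(ms_to_samples(333, 500), 166L)  # base-R round convention
})

test_that("delimited write/read round trip is exact", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  m <- matrix(rnorm(3 * 40), nrow = 3)
  rec <- recording(m, fs = 250, channel_labels = c("a", "b", "c"))
  write_recording(rec, path, sidecar = TRUE)
  back <- read_recording(path, fs = 250)
  expect_identical(back$samples, m)
  expect_true(file.exists(paste0(path, ".json")))

  expect_error(read_recording(path), "fs must be supplied")
  expect_error(read_recording(tempfile(), fs = 1), "not found")
})

test_that("downsampling preserves duration and spectral content", {
  spec <- synthetic_spec("pure_sine_noise", carrier_freq = 10,
                         noiseless = TRUE, duration = 4, fs = 2000, seed = 1)
  rec <- make_pure_sine_noise(spec)
  down <- downsample(rec, 500)
  expect_equal(down$fs, 500)
  expect_equal(n_samples(down), n_samples(rec) / 4)
  expect_lte(abs(duration(down) - duration(rec)), 1 / 500)

  # dominant frequency survives decimation within one interpolated bin
  est <- estimate_dominant(down$samples[1, 501:1000], fs = 500)
  expect_lte(abs(est$dominant_freq - 10), 0.05)

  expect_identical(downsample(rec, 2000)$samples, rec$samples)
  expect_error(downsample(rec, 4000), "must not exceed")
  expect_error(downsample(rec, 300), "divide")
})

test_that("sine-plus-noise generator is deterministic and on-spec", {
  spec <- synthetic_spec("pure_sine_noise", snr = 1, duration = 2, seed = 42)
  r1 <- make_pure_sine_noise(spec)
  r2 <- make_pure_sine_noise(spec)
  expect_identical(r1$samples, r2$samples)

  # noiseless sine values at known times (A = 1, 10 Hz, fs 500)
  clean <- noiseless_rec(duration = 1)
  expect_equal(clean$samples[1, 1], 0)
  # half-period antisymmetry of the 10 Hz sine (50 ms = 25 samples)
  expect_equal(clean$samples[1, 26:50], -clean$samples[1, 1:25])
  expect_gte(max(clean$samples), 0.998)  # peak falls between sample times
})

test_that("realized SNR matches the requested ratio within 5%", {
  for (snr in c(0.1, 1, 10)) {
    rec <- make_pure_sine_noise(synthetic_spec("pure_sine_noise", snr = snr,
                                               duration = 60, seed = 7))
    got <- measure_snr(attr(rec, "signal_part"), attr(rec, "noise_part"))
    expect_lte(abs(got$ratio - snr) / snr, 0.05)
  }
})

test_that("measure_snr follows its definition", {
  x <- rnorm(100)
  same <- measure_snr(x, x)
  expect_equal(same$ratio, 1)
  expect_equal(same$db, 0)

  # sine of amplitude A against unit-variance noise: ratio ~ A^2 / 2
  set.seed(3)
  a <- 3
  sine <- a * sin(2 * pi * 7 * (0:59999) / 500)
  noise <- rnorm(60000)
  expect_lte(abs(measure_snr(sine, noise)$ratio - a^2 / 2) / (a^2 / 2), 0.05)

  expect_equal(measure_snr(sqrt(10) * x, x)$db, 10)
  expect_error(measure_snr(x, numeric(100)), "zero power")
  expect_error(measure_snr(x, rnorm(50)), "equal length")
})

test_that("eeg-like generator is deterministic with controlled drift", {
  spec <- synthetic_spec("eeg_like", drift_std = 0.3, duration = 5, seed = 9)
  r1 <- make_eeg_like(spec)
  r2 <- make_eeg_like(spec)
  expect_identical(r1$samples, r2$samples)

  # the realized instantaneous-frequency spread tracks drift_std
  f <- attr(r1, "inst_freq")
  expect_gt(sd(f), 0.1)
  still <- make_eeg_like(synthetic_spec("eeg_like", drift_std = 0,
                                        duration = 5, seed = 9))
  expect_equal(sd(attr(still, "inst_freq")), 0)

  # in-band SNR calibration: oscillation vs background power in carrier +/- 2.5 Hz
  rec <- make_eeg_like(synthetic_spec("eeg_like", snr = 4, drift_std = 0.1,
                                      duration = 30, seed = 5))
  bg <- attr(rec, "noise_part")
  osc <- attr(rec, "signal_part")
  inband <- function(x) phaselock:::band_limited_power(x, 500, 7.5, 12.5)
  expect_lte(abs(inband(osc) / inband(bg) / 4 - 1), 0.25)

  expect_error(make_eeg_like(synthetic_spec("eeg_like", carrier_freq = 1,
                                            drift_std = 40, duration = 2,
                                            seed = 1)),
               "outside")
})

test_that("synthetic specs reject impossible requests", {
  expect_error(synthetic_spec(snr = 0), "snr")
  expect_error(synthetic_spec(snr = -2), "snr")
  expect_error(synthetic_spec(drift_std = -1), "drift_std")
  expect_error(synthetic_spec(carrier_freq = 300, fs = 500), "fs/2")
})
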