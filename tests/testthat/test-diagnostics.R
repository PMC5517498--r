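test_that("a constant-frequency signal has sub-bin peak variability", {
  rec <- noiseless_rec(duration = 10)
  rep_ <- peak_frequency_variability(rec, alpha_band(), 300, 50,
                                     with_plv = FALSE)
  expect_lt(rep_$variability, 0.05)   # within one interpolated FFT bin

  # same for a drift-free eeg-like oscillation
  still <- make_eeg_like(synthetic_spec("eeg_like", drift_std = 0,
                                        noiseless = TRUE, duration = 10,
                                        seed = 2))
  rep2 <- peak_frequency_variability(still, alpha_band(), 300, 50,
                                     with_plv = FALSE)
  expect_lt(rep2$variability, 0.05)
})

test_that("alternating 9/11 Hz blocks give a bimodal series with sd ~ 1 Hz", {
  fs <- 500
  blocks <- rep(c(9, 11), each = fs, times = 5)   # 1 s blocks, 10 s total
  x <- sin(2 * pi * cumsum(blocks) / fs)          # phase-continuous
  rec <- recording(x, fs = fs)
  # 500 ms windows stepping 500 ms: window i (0-based start i * 250 samples)
  # lies fully inside block floor(i / 2), so the series must alternate
  # low-low-high-high with the blocks
  rep_ <- peak_frequency_variability(rec, alpha_band(), 500, 500,
                                     with_plv = FALSE)
  s <- rep_$peak_freq_series
  block_of <- floor((seq_along(s) - 1) / 2) %% 2   # 0 -> 9 Hz, 1 -> 11 Hz
  lo_mode <- mean(s[block_of == 0])
  hi_mode <- mean(s[block_of == 1])
  # the causal filter transient pulls both modes toward band center, but
  # the bimodal split must straddle 10 Hz and track the blocks
  expect_lt(lo_mode, 10)
  expect_gt(hi_mode, 10)
  expect_gt(hi_mode - lo_mode, 1)
  expect_true(all(abs(s[block_of == 0] - lo_mode) < 0.5))
  expect_true(all(abs(s[block_of == 1] - hi_mode) < 0.5))
  expect_lt(abs(sd(s) - 1.0), 0.5)
})

test_that("generator drift translates into measured peak variability", {
  # strong alpha (snr 10) and a near-optimal 500 ms window keep the
  # estimator noise floor below the drift being measured
  lo <- make_eeg_like(synthetic_spec("eeg_like", drift_std = 0.05, snr = 10,
                                     duration = 15, seed = 8))
  hi <- make_eeg_like(synthetic_spec("eeg_like", drift_std = 0.5, snr = 10,
                                     duration = 15, seed = 8))
  v_lo <- peak_frequency_variability(lo, alpha_band(), 500, 50,
                                     with_plv = FALSE)$variability
  v_hi <- peak_frequency_variability(hi, alpha_band(), 500, 50,
                                     with_plv = FALSE)$variability
  expect_gt(v_hi, v_lo)
})

test_that("band power ratio matches analytic expectations", {
  fs <- 500
  # pure in-band sine: everything in the alpha band
  rec <- noiseless_rec(duration = 10)
  expect_gte(band_power_ratio(rec, alpha_band()), 0.95)

  # pure out-of-band sine: essentially nothing in alpha
  out <- make_pure_sine_noise(synthetic_spec("pure_sine_noise",
                                             carrier_freq = 30,
                                             noiseless = TRUE,
                                             duration = 10, seed = 1))
  expect_lte(band_power_ratio(out, alpha_band()), 0.05)

  # white noise: flat spectrum -> alpha fraction ~ 5 / 250
  set.seed(44)
  wn <- recording(rnorm(60 * fs), fs = fs)
  r <- band_power_ratio(wn, alpha_band())
  expect_lt(abs(r - 5 / 250), 0.005)

  expect_error(band_power_ratio(recording(rnorm(100), fs = 500),
                                alpha_band()), "2 s")
})

test_that("band powers across the canonical set partition the spectrum", {
  set.seed(45)
  rec <- make_eeg_like(synthetic_spec("eeg_like", snr = 4, duration = 20,
                                      seed = 45))
  ratios <- vapply(canonical_bands(), function(b) band_power_ratio(rec, b),
                   numeric(1))
  expect_true(all(ratios >= 0 & ratios <= 1))
  expect_lte(sum(ratios), 1 + 0.01)   # bands are disjoint
})

test_that("PLV regressions report and flag degenerate predictors", {
  mk <- function(vr, pr, pl) {
    structure(list(band = alpha_band(), peak_freq_series = numeric(0),
                   variability = vr, band_power_ratio = pr, plv = pl,
                   d_past_ms = 300, d_future_ms = 50),
              class = "variability_report")
  }
  expect_error(correlate_with_plv(list(mk(1, 0.2, 0.8))), "at least 3")

  # constant variability is flagged, varying power still regresses
  reports <- list(mk(0.5, 0.1, 0.9), mk(0.5, 0.2, 0.84), mk(0.5, 0.35, 0.7))
  expect_warning(tab <- correlate_with_plv(reports), "constant predictor")
  expect_true(is.na(tab$r_squared[tab$predictor == "variability"]))
  expect_gt(tab$r_squared[tab$predictor == "band_power_ratio"], 0.9)

  # a clean decreasing family recovers the negative slope
  reports2 <- list(mk(0.1, 0.2, 0.9), mk(0.4, 0.2, 0.8), mk(0.7, 0.25, 0.6),
                   mk(1.0, 0.21, 0.5))
  tab2 <- correlate_with_plv(reports2)
  vrow <- tab2[tab2$predictor == "variability", ]
  expect_lt(vrow$slope, 0)
  expect_gt(vrow$r_squared, 0.9)
  expect_lt(vrow$p_value, 0.05)
})
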