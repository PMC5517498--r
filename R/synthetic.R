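#' Specification of a synthetic test signal
#'
#' Two generator families are provided. `pure_sine_noise` is a fixed-frequency
#' sine with additive Gaussian white noise at a controlled signal-to-noise
#' ratio, the classic bench signal for phase-tracking tests. `eeg_like` is a
#' stand-in for resting EEG: a narrowband oscillation whose instantaneous
#' frequency drifts slowly (mean-reverting random walk) over a `1/f^beta`
#' broadband background.
#'
#' @param kind `"pure_sine_noise"` or `"eeg_like"`.
#' @param carrier_freq Oscillation frequency in Hz (default 10, an alpha
#'   rhythm).
#' @param snr Linear power ratio, `> 0`. For `pure_sine_noise`: sine power /
#'   white-noise power. For `eeg_like`: oscillation power / background power
#'   within carrier +/- 2.5 Hz (in-band SNR; see the methods vignette).
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param noiseless If `TRUE`, omit the noise/background entirely; `snr` is
#'   then ignored. Infinite SNR is requested this way, keeping `snr` finite.
#' @param amplitude Oscillation amplitude (default 1).
#' @param drift_std `eeg_like` only: stationary standard deviation, in Hz, of
#'   the slowly varying instantaneous peak frequency. 0 means a fixed peak.
#' @param drift_tau `eeg_like` only: relaxation time of the frequency drift
#'   in seconds (default 1).
#' @param background_exponent `eeg_like` only: spectral slope beta of the
#'   `1/f^beta` background (default 1).
#' @param seed Integer seed; the seed fully determines the output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("pure_sine_noise", "eeg_like"),
                           carrier_freq = 10, snr = 1, duration = 60,
                           fs = 500, noiseless = FALSE, amplitude = 1,
                           drift_std = 0.1, drift_tau = 1,
                           background_exponent = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (!noiseless && (!is.finite(snr) || snr <= 0)) {
    stop("snr must be a finite positive power ratio (use noiseless = TRUE for a clean signal)")
  }
  if (drift_std < 0) stop("drift_std must be >= 0")
  if (carrier_freq >= fs / 2) stop("carrier_freq must lie below fs/2")
  if (carrier_freq <= 0 || duration <= 0 || fs <= 0) {
    stop("carrier_freq, duration and fs must be positive")
  }
  structure(list(kind = kind, carrier_freq = carrier_freq, snr = snr,
                 duration = duration, fs = fs, noiseless = noiseless,
                 amplitude = amplitude, drift_std = drift_std,
                 drift_tau = drift_tau,
                 background_exponent = background_exponent,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a sine-plus-noise recording
#'
#' `A sin(2 pi f t) + n(t)` with `n` Gaussian white noise scaled so that the
#' sine-to-noise power ratio equals `spec$snr` (a sine of amplitude A has
#' power A^2/2). Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec] with `kind = "pure_sine_noise"`.
#' @return A one-channel [recording]. Attributes `signal_part` and
#'   `noise_part` carry the two components for SNR verification.
#' @examples
#' spec <- synthetic_spec("pure_sine_noise", snr = 1, duration = 2, seed = 7)
#' rec <- make_pure_sine_noise(spec)
#' @export
make_pure_sine_noise <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "pure_sine_noise")
  n <- round(spec$duration * spec$fs)
  t <- (0:(n - 1)) / spec$fs
  sine <- spec$amplitude * sin(2 * pi * spec$carrier_freq * t)
  if (spec$noiseless) {
    noise <- numeric(n)
  } else {
    noise_sd <- sqrt(spec$amplitude^2 / 2 / spec$snr)
    set.seed(spec$seed)
    noise <- stats::rnorm(n, sd = noise_sd)
  }
  rec <- recording(sine + noise, fs = spec$fs, channel_labels = "synthetic")
  attr(rec, "signal_part") <- sine
  attr(rec, "noise_part") <- noise
  attr(rec, "spec") <- spec
  rec
}

#' Generate an EEG-like recording
#'
#' A narrowband oscillation whose instantaneous frequency follows a
#' mean-reverting (Ornstein-Uhlenbeck-type) random walk around
#' `carrier_freq` with stationary standard deviation `drift_std` Hz and
#' relaxation time `drift_tau` s, superimposed on a `1/f^beta` background.
#' This emulates the structure of resting EEG relevant to phase forecasting:
#' a dominant peak whose frequency wanders slowly over a broadband floor.
#' The background is scaled so that the oscillation-to-background power
#' ratio *within carrier +/- 2.5 Hz* equals `spec$snr`.
#'
#' @param spec A [synthetic_spec] with `kind = "eeg_like"`.
#' @return A one-channel [recording], with attributes `signal_part`,
#'   `noise_part`, and `inst_freq` (the true instantaneous frequency in Hz).
#' @export
make_eeg_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "eeg_like")
  n <- round(spec$duration * spec$fs)
  fs <- spec$fs
  set.seed(spec$seed)

  # Instantaneous frequency: exact OU discretization, stationary sd drift_std.
  dt <- 1 / fs
  a <- exp(-dt / spec$drift_tau)
  innov_sd <- spec$drift_std * sqrt(1 - a^2)
  f_inst <- numeric(n)
  f_inst[1] <- spec$carrier_freq + spec$drift_std * stats::rnorm(1)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, sd = innov_sd)
    for (k in 2:n) {
      f_inst[k] <- spec$carrier_freq + a * (f_inst[k - 1] - spec$carrier_freq) +
        eps[k - 1]
    }
  }
  if (any(f_inst <= 0) || any(f_inst >= fs / 2)) {
    stop("drift_std drives the instantaneous frequency outside (0, fs/2)")
  }
  phase <- 2 * pi * cumsum(f_inst) / fs
  osc <- spec$amplitude * sin(phase)

  if (spec$noiseless) {
    bg <- numeric(n)
  } else {
    bg <- one_over_f_noise(n, fs, spec$background_exponent)
    # Scale to the requested in-band SNR (carrier +/- 2.5 Hz).
    band_lo <- max(spec$carrier_freq - 2.5, 0.01)
    band_hi <- min(spec$carrier_freq + 2.5, fs / 2 - 0.01)
    bg_inband <- band_limited_power(bg, fs, band_lo, band_hi)
    osc_power <- mean(osc^2)
    bg <- bg * sqrt(osc_power / (spec$snr * bg_inband))
  }
  rec <- recording(osc + bg, fs = fs, channel_labels = "synthetic")
  attr(rec, "signal_part") <- osc
  attr(rec, "noise_part") <- bg
  attr(rec, "inst_freq") <- f_inst
  attr(rec, "spec") <- spec
  rec
}

# Gaussian 1/f^beta noise by spectral shaping, unit variance.
one_over_f_noise <- function(n, fs, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  X <- stats::fft(w)
  freq <- seq(0, n - 1) * fs / n
  freq[freq > fs / 2] <- fs - freq[freq > fs / 2]   # fold to [0, fs/2]
  shape <- c(0, freq[-1]^(-beta / 2))                # kill DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Power of x within [lo, hi) Hz, raw periodogram integration.
band_limited_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n^2
  freq <- seq(0, n - 1) * fs / n
  half <- freq > 0 & freq < fs / 2
  inb <- half & freq >= lo & freq < hi
  2 * sum(P[inb])
}

#' Measure a signal-to-noise power ratio
#'
#' The ratio of the mean-square of the signal part to the mean-square of the
#' noise part, reported both as a linear ratio and in dB.
#'
#' @param signal_part,noise_part Equal-length numeric vectors.
#' @return List with `ratio` (linear power ratio) and `db`
#'   (`10 log10(ratio)`).
#' @examples
#' measure_snr(sin(2 * pi * (0:999) / 100), rnorm(1000))
#' @export
measure_snr <- function(signal_part, noise_part) {
  if (length(signal_part) != length(noise_part)) {
    stop("signal and noise parts must have equal length")
  }
  if (length(signal_part) < 2L) stop("need at least 2 samples")
  p_noise <- mean(noise_part^2)
  if (p_noise == 0) {
    stop("noise part has zero power; request a noiseless signal explicitly instead")
  }
  ratio <- mean(signal_part^2) / p_noise
  list(ratio = ratio, db = 10 * log10(ratio))
}
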