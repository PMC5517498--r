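#' Dominant spectral component of a window
#'
#' Zero-pads the (already band-filtered) window to `nfft` total points,
#' takes the discrete Fourier transform, and picks the bin of maximum
#' modulus over `(0, fs/2)`. Zero-padding to ten thousand points shrinks
#' the bin width to `fs/nfft` (0.05 Hz at fs 500), interpolating the
#' spectrum so the dominant frequency is resolved far below the window's
#' natural resolution. Ties break to the lowest frequency.
#'
#' Phase convention: the returned `phase` is that of a *cosine* referenced
#' to window sample 0, i.e. the dominant component is modeled as
#' `cos(2 pi f t + phase)`. Consumers wanting a sine convention use
#' `sin(x) = cos(x - pi/2)`.
#'
#' @param filtered_window Numeric sample vector, length in `[2, nfft]`.
#' @param fs Sampling rate in Hz.
#' @param nfft Total transform length after zero-padding (default 10000).
#' @return A `spectral_estimate`: list with `dominant_freq` (Hz), `phase`
#'   (radians in `(-pi, pi]`), and `magnitude` (FFT bin modulus).
#' @examples
#' w <- cos(2 * pi * 10 * (0:149) / 500)
#' estimate_dominant(w, fs = 500)
#' @export
estimate_dominant <- function(filtered_window, fs, nfft = 10000L) {
  n <- length(filtered_window)
  if (n < 2L) stop("window must contain at least 2 samples")
  if (n > nfft) stop("window longer than the transform length nfft")
  if (any(!is.finite(filtered_window))) stop("window contains NaN/Inf")
  if (all(filtered_window == 0)) {
    stop("all-zero window: dominant component undefined")
  }
  X <- stats::fft(c(filtered_window, numeric(nfft - n)))
  # bins strictly inside (0, fs/2): k = 1 .. ceil(nfft/2) - 1 (0-based k)
  kmax <- ceiling(nfft / 2) - 1L
  mods <- Mod(X[2:(kmax + 1L)])
  k <- which.max(mods)                      # first max = lowest frequency
  structure(
    list(dominant_freq = k * fs / nfft,
         phase = Arg(X[k + 1L]),
         magnitude = mods[k],
         nfft = as.integer(nfft),
         window_length = n),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %.3f Hz, phase %.3f rad, magnitude %.3g\n",
              x$dominant_freq, x$phase, x$magnitude))
  invisible(x)
}

new_forecast_segment <- function(samples, start_index, estimate,
                                 corrected_phase) {
  structure(list(samples = samples, start_index = start_index,
                 estimate = estimate, corrected_phase = corrected_phase),
            class = "forecast_segment")
}

#' @export
print.forecast_segment <- function(x, ...) {
  cat(sprintf("<forecast_segment> %d samples from index %d (%.3f Hz)\n",
              length(x$samples), x$start_index,
              if (is.null(x$estimate)) NA_real_ else x$estimate$dominant_freq))
  invisible(x)
}

#' FFT-based phase/frequency forecast
#'
#' The core forecasting step: causally bandpass-filter the past window,
#' estimate the dominant component's frequency and phase from the
#' zero-padded FFT, add the filter's phase-delay correction at that
#' frequency, and extrapolate a sinusoid at the corrected phase over the
#' forecast horizon. The forecast is the analytic continuation of the fitted
#' sinusoid: sample `k` of the segment is the model evaluated at offset
#' `length(past_window) + k` (0-based) from the window start, so there is no
#' phase jump between the window model and the forecast.
#'
#' @param past_window Numeric vector of past samples (the analysis window).
#'   Must hold at least one full period of the band's low edge.
#' @param fs Sampling rate in Hz.
#' @param filter The `designed_filter` for the target band.
#' @param horizon_samples Forecast length in samples (`>= 0`; 0 gives an
#'   empty segment with the estimate still attached).
#' @param scale_amplitude If `TRUE`, scale the forecast by
#'   `2 * magnitude / length(past_window)` (the sinusoid's amplitude
#'   implied by its FFT bin); default is unit amplitude, since the
#'   phase-locking value is amplitude-blind.
#' @param nfft Zero-padding target passed to [estimate_dominant()].
#' @return A `forecast_segment`; `start_index` is the 0-based offset of the
#'   first forecast sample from the window start (= window length).
#' @examples
#' flt <- design_bandpass(frequency_band("alpha", 8, 13), fs = 500)
#' w <- sin(2 * pi * 10 * (0:149) / 500)
#' fft_forecast(w, 500, flt, horizon_samples = 25)
#' @export
fft_forecast <- function(past_window, fs, filter, horizon_samples,
                         scale_amplitude = FALSE, nfft = 10000L) {
  stopifnot(inherits(filter, "designed_filter"))
  n <- length(past_window)
  min_len <- max(2, ceiling(fs / filter$band$low))
  if (n < min_len) {
    stop(sprintf(
      "past window (%d samples) shorter than one period of the band low edge (%d samples)",
      n, min_len))
  }
  if (horizon_samples < 0) stop("horizon_samples must be >= 0")

  filtered <- apply_causal(filter, past_window)
  est <- estimate_dominant(filtered, fs, nfft = nfft)
  corrected <- est$phase + phase_delay_correction(filter, est$dominant_freq)
  amp <- if (scale_amplitude) 2 * est$magnitude / n else 1
  k <- seq_len(horizon_samples) - 1L
  samples <- amp * cos(2 * pi * est$dominant_freq * (n + k) / fs + corrected)
  new_forecast_segment(samples, start_index = n, estimate = est,
                       corrected_phase = corrected)
}

# Yule-Walker AR fit (autocorrelation method, biased autocovariances),
# the package's fitting wrapper around stats::ar.yw.
fit_ar_yw <- function(x, order) {
  if (length(x) <= order) {
    stop(sprintf("window (%d samples) must exceed the AR order (%d)",
                 length(x), order))
  }
  if (stats::sd(x) == 0) {
    stop("constant window: autocorrelation matrix is singular")
  }
  stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
}

#' Autoregressive (Yule-Walker) comparator forecast
#'
#' The benchmark forecaster: causally bandpass-filter the past window, fit
#' an AR model of the given order by the Yule-Walker method, and forecast
#' recursively with future innovations set to zero (the conditional-mean
#' forecast). A post-hoc spectral estimate of the forecast itself is
#' attached for logging when the horizon allows it.
#'
#' The causal filter delays the training signal, so the raw AR forecast is
#' delayed relative to the undelayed reference oscillation. With
#' `delay_compensate = TRUE` (default) the forecast is advanced in time by
#' the filter's phase delay at the band center frequency, putting both
#' forecasters on equal footing against a zero-phase reference;
#' `delay_compensate = FALSE` leaves the forecast as trained.
#'
#' @param past_window Numeric vector of past samples; length must exceed
#'   `order`.
#' @param fs Sampling rate in Hz.
#' @param filter The `designed_filter` for the target band.
#' @param horizon_samples Forecast length in samples (`>= 0`).
#' @param order AR model order (default 50).
#' @param delay_compensate Advance the forecast by the filter delay at band
#'   center (default `TRUE`).
#' @return A `forecast_segment`.
#' @export
ar_forecast <- function(past_window, fs, filter, horizon_samples,
                        order = 50L, delay_compensate = TRUE) {
  stopifnot(inherits(filter, "designed_filter"))
  if (horizon_samples < 0) stop("horizon_samples must be >= 0")
  filtered <- apply_causal(filter, past_window)
  fit <- fit_ar_yw(filtered, order)
  n <- length(past_window)

  n_adv <- 0L
  if (delay_compensate) {
    fc <- (filter$band$low + filter$band$high) / 2
    tau <- phase_delay_correction(filter, fc) / (2 * pi * fc)
    n_adv <- max(0L, as.integer(round(tau * fs)))
  }
  if (horizon_samples + n_adv > 0) {
    pred <- as.numeric(stats::predict(fit, newdata = filtered,
                                      n.ahead = horizon_samples + n_adv,
                                      se.fit = FALSE))
    samples <- pred[(n_adv + 1L):(n_adv + horizon_samples)]
    if (horizon_samples == 0L) samples <- numeric(0)
  } else {
    samples <- numeric(0)
  }

  est <- NULL
  if (length(samples) >= 2L && any(samples != 0)) {
    est <- tryCatch(estimate_dominant(samples, fs), error = function(e) NULL)
  }
  new_forecast_segment(samples, start_index = n, estimate = est,
                       corrected_phase = NA_real_)
}

# -- forecaster registry ------------------------------------------------------

forecaster_registry <- new.env(parent = emptyenv())

#' Register or look up a forecaster
#'
#' A forecaster is any function with signature
#' `f(past_window, fs, filter, horizon_samples, ...)` returning a
#' `forecast_segment`. The built-ins `"fft"` and `"ar"` are pre-registered;
#' third-party forecasters can be registered for benchmarking under the
#' same contract.
#'
#' @param name Forecaster name.
#' @param fn Function honoring the contract.
#' @return `register_forecaster()` returns `fn` invisibly;
#'   `get_forecaster()` returns the registered function.
#' @export
register_forecaster <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = forecaster_registry)
  invisible(fn)
}

#' @rdname register_forecaster
#' @export
get_forecaster <- function(name) {
  if (is.function(name)) return(name)
  if (!exists(name, envir = forecaster_registry, inherits = FALSE)) {
    stop(sprintf("unknown forecaster '%s'", name))
  }
  get(name, envir = forecaster_registry, inherits = FALSE)
}
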