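#' Peak-frequency variability of a recording in a band
#'
#' Replays the moving-window stepping of the evaluation harness (past
#' window `d_past_ms`, step `d_future_ms`), records the dominant frequency
#' of each causally filtered window, and summarizes its variability as the
#' sample standard deviation of the series. A stable dominant rhythm gives
#' near-zero variability; a wandering peak inflates it, which is the signal
#' property that degrades sinusoidal-extrapolation forecasting.
#'
#' The report also carries the band-power ratio of the recording and, when
#' `with_plv = TRUE` (default), the phase-locking value of the FFT
#' forecaster from a paired evaluation run with the same windows, so that
#' reports can be fed directly to [correlate_with_plv()].
#'
#' @param rec A [recording]; the first channel is analyzed.
#' @param band Target [frequency_band].
#' @param d_past_ms,d_future_ms Window and step durations in ms.
#' @param with_plv Attach the paired evaluation PLV (default `TRUE`).
#' @param ... Passed to [moving_window_evaluate()] for the paired run.
#' @return A `variability_report`: list with `band`, `peak_freq_series`
#'   (Hz per window), `variability` (Hz), `band_power_ratio`, `plv`.
#' @export
peak_frequency_variability <- function(rec, band, d_past_ms = 300,
                                       d_future_ms = 50, with_plv = TRUE,
                                       ...) {
  stopifnot(inherits(rec, "recording"))
  check_band_fs(band, rec$fs)
  fs <- rec$fs
  flt <- design_bandpass(band, fs)
  n_past <- ms_to_samples(d_past_ms, fs)
  n_future <- ms_to_samples(d_future_ms, fs)
  n <- n_samples(rec)
  if (n <= n_past + n_future) stop("recording too short for one window")
  k_steps <- (n - n_past) %/% n_future
  x <- rec$samples[1, ]
  series <- vapply(seq_len(k_steps), function(i) {
    w0 <- (i - 1L) * n_future
    win <- apply_causal(flt, x[(w0 + 1L):(w0 + n_past)])
    estimate_dominant(win, fs)$dominant_freq
  }, numeric(1))

  plv_val <- NA_real_
  if (with_plv) {
    res <- moving_window_evaluate(rec, "fft", band, d_past_ms, d_future_ms,
                                  filter = flt, ...)
    plv_val <- res$report$plv
  }
  structure(
    list(band = band, peak_freq_series = series,
         variability = stats::sd(series),
         band_power_ratio = band_power_ratio(rec, band),
         plv = plv_val,
         d_past_ms = d_past_ms, d_future_ms = d_future_ms),
    class = "variability_report"
  )
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf(
    "<variability_report> %s band: peak-freq sd %.3f Hz over %d windows, power ratio %.3f, PLV %s\n",
    x$band$name, x$variability, length(x$peak_freq_series),
    x$band_power_ratio,
    if (is.na(x$plv)) "-" else sprintf("%.3f", x$plv)))
  invisible(x)
}

#' Band power as a fraction of total power
#'
#' Spectral power within `[low, high)` Hz divided by the total power over
#' `(0, fs/2)`, estimated by an averaged periodogram (Welch estimator with
#' rectangular taper): 2 s segments, 50% overlap. DC is excluded from both
#' numerator and denominator.
#'
#' @param rec A [recording] (first channel analyzed) or numeric vector with
#'   `fs` supplied.
#' @param band Target [frequency_band].
#' @param fs Sampling rate, required when `rec` is a bare vector.
#' @param segment_s Welch segment length in seconds (default 2).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return Ratio in `[0, 1]`.
#' @examples
#' rec <- make_pure_sine_noise(synthetic_spec("pure_sine_noise",
#'   noiseless = TRUE, duration = 4, seed = 1))
#' band_power_ratio(rec, frequency_band("alpha", 8, 13))
#' @export
band_power_ratio <- function(rec, band, fs = NULL, segment_s = 2,
                             overlap = 0.5) {
  if (inherits(rec, "recording")) {
    x <- rec$samples[1, ]
    fs <- rec$fs
  } else {
    if (is.null(fs)) stop("fs required for vector input")
    x <- rec
  }
  if (length(x) < 2 * fs) stop("need at least 2 s of signal for a stable spectral estimate")
  if (all(x == 0)) stop("zero-power recording")
  seg_len <- round(segment_s * fs)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  P <- numeric(seg_len)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    P <- P + Mod(stats::fft(seg))^2
  }
  freq <- seq(0, seg_len - 1) * fs / seg_len
  half <- freq > 0 & freq < fs / 2
  inb <- half & freq >= band$low & freq < band$high
  sum(P[inb]) / sum(P[half])
}

#' Correlate phase-locking performance with signal properties
#'
#' Ordinary least-squares regression of PLV on each signal property
#' (peak-frequency variability and band-power ratio) across a collection of
#' variability reports; reports slope, R-squared, and the two-sided p-value
#' of the slope, one row per predictor. A constant predictor leaves R^2
#' undefined and is flagged with `NA` and a warning; a two-point fit is
#' algebraically perfect (R^2 = 1) and is warned about as degenerate.
#'
#' @param reports List of `variability_report` objects (each with a paired
#'   PLV), length >= 3.
#' @return Data.frame with columns `predictor`, `slope`, `r_squared`,
#'   `p_value`, `n`.
#' @export
correlate_with_plv <- function(reports) {
  if (length(reports) < 3L) stop("need at least 3 reports")
  ok <- vapply(reports, function(r) inherits(r, "variability_report"),
               logical(1))
  if (!all(ok)) stop("all elements must be variability_report objects")
  df <- data.frame(
    variability = vapply(reports, function(r) r$variability, numeric(1)),
    band_power_ratio = vapply(reports, function(r) r$band_power_ratio,
                              numeric(1)),
    plv = vapply(reports, function(r) r$plv, numeric(1))
  )
  if (any(is.na(df$plv))) stop("reports must carry paired PLVs (with_plv = TRUE)")
  if (nrow(df) == 2L) warning("two points: regression fit is degenerate (R^2 = 1)")
  one <- function(name) {
    x <- df[[name]]
    if (stats::sd(x) == 0) {
      warning(sprintf("constant predictor '%s': R^2 undefined", name))
      return(data.frame(predictor = name, slope = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = nrow(df), stringsAsFactors = FALSE))
    }
    fit <- stats::lm(plv ~ x, data = data.frame(plv = df$plv, x = x))
    sm <- summary(fit)
    p <- if (nrow(df) > 2L) sm$coefficients[2, 4] else NA_real_
    data.frame(predictor = name, slope = stats::coef(fit)[[2]],
               r_squared = sm$r.squared, p_value = p, n = nrow(df),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("variability"), one("band_power_ratio"))
  rownames(out) <- NULL
  out
}
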