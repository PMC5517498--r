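#' Instantaneous phase via the analytic signal
#'
#' The angle of the analytic signal (FFT construction of the Hilbert
#' transform). Meaningful only for narrowband input — the caller filters
#' first. The first and last 5% of samples are flagged in the `edge_mask`
#' attribute for optional exclusion, since the analytic signal is least
#' reliable at the record edges.
#'
#' @param x Numeric vector, length >= 8, not all zero.
#' @return Phase vector in radians, with attribute `edge_mask` (logical,
#'   `TRUE` on the flagged edges).
#' @examples
#' ph <- instantaneous_phase(cos(2 * pi * 10 * (0:4999) / 500))
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples for a phase estimate")
  if (all(x == 0)) stop("all-zero input: phase undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  phase <- Arg(analytic)
  guard <- max(1L, floor(0.05 * n))
  mask <- rep(FALSE, n)
  mask[seq_len(guard)] <- TRUE
  mask[(n - guard + 1L):n] <- TRUE
  attr(phase, "edge_mask") <- mask
  phase
}

#' Phase-locking value
#'
#' `PLV = | mean(exp(i (phase_a - phase_b))) |`: the modulus of the mean
#' unit phasor of the phase differences. 1 means a perfectly consistent
#' phase relation (any constant offset), 0 means none.
#'
#' @param phase_a,phase_b Equal-length phase vectors in radians,
#'   length >= 1.
#' @return A `plv_report`: list with `plv` in `[0, 1]` and `n_compared`.
#' @examples
#' plv(rep(0.3, 100), rep(1.1, 100))$plv  # constant offset -> 1
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase vectors must have equal length")
  }
  if (length(phase_a) < 1L) stop("need at least one phase sample")
  value <- Mod(mean(exp(1i * (phase_a - phase_b))))
  structure(list(plv = value, n_compared = length(phase_a),
                 per_channel = NULL),
            class = "plv_report")
}

#' @export
print.plv_report <- function(x, ...) {
  cat(sprintf("<plv_report> PLV = %.4f over %d samples\n", x$plv, x$n_compared))
  if (!is.null(x$per_channel)) {
    for (ch in names(x$per_channel)) {
      cat(sprintf("  %s: %.4f\n", ch, x$per_channel[[ch]]))
    }
  }
  invisible(x)
}

#' Offline moving-window evaluation of a forecaster
#'
#' Simulates the closed-loop use of a forecaster on a pre-recorded signal:
#' a past window of `d_past_ms` slides in steps of `d_future_ms`; at each
#' step the forecaster maps the window to a forecast of the next step, and
#' the segments are stitched into a forecast trace tiling the record beyond
#' the first window. The trace's phase (via the analytic signal) is
#' compared against the phase of the band-filtered recording, and scored by
#' the phase-locking value per channel.
#'
#' The reference is built by filtering the *full* recording with the band
#' filter: zero-phase (forward-backward) by default, so the reference
#' carries no filter delay and represents the undelayed underlying
#' oscillation; `reference_mode = "causal"` uses the forward-only filter
#' instead. The analytic signal of the reference is computed once on the
#' whole record, then restricted to the evaluated span.
#'
#' @param rec A [recording].
#' @param forecaster `"fft"`, `"ar"`, or any registered forecaster /
#'   function honoring the forecaster contract.
#' @param band Target [frequency_band].
#' @param d_past_ms,d_future_ms Past-window and horizon durations in ms.
#' @param reference_mode `"zero_phase"` (default) or `"causal"`.
#' @param reference Optional explicit reference signal (numeric vector of
#'   `n_samples(rec)` per channel, or a channels x time matrix): when the
#'   ground truth underlying a synthetic recording is known, supplying it
#'   scores the forecast against the truth rather than against the filtered
#'   (noisy) recording. Overrides `reference_mode`.
#' @param edge_guard If `TRUE`, drop the first and last 5% of compared
#'   samples (analytic-signal edge guard). Default `FALSE`.
#' @param filter Optional pre-designed `designed_filter`; designed from
#'   `band` and `rec$fs` when omitted.
#' @param ... Passed through to the forecaster (e.g. `order`,
#'   `delay_compensate`, `scale_amplitude`).
#' @return List with `trace` (a `forecast_trace`: stitched forecast,
#'   per-window dominant frequencies and phases, tiling bookkeeping) and
#'   `report` (a `plv_report`; `plv` is the mean over channels, with the
#'   per-channel map attached).
#' @examples
#' rec <- make_pure_sine_noise(synthetic_spec("pure_sine_noise",
#'   noiseless = TRUE, duration = 5, seed = 1))
#' res <- moving_window_evaluate(rec, "fft", frequency_band("alpha", 8, 13),
#'   d_past_ms = 300, d_future_ms = 50)
#' res$report
#' @export
moving_window_evaluate <- function(rec, forecaster, band, d_past_ms,
                                   d_future_ms,
                                   reference_mode = c("zero_phase", "causal"),
                                   edge_guard = FALSE, filter = NULL,
                                   reference = NULL, ...) {
  stopifnot(inherits(rec, "recording"))
  reference_mode <- match.arg(reference_mode)
  if (!is.null(reference)) {
    if (is.vector(reference)) reference <- matrix(reference, nrow = 1L)
    if (ncol(reference) != n_samples(rec)) {
      stop("reference must match the recording length")
    }
  }
  check_band_fs(band, rec$fs)
  fs <- rec$fs
  n_past <- ms_to_samples(d_past_ms, fs)
  n_future <- ms_to_samples(d_future_ms, fs)
  if (n_future < 1L) stop("d_future_ms too short: zero samples")
  n <- n_samples(rec)
  if (n <= n_past + n_future) {
    stop("recording shorter than one past window plus one horizon")
  }
  if (is.null(filter)) filter <- design_bandpass(band, fs)
  fc <- get_forecaster(forecaster)

  k_steps <- (n - n_past) %/% n_future
  span <- (n_past + 1L):(n_past + k_steps * n_future)   # 1-based indices

  per_channel <- numeric(n_channels(rec))
  names(per_channel) <- rec$channel_labels
  traces <- vector("list", n_channels(rec))

  for (ch in seq_len(n_channels(rec))) {
    x <- rec$samples[ch, ]
    stitched <- numeric(k_steps * n_future)
    freqs <- rep(NA_real_, k_steps)
    phases <- rep(NA_real_, k_steps)
    for (i in seq_len(k_steps)) {
      w0 <- (i - 1L) * n_future            # 0-based window start
      window <- x[(w0 + 1L):(w0 + n_past)]
      seg <- fc(window, fs, filter, n_future, ...)
      stitched[((i - 1L) * n_future + 1L):(i * n_future)] <- seg$samples
      if (!is.null(seg$estimate)) {
        freqs[i] <- seg$estimate$dominant_freq
        phases[i] <- if (is.na(seg$corrected_phase)) seg$estimate$phase
                     else seg$corrected_phase
      }
    }
    ref <- if (!is.null(reference)) {
      reference[min(ch, nrow(reference)), ]
    } else if (reference_mode == "zero_phase") {
      apply_zero_phase(filter, x)
    } else {
      apply_causal(filter, x)
    }
    phi_ref <- instantaneous_phase(ref)[span]
    phi_fc <- instantaneous_phase(stitched)
    keep <- rep(TRUE, length(span))
    if (edge_guard) {
      g <- max(1L, floor(0.05 * length(span)))
      keep[seq_len(g)] <- FALSE
      keep[(length(keep) - g + 1L):length(keep)] <- FALSE
    }
    n_kept <- sum(keep)
    per_channel[ch] <- plv(phi_ref[keep], phi_fc[keep])$plv
    traces[[ch]] <- list(stitched = stitched, dominant_freq = freqs,
                         corrected_phase = phases)
  }

  trace <- structure(
    list(band = band, d_past_ms = d_past_ms, d_future_ms = d_future_ms,
         n_past = n_past, n_future = n_future, n_segments = k_steps,
         span = c(n_past, n_past + k_steps * n_future),  # 0-based [start, end)
         channels = traces, reference_mode = reference_mode),
    class = "forecast_trace"
  )
  report <- structure(
    list(plv = mean(per_channel), n_compared = n_kept,
         per_channel = as.list(per_channel)),
    class = "plv_report"
  )
  list(trace = trace, report = report)
}

#' @export
print.forecast_trace <- function(x, ...) {
  cat(sprintf(
    "<forecast_trace> %s band, D_past %g ms / D_future %g ms, %d segments\n",
    x$band$name, x$d_past_ms, x$d_future_ms, x$n_segments))
  invisible(x)
}

#' Time a forecaster's per-iteration cost
#'
#' Wall-clock time of a single forecaster call, repeated `times` times.
#' Intended for relative comparisons between forecasters on identical
#' inputs; absolute values are hardware-dependent and are reported, not
#' asserted.
#'
#' @param forecaster Name or function (forecaster contract).
#' @param past_window Input window (shared across repetitions).
#' @param fs Sampling rate in Hz.
#' @param filter A `designed_filter`.
#' @param horizon_samples Forecast length in samples.
#' @param times Number of repetitions (default 100).
#' @param ... Passed to the forecaster.
#' @return List with `mean_s`, `sd_s`, and the raw `times_s` vector
#'   (seconds per iteration).
#' @export
time_iteration <- function(forecaster, past_window, fs, filter,
                           horizon_samples, times = 100L, ...) {
  fc <- get_forecaster(forecaster)
  fc(past_window, fs, filter, horizon_samples, ...)   # warm-up
  elapsed <- vapply(seq_len(times), function(i) {
    t0 <- proc.time()[["elapsed"]]
    fc(past_window, fs, filter, horizon_samples, ...)
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  list(mean_s = mean(elapsed), sd_s = stats::sd(elapsed), times_s = elapsed)
}
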