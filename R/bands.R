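#' Frequency band of interest
#'
#' A named `[low, high)` interval in Hz. Bands drive bandpass filter design
#' and every per-band analysis in the package.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `frequency_band`.
#' @examples
#' frequency_band("alpha", 8, 13)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) ||
      length(low) != 1L || length(high) != 1L) {
    stop("band edges must be single numbers")
  }
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("frequency band requires 0 < low < high")
  }
  structure(list(name = name, low = as.numeric(low), high = as.numeric(high)),
            class = "frequency_band")
}

#' Canonical EEG frequency bands
#'
#' The band set used throughout: the established EEG bands below 20 Hz and
#' 10 Hz splits of beta/gamma above 20 Hz. Phase tuning to a single dominant
#' component becomes ill-defined in very wide bands, hence the splits.
#'
#' @return Named list of [frequency_band] objects: delta 2-4, theta 4-8,
#'   alpha 8-13, low-beta 13-20, and 20-30, 30-40, 40-50 Hz.
#' @export
canonical_bands <- function() {
  list(
    delta    = frequency_band("delta", 2, 4),
    theta    = frequency_band("theta", 4, 8),
    alpha    = frequency_band("alpha", 8, 13),
    low_beta = frequency_band("low-beta", 13, 20),
    b20_30   = frequency_band("20-30", 20, 30),
    b30_40   = frequency_band("30-40", 30, 40),
    b40_50   = frequency_band("40-50", 40, 50)
  )
}

# Band edges must sit strictly inside (0, fs/2) for the recording in use.
check_band_fs <- function(band, fs) {
  stopifnot(inherits(band, "frequency_band"))
  if (band$high >= fs / 2) {
    stop(sprintf("band '%s' (%g-%g Hz) violates the Nyquist limit %g Hz",
                 band$name, band$low, band$high, fs / 2))
  }
  invisible(band)
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
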