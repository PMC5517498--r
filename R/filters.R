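#' Design the elliptic IIR bandpass filter for a band
#'
#' A 10th-order elliptic (Cauer) bandpass with 0.5 dB passband ripple and
#' 40 dB stopband attenuation, represented as cascaded second-order sections
#' (SOS). Short analysis windows rule out FIR filters of useful order, and
#' the direct transfer-function form of a narrow band at fs far above the
#' band edges is numerically unusable, hence the SOS cascade.
#'
#' The design runs entirely in zero-pole-gain form (analog Cauer prototype,
#' lowpass-to-bandpass transform, bilinear transform, via the \pkg{signal}
#' package) and the poles/zeros are then paired into biquads, so the
#' coefficients never pass through an ill-conditioned high-order polynomial.
#' Designs are cached per (band, fs, design parameters).
#'
#' @param band A [frequency_band].
#' @param fs Sampling rate in Hz; the band must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Total bandpass filter order; must be even (default 10).
#' @param passband_ripple Passband ripple in dB (default 0.5).
#' @param stopband_attenuation Stopband attenuation in dB (default 40).
#' @return A `designed_filter`: list with `sections` (L x 6 matrix, columns
#'   b0 b1 b2 a0 a1 a2 with a0 = 1), `band`, `fs`, the design parameters,
#'   and a precomputed unwrapped phase-response table.
#' @examples
#' flt <- design_bandpass(frequency_band("alpha", 8, 13), fs = 500)
#' @export
design_bandpass <- function(band, fs, order = 10, passband_ripple = 0.5,
                            stopband_attenuation = 40) {
  check_band_fs(band, fs)
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even integer")
  key <- sprintf("%s|%g|%g|%g|%d|%g|%g", band$name, band$low, band$high,
                 fs, order, passband_ripple, stopband_attenuation)
  cached <- filter_cache[[key]]
  if (!is.null(cached)) return(cached)

  # Same pipeline signal::ellip() uses, kept in zpk form throughout.
  T <- 2
  W <- 2 / T * tan(pi * (c(band$low, band$high) / (fs / 2)) / T)
  zpg <- signal:::ncauer(passband_ripple, stopband_attenuation, order / 2)
  zpg <- signal::sftrans(zpg, W = W, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)

  sections <- zp2sos(zpg$zero, zpg$pole, zpg$gain)
  flt <- designed_filter(sections, band, fs, order = order,
                         passband_ripple = passband_ripple,
                         stopband_attenuation = stopband_attenuation)
  filter_cache[[key]] <- flt
  flt
}

filter_cache <- new.env(parent = emptyenv())

#' Construct a designed filter from second-order sections
#'
#' Lower-level constructor used by [design_bandpass()] and by the JSON
#' import; validates stability (every section pole strictly inside the unit
#' circle) and precomputes the cascade's unwrapped phase response.
#'
#' @param sections Numeric L x 6 matrix, one biquad per row
#'   (b0 b1 b2 a0 a1 a2, `a0 = 1`).
#' @param band A [frequency_band] (what the cascade is meant to pass).
#' @param fs Sampling rate in Hz.
#' @param order,passband_ripple,stopband_attenuation Design parameters,
#'   recorded on the object.
#' @return A `designed_filter`.
#' @export
designed_filter <- function(sections, band, fs, order = 2 * nrow(sections),
                            passband_ripple = NA_real_,
                            stopband_attenuation = NA_real_) {
  sections <- as.matrix(sections)
  if (ncol(sections) != 6L) stop("sections must be an L x 6 matrix")
  if (any(abs(sections[, 4] - 1) > 1e-12)) {
    stop("each section must be normalized to a leading denominator of 1")
  }
  for (i in seq_len(nrow(sections))) {
    p <- polyroot(rev(sections[i, 4:6]))
    if (any(Mod(p) >= 1)) stop("unstable section: pole on or outside the unit circle")
  }
  flt <- structure(
    list(sections = sections, band = band, fs = fs, order = order,
         passband_ripple = passband_ripple,
         stopband_attenuation = stopband_attenuation),
    class = "designed_filter"
  )
  flt$phase_table <- build_phase_table(flt)
  flt
}

#' @export
print.designed_filter <- function(x, ...) {
  cat(sprintf(
    "<designed_filter> %s %g-%g Hz @ fs %g Hz, order %d (%d sections)\n",
    x$band$name, x$band$low, x$band$high, x$fs, x$order, nrow(x$sections)))
  invisible(x)
}

# Pair zeros and poles into stable biquads. Pole pairs are processed from
# the least damped (largest modulus) down, each taking its nearest
# remaining zero pair; the overall gain is spread evenly across sections.
zp2sos <- function(zeros, poles, gain) {
  if (length(zeros) > length(poles)) stop("more zeros than poles")
  if (length(poles) %% 2 != 0) stop("odd filter order not supported")
  pair_up <- function(r) {
    cplx <- r[Im(r) > 1e-10]
    real <- sort(Re(r[abs(Im(r)) <= 1e-10]))
    pairs <- lapply(cplx, function(z) c(z, Conj(z)))
    if (length(real) %% 2 != 0) stop("unpaired real root; inconsistent conjugates")
    if (length(real) > 0) {
      # pair adjacent real roots
      for (i in seq(1, length(real), by = 2)) {
        pairs <- c(pairs, list(complex(real = real[i:(i + 1)], imaginary = 0)))
      }
    }
    pairs
  }
  zp <- pair_up(zeros)
  pp <- pair_up(poles)
  # pad with zero pairs at the origin if the numerator order is lower
  while (length(zp) < length(pp)) zp <- c(zp, list(c(0 + 0i, 0 + 0i)))

  ord <- order(vapply(pp, function(p) max(Mod(p)), numeric(1)),
               decreasing = TRUE)
  pp <- pp[ord]
  L <- length(pp)
  g_sec <- abs(gain)^(1 / L)
  sections <- matrix(0, nrow = L, ncol = 6)
  for (i in seq_len(L)) {
    p <- pp[[i]]
    d <- vapply(zp, function(z) min(Mod(z - p[1])), numeric(1))
    j <- which.min(d)
    z <- zp[[j]]
    zp <- zp[-j]
    b <- Re(c(1, -(z[1] + z[2]), z[1] * z[2]))
    a <- Re(c(1, -(p[1] + p[2]), p[1] * p[2]))
    sections[i, ] <- c(g_sec * b, a)
  }
  if (gain < 0) sections[1, 1:3] <- -sections[1, 1:3]
  sections
}

#' Apply a filter causally to a segment
#'
#' Sections applied sequentially in cascade order with zero initial state —
#' the real-time-compatible, forward-only application the forecaster uses on
#' each past window. The startup transient at the head of short segments is
#' inherent to causal IIR filtering and is accepted.
#'
#' @param filter A `designed_filter`.
#' @param segment Numeric sample vector, length >= 1.
#' @return Filtered vector, same length as the input.
#' @export
apply_causal <- function(filter, segment) {
  stopifnot(inherits(filter, "designed_filter"))
  if (!is.numeric(segment) || length(segment) < 1L) {
    stop("segment must be a numeric vector of length >= 1")
  }
  if (any(!is.finite(segment))) stop("segment contains NaN/Inf")
  y <- segment
  for (i in seq_len(nrow(filter$sections))) {
    s <- filter$sections[i, ]
    y <- as.numeric(signal::filter(s[1:3], s[4:6], y))
  }
  y
}

# Zero-phase (forward-backward) application; used for the evaluation
# reference, never inside the real-time path. Magnitude response applies
# twice; phase cancels.
apply_zero_phase <- function(filter, segment) {
  y <- segment
  for (i in seq_len(nrow(filter$sections))) {
    s <- filter$sections[i, ]
    y <- as.numeric(signal::filter(s[1:3], s[4:6], y))
    y <- rev(as.numeric(signal::filter(s[1:3], s[4:6], rev(y))))
  }
  y
}

#' Complex frequency response of the cascade
#'
#' `H(f)` evaluated as the product over sections at `z = exp(i 2 pi f / fs)`
#' — the numerically safe route; the cascade is never expanded into one
#' high-order polynomial.
#'
#' @param filter A `designed_filter`.
#' @param freq Frequencies in Hz (vectorized).
#' @return Complex vector `H(freq)`.
#' @export
filter_frequency_response <- function(filter, freq) {
  stopifnot(inherits(filter, "designed_filter"))
  z1 <- exp(-1i * 2 * pi * freq / filter$fs)
  z2 <- z1^2
  H <- rep(1 + 0i, length(freq))
  for (i in seq_len(nrow(filter$sections))) {
    s <- filter$sections[i, ]
    H <- H * (s[1] + s[2] * z1 + s[3] * z2) / (s[4] + s[5] * z1 + s[6] * z2)
  }
  H
}

# Dense unwrapped-phase table over (0, fs/2), built once at design time.
build_phase_table <- function(filter) {
  f <- seq(0.01, filter$fs / 2 - 0.01, length.out = 8192L)
  ph <- signal::unwrap(Arg(filter_frequency_response(filter, f)))
  list(freq = f, phase = ph)
}

#' Phase correction for the filter's delay at a frequency
#'
#' The causal bandpass filter delays the oscillation it passes; a phase
#' estimated from causally filtered data is therefore lagged by the filter's
#' phase response. This returns `delta_phi = -arg H(f)` from the cascade's
#' unwrapped phase response: adding it to a phase estimated from causally
#' filtered data recovers the phase of the unfiltered oscillation at `f`
#' (modulo 2 pi). The unwrapped table makes the correction continuous in
#' `f` across the passband.
#'
#' @param filter A `designed_filter`.
#' @param freq Frequency in Hz, inside `(0, fs/2)` (vectorized).
#' @return Correction in radians.
#' @export
phase_delay_correction <- function(filter, freq) {
  stopifnot(inherits(filter, "designed_filter"))
  if (any(freq <= 0 | freq >= filter$fs / 2)) {
    stop("freq must lie strictly inside (0, fs/2)")
  }
  tab <- filter$phase_table
  -stats::approx(tab$freq, tab$phase, xout = freq, rule = 2)$y
}

#' Export a designed filter to JSON
#'
#' Serializes sections, band, fs and design parameters for
#' cross-implementation comparison.
#'
#' @param filter A `designed_filter`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
filter_to_json <- function(filter, path = NULL) {
  stopifnot(inherits(filter, "designed_filter"))
  obj <- list(
    band = list(name = filter$band$name, low = filter$band$low,
                high = filter$band$high),
    fs = filter$fs, order = filter$order,
    passband_ripple = filter$passband_ripple,
    stopband_attenuation = filter$stopband_attenuation,
    sections = filter$sections
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a designed filter from JSON
#'
#' @param json Path to a JSON file written by [filter_to_json()], or the
#'   JSON string itself.
#' @return A `designed_filter`.
#' @export
filter_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  designed_filter(obj$sections,
                  frequency_band(obj$band$name, obj$band$low, obj$band$high),
                  fs = obj$fs, order = obj$order,
                  passband_ripple = obj$passband_ripple,
                  stopband_attenuation = obj$stopband_attenuation)
}
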