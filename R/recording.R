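#' Multichannel sampled recording
#'
#' The unit of I/O and evaluation: a channels x time numeric matrix with a
#' sampling rate. Values are microvolts for EEG and arbitrary units for
#' synthetic signals. Sample `k` (0-based) occurs at time `t0 + k / fs`
#' seconds.
#'
#' @param samples Numeric matrix, channels x time, or a numeric vector for a
#'   single channel. Must be finite throughout; NaN/Inf are rejected.
#' @param fs Sampling rate in Hz, `> 0`.
#' @param channel_labels Optional character vector, one label per channel;
#'   autogenerated as `"ch01"`, `"ch02"`, ... when missing.
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:499) / 500), fs = 500)
#' duration(rec)
#' @export
recording <- function(samples, fs, channel_labels = NULL, t0 = 0) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix (channels x time) or vector")
  }
  if (!all(is.finite(samples))) {
    stop("recording contains NaN/Inf values; refusing to ingest")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  nch <- nrow(samples)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nch))
  }
  if (length(channel_labels) != nch) {
    stop("channel_labels length must equal the number of channels")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels), t0 = as.numeric(t0)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$fs, duration(x)))
  invisible(x)
}

#' Number of samples per channel
#' @param rec A [recording].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Number of channels
#' @param rec A [recording].
#' @return Integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' Recording duration in seconds
#'
#' Exactly `n_samples / fs`.
#' @param rec A [recording].
#' @return Duration in seconds.
#' @export
duration <- function(rec) n_samples(rec) / rec$fs

#' Convert a duration in milliseconds to a sample count
#'
#' The package-wide convention: `round(ms * fs / 1000)`. Window durations
#' (`d_past_ms`, `d_future_ms`) are always specified in milliseconds and
#' converted with this single rule.
#'
#' @param ms Duration in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Integer number of samples.
#' @export
ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Read a recording from disk
#'
#' Supports European Data Format (EDF) files and plain delimited numeric
#' matrices (channels as rows). For delimited input the sampling rate must be
#' supplied; for EDF it comes from the header, as do channel labels.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"`, or `"delimited"`.
#' @param fs Sampling rate in Hz; required for delimited matrices, ignored
#'   for EDF.
#' @param sep Field separator for delimited input (default: whitespace/tab,
#'   as written by [write_recording()]).
#' @return A [recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           fs = NULL, sep = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") {
    return(read_edf(path))
  }
  if (is.null(fs)) stop("fs must be supplied for delimited-matrix input")
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) sep <- ","
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "numeric")
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  recording(m, fs = fs)
}

#' Write a recording as a delimited matrix
#'
#' Channels as rows, tab-separated, full double precision (`%.17g`), so a
#' write/read round trip reproduces the samples exactly. Optionally writes a
#' JSON sidecar with metadata (fs, labels, and any extra fields supplied).
#'
#' @param rec A [recording].
#' @param path Output file path.
#' @param sidecar If `TRUE`, also write `<path>.json` with fs, channel
#'   labels, t0 and `extra`.
#' @param extra Named list merged into the sidecar (e.g. the synthetic spec).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sidecar = FALSE, extra = NULL) {
  stopifnot(inherits(rec, "recording"))
  lines <- apply(rec$samples, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(lines, path)
  if (sidecar) {
    meta <- c(list(fs = rec$fs, channel_labels = rec$channel_labels,
                   t0 = rec$t0, n_samples = n_samples(rec)), extra)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Downsample a recording
#'
#' Anti-alias filters and decimates each channel (via [signal::decimate()],
#' 8th-order Chebyshev type-I lowpass). The target rate must divide the
#' source rate; duration is preserved to within one sample.
#'
#' @param rec A [recording].
#' @param target_fs Target sampling rate in Hz, `<= rec$fs`.
#' @return A [recording] at `target_fs`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:3999) / 2000), fs = 2000)
#' downsample(rec, 500)
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) {
    stop("target_fs must not exceed the recording's sampling rate")
  }
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop("target_fs must divide the recording's sampling rate")
  }
  q <- as.integer(round(q))
  dec <- t(apply(rec$samples, 1L, function(ch) {
    as.numeric(signal::decimate(ch, q, ftype = "iir"))
  }))
  if (nrow(rec$samples) == 1L) dec <- matrix(dec, nrow = 1L)
  recording(dec, fs = target_fs, channel_labels = rec$channel_labels,
            t0 = rec$t0)
}
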