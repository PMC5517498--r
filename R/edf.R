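# Minimal European Data Format (EDF) support: continuous recordings,
# 16-bit little-endian samples, one uniform sampling rate across signals.
# Annotation channels ("EDF Annotations") are skipped on read.

edf_read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n = n)))
}

#' Read an EDF file
#'
#' Parses the fixed 256-byte header, the per-signal headers, and all data
#' records, converting digital values to physical units via the per-signal
#' calibration. All retained signals must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @return A [recording] with channel labels from the EDF header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  edf_read_ascii(con, 8L)                       # version
  edf_read_ascii(con, 80L)                      # patient id
  edf_read_ascii(con, 80L)                      # recording id
  edf_read_ascii(con, 8L)                       # start date
  edf_read_ascii(con, 8L)                       # start time
  edf_read_ascii(con, 8L)                       # header bytes
  edf_read_ascii(con, 44L)                      # reserved
  n_records <- as.integer(edf_read_ascii(con, 8L))
  rec_dur <- as.numeric(edf_read_ascii(con, 8L))
  ns <- as.integer(edf_read_ascii(con, 4L))
  if (!is.finite(ns) || ns < 1L) stop("unreadable EDF: bad signal count")
  if (!is.finite(n_records) || n_records < 1L) {
    stop("unreadable EDF: unknown record count")
  }

  field <- function(width) {
    vapply(seq_len(ns), function(i) edf_read_ascii(con, width), character(1))
  }
  labels <- field(16L)
  field(80L)                                    # transducer
  field(8L)                                     # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                                    # prefiltering
  spr <- as.integer(field(8L))                  # samples per record
  field(32L)                                    # reserved

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF contains no data signals")
  if (length(unique(spr[keep])) != 1L) {
    stop("EDF signals have differing sampling rates; not supported")
  }
  fs <- spr[keep][1L] / rec_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  total_per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = total_per_rec * n_records,
                 size = 2L, signed = TRUE, endian = "little")
  if (length(raw) < total_per_rec * n_records) {
    stop("unreadable EDF: truncated data section")
  }

  offsets <- c(0L, cumsum(spr))
  out <- matrix(0, nrow = sum(keep), ncol = spr[keep][1L] * n_records)
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * total_per_rec
    ki <- 0L
    for (s in seq_len(ns)) {
      if (!keep[s]) next
      ki <- ki + 1L
      dig <- raw[(base + offsets[s] + 1L):(base + offsets[s + 1L])]
      phys <- phys_min[s] + (dig - dig_min[s]) * gain[s]
      out[ki, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  recording(out, fs = fs, channel_labels = labels[keep])
}

# Write a recording as a minimal EDF file (one data record per second).
# Used to build round-trip fixtures at test time; 16-bit quantization over
# the per-channel physical range applies.
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  ns <- n_channels(rec)
  spr <- as.integer(round(fs))
  n_records <- floor(n_samples(rec) / spr)
  if (n_records < 1L) stop("recording shorter than one 1 s data record")

  pad <- function(x, width) {
    s <- as.character(x)
    if (any(nchar(s) > width)) stop("EDF header field overflow")
    formatC(s, width = -width)
  }
  # Physical limits are written as <=8 ASCII chars; calibration must use the
  # printed (rounded) values so that a write/read round trip is consistent.
  fmt8 <- function(x) {
    s <- sprintf("%.6g", x)
    long <- nchar(s) > 8L
    s[long] <- sprintf("%.3g", x[long])
    s
  }
  phys_min <- apply(rec$samples, 1L, min)
  phys_max <- apply(rec$samples, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  rng <- phys_max - phys_min
  phys_min <- as.numeric(fmt8(phys_min - 0.02 * rng))
  phys_max <- as.numeric(fmt8(phys_max + 0.02 * rng))
  dig_min <- rep(-32768L, ns)
  dig_max <- rep(32767L, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad("0", 8), pad("synthetic", 80), pad("phaselock test fixture", 80),
    pad("01.01.26", 8), pad("00.00.00", 8), pad(hdr_bytes, 8),
    pad("", 44), pad(n_records, 8), pad("1", 8), pad(ns, 4),
    paste(vapply(rec$channel_labels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_min), pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), pad, "", width = 8), collapse = ""),
    paste(vapply(dig_min, pad, "", width = 8), collapse = ""),
    paste(vapply(dig_max, pad, "", width = 8), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(spr, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- rec$samples[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - phys_min[s]) / gain[s]) + dig_min[s])
      dig <- pmin(pmax(dig, dig_min[s]), dig_max[s])
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
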