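# Minimal EDF (European Data Format) reader/writer: ASCII header blocks,
# 16-bit little-endian samples, 1-second data records. Covers exactly what
# the toolkit needs — uniform sampling rate across channels, uV units — and
# validates what it reads.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a recording to an EDF file
#'
#' Standard EDF: 16-bit samples in 1-second records. The physical range is
#' chosen symmetrically per channel from the data, so the quantisation step
#' is `range / 2^16`. Samples beyond the last whole second are dropped (with
#' a message). Channel roles are encoded in the label prefix
#' (`"EEG "`/`"ECG "`).
#'
#' @param recording a [continuous_recording()] (integer sampling rate).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop_hv("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  nrec <- n_samples(recording) %/% fs
  if (nrec < 1L) stop_hv("recording shorter than one EDF record (1 s)")
  dropped <- n_samples(recording) - nrec * fs
  if (dropped > 0)
    message(sprintf("write_edf: dropped %d trailing sample(s) beyond the last whole second", dropped))
  ns <- nrow(recording$data)
  dat <- recording$data[, seq_len(nrec * fs), drop = FALSE]

  pmax_ <- apply(abs(dat), 1, max)
  pmax_ <- ifelse(pmax_ > 0, signif(pmax_ * 1.0001, 7), 1)
  dig_max <- 32767; dig_min <- -32768
  labels <- paste(toupper(substr(recording$channel_roles, 1, 3)),
                  recording$channel_labels)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8)                       # version
  wr("hepvalid", 80)               # patient id
  wr("synthetic", 80)              # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8)            # header bytes
  wr("", 44)
  wr(nrec, 8)
  wr(1, 8)                         # record duration (s)
  wr(ns, 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                 # transducer
  for (i in seq_len(ns)) wr("uV", 8)                # physical dimension
  for (i in seq_len(ns)) wr(formatC(-pmax_[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)                 # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)                  # samples per record
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dig_max - dig_min) / (2 * pmax_)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      d <- round((dat[i, cols] + pmax_[i]) * scale[i]) + dig_min
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Counterpart of [write_edf()]; requires an identical sampling rate across
#' channels and physical units of uV (or dimensionless). Roles are decoded
#' from the `EEG`/`ECG` label prefix (anything else becomes `"other"`).
#'
#' @param path EDF file path.
#' @return a [continuous_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop_hv("malformed EDF header (version field)")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, nrec, dur, ns)) || ns < 1L)
    stop_hv("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  if (!all(dims %in% c("uV", "")))
    stop_hv("unit mismatch: expected uV, got ", paste(unique(dims), collapse = ","))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop_hv("channels with different sampling rates are not supported")
  fs <- spr[1] / dur
  n_total <- nrec * spr[1]
  dat <- matrix(NA_real_, ns, n_total)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      dat[i, cols] <- pmin_[i] + (d - dmin[i]) *
        (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    }
  }
  role <- rep("other", ns)
  role[grepl("^EEG", labels)] <- "eeg"
  role[grepl("^ECG", labels)] <- "ecg"
  clean <- trimws(sub("^(EEG|ECG|OTH)\\s*", "", labels))
  clean[clean == ""] <- labels[clean == ""]
  if (anyDuplicated(clean)) clean <- make.unique(clean)
  continuous_recording(dat, fs, clean, role)
}
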