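# Minimal European Data Format (EDF, 16-bit) writer/reader for the
# single-channel synthetic EEG. No installed R package provides EDF I/O, so
# the subset needed here (continuous records, one or more channels, fixed
# record duration) is implemented directly against the format definition.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a single-channel EDF file
#'
#' @param path output file
#' @param samples numeric vector of samples (physical units, "uV")
#' @param sfreq sampling rate in Hz (samples per 1-s data record)
#' @param channel channel label (default "C3")
#' @return `path`, invisibly
#' @export
write_edf <- function(path, samples, sfreq, channel = "C3") {
  sfreq <- as.integer(sfreq)
  n_rec <- length(samples) %/% sfreq
  if (n_rec * sfreq != length(samples))
    stop_pmbr("sample count must be a multiple of sfreq (1-s records)")
  pmin_ <- min(samples); pmax_ <- max(samples)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((samples - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("synthetic cohort", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(1, 4),
    pad_field(channel, 16), pad_field("synthetic", 80), pad_field("uV", 8),
    pad_field(sprintf("%.4f", pmin_), 8), pad_field(sprintf("%.4f", pmax_), 8),
    pad_field(dmin, 8), pad_field(dmax, 8), pad_field("", 80),
    pad_field(sfreq, 8), pad_field("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Supports continuous multi-channel 16-bit EDF with a common record
#' structure; returns physical-unit samples.
#'
#' @param path EDF file
#' @return list with `channels` (named list of numeric vectors), `sfreq`
#'   (per channel, samples per record / record duration)
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  channels <- stats::setNames(vector("list", ns), labels)
  offsets <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer((offsets[i] + 1):offsets[i + 1],
                           (seq_len(n_rec) - 1) * rec_len, `+`))
    d <- raw[idx]
    channels[[i]] <- (d - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  list(channels = channels, sfreq = spr / rec_dur)
}
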