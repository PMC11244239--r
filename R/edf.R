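# Minimal European Data Format (EDF) I/O: continuous recordings, 16-bit
# samples, one data record per second. Covers what this pipeline needs
# (export of synthetic cohorts, import of plain continuous EEG); EDF+
# annotations and discontinuous files are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16 bits over the per-channel physical range, the
#' usual EDF resolution. The subject label is not representable in EDF and
#' is carried separately in a labels CSV (see [write_cohort_edf()]).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
edf_write <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dat <- rec$data
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  n_ch <- nrow(dat)
  n_rec <- floor(ncol(dat) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1-s data record")
  dat <- dat[, seq_len(n_rec * fs), drop = FALSE]

  phys_min <- apply(dat, 1, min)
  phys_max <- apply(dat, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # the header stores these as 8-char ASCII; quantise through that
  # representation so written samples scale by exactly what a reader sees
  fmt8 <- function(x) vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8L) return(s)
    }
    formatC(v, format = "e", digits = 1)
  }, "")
  phys_min_s <- fmt8(phys_min)
  phys_max_s <- fmt8(phys_max)
  phys_min <- as.numeric(phys_min_s)
  phys_max <- as.numeric(phys_max_s)
  if (any(phys_max - phys_min <= 0))
    stop("channel range collapses under 8-character header formatting")
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad("strokeEEG export", 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * n_ch, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(n_ch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(phys_min_s, 8)
  field(phys_max_s, 8)
  field(rep(dig_min, n_ch), 8)
  field(rep(dig_max, n_ch), 8)
  field(rep("", n_ch), 80)
  field(rep(fs, n_ch), 8)
  field(rep("", n_ch), 32)

  # physical -> digital, per channel
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- dat[, idx, drop = FALSE]
    dig <- round((block - phys_min) * scale + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    # records are channel-major: all samples of ch1, then ch2, ...
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with a uniform sampling rate across signals.
#'
#' @param path EDF file path.
#' @param label Optional class label to attach.
#' @return An [eeg_recording()].
#' @export
edf_read <- function(path, label = NA_integer_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))   # samples per record, per signal
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, n_ch, n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = n_ch)  # channel-major records
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    dat[, idx] <- t((block - rep(dig_min, each = spr[1])) *
                      rep(scale, each = spr[1]) +
                      rep(phys_min, each = spr[1]))
  }
  eeg_recording(dat, fs = fs, channel_names = labels,
                subject_id = subject_id, label = label)
}
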