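# Minimal European Data Format (EDF) I/O: 16-bit integer samples with
# per-channel physical scaling in microvolts. Covers plain continuous EDF
# (no EDF+ annotations), which is all the pipeline needs for interchange.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records and symmetric per-channel
#' physical ranges in microvolts. A trailing partial record is dropped.
#'
#' @param rec An `eeg_recording` with integer samples-per-second rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop_relbeta("EDF writer requires an integer sampling rate", "edf_error")
  }
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop_relbeta("recording shorter than one data record", "edf_error")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  # integer physical range: what the header prints is exactly what scaling uses
  pmax_ <- as.integer(pmax(ceiling(apply(abs(data), 1, max)), 1))
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(rec$labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(sprintf("%d", -pmax_), 8), collapse = ""),
    paste(edf_pad(sprintf("%d", pmax_), 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # the exact EDF affine map (phys_min = -pmax, dig range -32768..32767),
  # so the reader's inverse reproduces samples to half a digital step
  scale <- (dig_max - (-32768)) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round((data[, idx, drop = FALSE] + pmax_) * scale - 32768)
    block <- pmin(pmax(block, -32768), 32767)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param montage Optional montage to attach; defaults to
#'   [standard_montage_1020()] when every channel label matches it.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1L) {
    stop_relbeta("mixed per-signal sampling rates are not supported", "edf_error")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t((block - rep(dmin, each = spr[1])) *
                       rep(scale, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  if (is.null(montage)) {
    std <- standard_montage_1020()
    if (all(labels %in% std$labels)) montage <- std
  }
  recording(data, fs, labels, montage = montage)
}
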