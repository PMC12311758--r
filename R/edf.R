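#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, physical units microvolts. The sampling rate must be a whole
#' number of samples per second. Condition annotations, if present, are
#' written to a sidecar CSV (`<path>.annotations.csv` with columns
#' `onset_s, duration_s, label`), keeping the EDF itself plain.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- n %/% fs                     # trailing partial second dropped
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")

  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256L * (n_ch + 1L)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(n_ch), 4)),
    con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w = w),
                                            collapse = ""), con, eos = NULL)
  fld(rec$labels, 16)
  fld(rep("EEG", n_ch), 80)
  fld(rep("uV", n_ch), 8)
  fld(formatC(pmin_, format = "g", digits = 7), 8)
  fld(formatC(pmax_, format = "g", digits = 7), 8)
  fld(rep(as.character(dmin), n_ch), 8)
  fld(rep(as.character(dmax), n_ch), 8)
  fld(rep("", n_ch), 80)
  fld(rep(as.character(fs), n_ch), 8)
  fld(rep("", n_ch), 32)

  # re-read the exact physical min/max as they will be parsed, so the
  # round trip is lossless to 16-bit quantization
  pmin_r <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  gain <- (pmax_r - pmin_r) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(n_ch)) {
      dig <- round((rec$data[ch, idx] - pmin_r[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  if (!is.null(rec$annotations)) {
    utils::write.csv(rec$annotations, paste0(path, ".annotations.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [write_edf()]. If a sidecar `<path>.annotations.csv`
#' exists (or `annotations` names a CSV with columns
#' `onset_s, duration_s, label`), the segments are attached to the
#' recording.
#'
#' @param path EDF file path.
#' @param annotations optional path to an annotations CSV.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, a, b) trimws(substr(s, a, b))
  n_rec <- as.integer(fld(hdr, 237, 244))
  rec_dur <- as.numeric(fld(hdr, 245, 252))
  n_ch <- as.integer(fld(hdr, 253, 256))
  sh <- readChar(con, 256L * n_ch, useBytes = TRUE)
  grab <- function(off, w) {
    vapply(seq_len(n_ch), function(i) {
      trimws(substr(sh, off + (i - 1L) * w + 1L, off + i * w))
    }, "")
  }
  off <- 0L
  labels <- grab(off, 16); off <- off + 16L * n_ch
  off <- off + 80L * n_ch + 8L * n_ch     # transducer, unit
  pmin_ <- as.numeric(grab(off, 8)); off <- off + 8L * n_ch
  pmax_ <- as.numeric(grab(off, 8)); off <- off + 8L * n_ch
  dmin <- as.numeric(grab(off, 8)); off <- off + 8L * n_ch
  dmax <- as.numeric(grab(off, 8)); off <- off + 8L * n_ch
  off <- off + 80L * n_ch                  # prefiltering
  spr <- as.integer(grab(off, 8))          # samples per record

  data <- matrix(0, n_ch, n_rec * spr[1])
  if (length(unique(spr)) != 1L) stop("unequal per-channel sampling rates are not supported")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  ann <- NULL
  side <- if (!is.null(annotations)) annotations else paste0(path, ".annotations.csv")
  if (file.exists(side)) {
    ann <- tibble::as_tibble(utils::read.csv(side, stringsAsFactors = FALSE))
  }
  new_recording(data, spr[1] / rec_dur, labels = labels, annotations = ann)
}
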