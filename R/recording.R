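#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples matrix with its sampling rate and channel
#' metadata. All preprocessing and decomposition functions take and return
#' this class, so a pipeline reads naturally left to right.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel labels (10-10 names where
#'   applicable). Defaults to `"ch1"..."chN"`.
#' @param positions optional tibble/data.frame with columns `label, x, y, z`
#'   giving unit-sphere electrode coordinates (see [montage_1010()]).
#' @param bad_channels character vector of labels marked bad by the operator;
#'   must be a subset of `labels`.
#' @param annotations optional tibble with columns `onset_s, duration_s, label`
#'   marking condition segments (e.g. "eyes-closed").
#' @param splices numeric vector of sample indices (last sample before a
#'   splice) where non-contiguous segments were concatenated. Downstream
#'   windowing never crosses a splice.
#'
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels = NULL, positions = NULL,
                          bad_channels = character(), annotations = NULL,
                          splices = numeric()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  n_ch <- nrow(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_ch))
  if (length(labels) != n_ch) stop("`labels` must have one entry per channel")
  if (!all(bad_channels %in% labels)) {
    stop("bad_channels must be a subset of channel labels")
  }
  if (!is.null(positions)) {
    positions <- tibble::as_tibble(positions)
    stopifnot(all(c("label", "x", "y", "z") %in% names(positions)))
    nrm <- sqrt(positions$x^2 + positions$y^2 + positions$z^2)
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("electrode positions must lie on the unit sphere (|r| = 1 within 1e-6)")
    }
  }
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("onset_s", "duration_s", "label") %in% names(annotations)))
  }
  structure(
    list(data = data, fs = fs, labels = labels, positions = positions,
         bad_channels = bad_channels, annotations = annotations,
         splices = as.numeric(splices)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  if (length(x$splices)) cat("  splices at samples:", paste(x$splices, collapse = ", "), "\n")
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotation segment(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Extract annotated condition segments
#'
#' Concatenates all annotation segments carrying `label` (default the
#' eyes-closed resting condition) into one recording, storing the splice
#' points so that later windowing never crosses a segment boundary. Subjects
#' retaining less than `min_duration` seconds of the condition are rejected
#' with an error, mirroring the usual artifact-cleaning exclusion rule.
#'
#' @param rec an `eeg_recording` with annotations.
#' @param label condition label to select.
#' @param min_duration minimum total duration in seconds; shorter totals
#'   raise a subject-rejection error. Default 60 s.
#' @return an `eeg_recording` containing only the selected condition.
#' @export
select_condition <- function(rec, label = "eyes-closed", min_duration = 60) {
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0L) {
    stop("recording has no annotations; cannot select a condition")
  }
  ann <- rec$annotations[rec$annotations$label == label, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop(sprintf("no annotation segment labelled '%s' (available: %s)", label,
                 paste(unique(rec$annotations$label), collapse = ", ")))
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  n <- ncol(rec$data)
  pieces <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    i0 <- max(1L, floor(ann$onset_s[i] * rec$fs) + 1L)
    i1 <- min(n, floor((ann$onset_s[i] + ann$duration_s[i]) * rec$fs))
    if (i1 < i0) stop("annotation segment outside the recording")
    pieces[[i]] <- rec$data[, i0:i1, drop = FALSE]
  }
  lens <- vapply(pieces, ncol, integer(1))
  total_s <- sum(lens) / rec$fs
  if (total_s < min_duration) {
    stop(sprintf(
      "subject rejected: only %.1f s of '%s' data (< %g s minimum)",
      total_s, label, min_duration))
  }
  splices <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] else numeric()
  out <- rec
  out$data <- do.call(cbind, pieces)
  out$annotations <- NULL
  out$splices <- splices
  out
}
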