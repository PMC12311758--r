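#' Standard preprocessing pipeline
#'
#' Applies the fixed conditioning order notch -> bad-channel interpolation
#' -> FIR band-pass -> surface Laplacian -> condition selection, with each
#' stage individually switchable (e.g. the Laplacian is usually skipped for
#' low-density synthetic montages). The applied order is recorded in the
#' `"pipeline"` attribute of the result.
#'
#' @param rec an `eeg_recording`.
#' @param notch,interpolate,bandpass,laplacian,select logical stage switches.
#' @param condition condition label for the selection stage.
#' @param ... currently unused.
#' @return preprocessed `eeg_recording` with attribute `"pipeline"`.
#' @export
preprocess_pipeline <- function(rec, notch = TRUE, interpolate = TRUE,
                                bandpass = TRUE, laplacian = TRUE,
                                select = TRUE, condition = "eyes-closed",
                                ...) {
  applied <- character()
  if (notch) { rec <- notch_filter(rec); applied <- c(applied, "notch") }
  if (interpolate && length(rec$bad_channels)) {
    rec <- interpolate_bad_channels(rec); applied <- c(applied, "interpolate")
  }
  if (bandpass) { rec <- bandpass_fir(rec); applied <- c(applied, "bandpass") }
  if (laplacian) { rec <- surface_laplacian(rec); applied <- c(applied, "laplacian") }
  if (select && !is.null(rec$annotations)) {
    rec <- select_condition(rec, condition); applied <- c(applied, "select")
  }
  attr(rec, "pipeline") <- applied
  rec
}

#' Notch filter for power-line noise
#'
#' Zero-phase Butterworth band-stop (applied forward and backward with
#' [signal::filtfilt()]) centered on the mains frequency. Output length
#' equals input length and zero-phase application leaves phase metrics
#' (wPLI) untouched.
#'
#' @param rec an `eeg_recording`.
#' @param freq mains frequency in Hz (default 50).
#' @param order filter order (default 2).
#' @param width full stop-band width in Hz (default 4, i.e. freq +/- 2).
#' @return filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 50, order = 2, width = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (freq >= nyq) {
    stop(sprintf("notch frequency %g Hz is at or above Nyquist (%g Hz)", freq, nyq))
  }
  band <- c(freq - width / 2, freq + width / 2) / nyq
  bt <- signal::butter(order, band, type = "stop")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- signal::filtfilt(bt, rec$data[ch, ])
  }
  out
}

# linear convolution via FFT, returning the same-length segment after
# compensating the (linear-phase) group delay of a length-(order+1) kernel
fft_filt_zerophase <- function(x, h) {
  n <- length(x); m <- length(h)
  delay <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[(delay + 1L):(delay + n)]
}

#' FIR band-pass filter (Kaiser window)
#'
#' Linear-phase FIR band-pass designed with [signal::fir1()] and a Kaiser
#' window, applied in a single forward pass with exact group-delay
#' compensation (linear phase makes the delay a constant `order/2` samples),
#' so the output is zero-phase.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz (defaults 1 and 80).
#' @param order FIR order (default 1858).
#' @param kaiser_beta Kaiser window shape parameter (default 5).
#' @return filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, lo = 1, hi = 80, order = 1858, kaiser_beta = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo < hi && hi < nyq)) stop("need lo < hi < fs/2")
  n <- ncol(rec$data)
  if (n < 3 * order) {
    stop(sprintf("signal too short for order-%d FIR: need >= %d samples, have %d",
                 order, 3 * order, n))
  }
  h <- signal::fir1(order, c(lo, hi) / nyq, type = "pass",
                    window = signal::kaiser(order + 1, kaiser_beta))
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- fft_filt_zerophase(rec$data[ch, ], h)
  }
  out
}

# ---- spherical-spline machinery (Perrin et al. style) ----

# Legendre polynomials P_1..P_nmax evaluated at each element of x;
# returns matrix length(x) x nmax
legendre_table <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- 0.5 * (3 * x^2 - 1)
  for (nn in 3:nmax) {
    P[, nn] <- ((2 * nn - 1) * x * P[, nn - 1] - (nn - 1) * P[, nn - 2]) / nn
  }
  P
}

# g(cos gamma) for interpolation (order m) and h(cos gamma) for the surface
# Laplacian (order m-1), truncated at n_terms Legendre terms. Terms decay as
# n^(1-2m) so 50 terms put the truncation error below 1e-6 for m = 4.
spline_g <- function(cosg, m = 4, n_terms = 50L) {
  nn <- seq_len(n_terms)
  w <- (2 * nn + 1) / (nn * (nn + 1))^m
  P <- legendre_table(as.vector(cosg), n_terms)
  matrix(P %*% w / (4 * pi), nrow = nrow(as.matrix(cosg)))
}

spline_h <- function(cosg, m = 4, n_terms = 50L) {
  nn <- seq_len(n_terms)
  w <- (2 * nn + 1) / (nn * (nn + 1))^(m - 1)
  P <- legendre_table(as.vector(cosg), n_terms)
  matrix(P %*% w / (4 * pi), nrow = nrow(as.matrix(cosg)))
}

positions_matrix <- function(rec, labels) {
  if (is.null(rec$positions)) {
    stop("recording has no electrode positions; supply a montage (see montage_1010())")
  }
  idx <- match(labels, rec$positions$label)
  if (anyNA(idx)) {
    stop("positions missing for channels: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  as.matrix(rec$positions[idx, c("x", "y", "z")])
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the channels listed in `bad_channels` by spherical-spline
#' estimates (order `m`, ridge regularization `lambda`) computed from the
#' good channels; good channels are returned unchanged. Which channels are
#' bad is operator-supplied metadata, not detected automatically.
#'
#' @param rec an `eeg_recording` with electrode positions and a non-empty
#'   `bad_channels` list. An empty list returns the input unchanged.
#' @param m spline order (default 4).
#' @param lambda regularization added to the spline system (default 1e-5).
#' @param n_terms Legendre series truncation (default 50).
#' @return `eeg_recording` with interpolated channels and `bad_channels`
#'   cleared.
#' @export
interpolate_bad_channels <- function(rec, m = 4, lambda = 1e-5, n_terms = 50L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$bad_channels) == 0L) return(rec)
  good <- setdiff(rec$labels, rec$bad_channels)
  if (length(good) < 4L) stop("need at least 4 good channels to interpolate")
  Pg <- positions_matrix(rec, good)
  Pb <- positions_matrix(rec, rec$bad_channels)
  ng <- length(good)
  G <- spline_g(tcrossprod(Pg), m, n_terms)
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  rhs <- rbind(rec$data[match(good, rec$labels), , drop = FALSE], 0)
  C <- solve(A, rhs)
  Gb <- spline_g(tcrossprod(Pb, Pg), m, n_terms)
  est <- Gb %*% C[seq_len(ng), , drop = FALSE] +
    matrix(C[ng + 1L, ], nrow(Pb), ncol(rec$data), byrow = TRUE)
  out <- rec
  out$data[match(rec$bad_channels, rec$labels), ] <- est
  out$bad_channels <- character()
  out
}

#' Spherical-spline surface Laplacian (scalp current density)
#'
#' Perrin-style current-source-density transform: a spherical spline of
#' order `m_order` with regularization `lambda` is fitted to each time
#' sample across channels and its surface Laplacian is evaluated at the
#' electrodes. The transform removes any channel-common offset (the
#' Laplacian of a spatially constant field is zero) and sharpens focal
#' topographies.
#'
#' @param rec an `eeg_recording` with positions for all channels.
#' @param lambda spline regularization (default 1e-5).
#' @param m_order spline order (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @return `eeg_recording` whose data are scalp current densities.
#' @export
surface_laplacian <- function(rec, lambda = 1e-5, m_order = 4, n_terms = 50L) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  if (n_ch < 16L) {
    warning("fewer than 16 channels: surface Laplacian is poorly conditioned")
  }
  P <- positions_matrix(rec, rec$labels)
  G <- spline_g(tcrossprod(P), m_order, n_terms)
  H <- spline_h(tcrossprod(P), m_order, n_terms)
  A <- rbind(cbind(G + diag(lambda, n_ch), 1), c(rep(1, n_ch), 0))
  C <- solve(A, rbind(rec$data, 0))
  out <- rec
  out$data <- H %*% C[seq_len(n_ch), , drop = FALSE]
  out
}
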