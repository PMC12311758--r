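#' Log-spaced Morlet wavelet bank
#'
#' Thirty center frequencies log-spaced over 2-70 Hz,
#' `freqs[k] = 2 * 35^(k/29)` for k = 0..29, with cycles parameter m (the
#' ratio of center frequency to the Gaussian bandwidth of the wavelet:
#' temporal SD `sigma_t = m / (2*pi*f)`).
#'
#' @param fs sampling rate in Hz; must exceed twice the top frequency.
#' @param n_freqs number of wavelets (default 30).
#' @param f_range frequency range in Hz (default c(2, 70)).
#' @param m cycles parameter (default 5).
#' @return an object of class `wavelet_bank` with fields `freqs`, `m`, `fs`.
#' @export
make_bank <- function(fs, n_freqs = 30L, f_range = c(2, 70), m = 5) {
  stopifnot(m > 0, n_freqs >= 1, f_range[1] > 0, f_range[2] >= f_range[1])
  if (n_freqs > 1L && f_range[2] <= f_range[1]) {
    stop("f_range must be increasing for a multi-frequency bank")
  }
  if (fs <= 2 * f_range[2]) {
    stop(sprintf("fs = %g Hz violates the Nyquist constraint: need fs > %g Hz",
                 fs, 2 * f_range[2]))
  }
  freqs <- if (n_freqs == 1L) f_range[1] else {
    k <- seq_len(n_freqs) - 1L
    f_range[1] * (f_range[2] / f_range[1])^(k / (n_freqs - 1L))
  }
  structure(list(freqs = freqs, m = m, fs = fs), class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank> %d Morlet wavelets, %.3g-%.3g Hz (m = %g) @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$m, x$fs))
  invisible(x)
}

#' Index of the bank frequency nearest a target
#' @param bank a [make_bank()] object.
#' @param freq target frequency in Hz.
#' @return integer index into `bank$freqs`.
#' @export
nearest_freq <- function(bank, freq) which.min(abs(bank$freqs - freq))

#' Morlet time-frequency decomposition
#'
#' Convolves every channel with complex Morlet wavelets
#' `w(t) = (sigma_t * sqrt(pi))^{-1/2} exp(-t^2 / (2 sigma_t^2)) exp(i 2 pi f t)`
#' (L2-normalized, `sigma_t = m/(2*pi*f)`) via FFT with reflection padding.
#' The modulus of the coefficients is the amplitude envelope; the argument is
#' the instantaneous phase. Samples within 3 `sigma_t` of the recording edges
#' or of any splice are flagged invalid and excluded by all downstream
#' metrics, never silently included.
#'
#' @param rec an `eeg_recording` (after preprocessing).
#' @param bank a [make_bank()] wavelet bank with `bank$fs == rec$fs`.
#' @return an object of class `nb_decomposition`: list with `coeffs`
#'   (complex array channels x frequencies x time), `freqs`, `fs`, `labels`,
#'   `valid` (logical frequencies x time mask) and `splices`.
#' @export
nb_transform <- function(rec, bank) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(bank, "wavelet_bank"))
  if (abs(bank$fs - rec$fs) > 1e-9) stop("bank and recording sampling rates differ")
  n <- ncol(rec$data)
  lowest <- min(bank$freqs)
  if (n / rec$fs < 10 / lowest) {
    stop(sprintf("recording too short: need at least 10 cycles of %.3g Hz (%.1f s)",
                 lowest, 10 / lowest))
  }
  n_ch <- nrow(rec$data)
  n_f <- length(bank$freqs)
  pad <- min(n - 2L, ceiling(3 * bank$m / (2 * pi * lowest) * rec$fs) + 1L)
  n_ext <- n + 2L * pad
  nfft <- stats::nextn(n_ext, 2)
  fgrid <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) * rec$fs / nfft

  coeffs <- array(complex(real = NA_real_), dim = c(n_ch, n_f, n))
  X <- matrix(complex(real = 0), nrow = nfft, ncol = n_ch)
  for (ch in seq_len(n_ch)) {
    x <- rec$data[ch, ]
    # reflection padding suppresses wrap-around transients
    xe <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[(n - pad):(n - 1L)]))
    X[, ch] <- stats::fft(c(xe, numeric(nfft - n_ext)))
  }
  for (fi in seq_len(n_f)) {
    f0 <- bank$freqs[fi]
    sigma_t <- bank$m / (2 * pi * f0)
    # frequency response of the L2-normalized analytic Morlet
    H <- (4 * pi * sigma_t^2)^(1 / 4) *
      exp(-2 * pi^2 * sigma_t^2 * (fgrid - f0)^2)
    for (ch in seq_len(n_ch)) {
      y <- stats::fft(X[, ch] * H, inverse = TRUE) / nfft
      coeffs[ch, fi, ] <- y[(pad + 1L):(pad + n)]
    }
  }

  valid <- matrix(TRUE, nrow = n_f, ncol = n)
  for (fi in seq_len(n_f)) {
    guard <- ceiling(3 * bank$m / (2 * pi * bank$freqs[fi]) * rec$fs)
    bad <- c(seq_len(min(guard, n)), seq(max(1L, n - guard + 1L), n))
    for (sp in rec$splices) {
      bad <- c(bad, max(1L, sp - guard + 1L):min(n, sp + guard))
    }
    valid[fi, unique(bad)] <- FALSE
  }
  structure(
    list(coeffs = coeffs, freqs = bank$freqs, fs = rec$fs, m = bank$m,
         labels = rec$labels, valid = valid, splices = rec$splices),
    class = "nb_decomposition")
}

#' @export
print.nb_decomposition <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<nb_decomposition> %d channel(s) x %d frequencies x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Amplitude envelope of one channel x frequency series
#' @param decomp an `nb_decomposition`.
#' @param channel channel index or label.
#' @param freq_index index into `decomp$freqs`.
#' @param valid_only drop invalid (edge/splice) samples; default TRUE.
#' @return numeric envelope vector.
#' @export
envelope <- function(decomp, channel = 1L, freq_index = 1L, valid_only = TRUE) {
  if (is.character(channel)) channel <- match(channel, decomp$labels)
  e <- Mod(decomp$coeffs[channel, freq_index, ])
  if (valid_only) e <- e[decomp$valid[freq_index, ]] else e
  e
}
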