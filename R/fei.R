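#' Functional excitation-inhibition ratio
#'
#' Computes fEI from a narrowband amplitude envelope in windows of a fixed
#' number of carrier cycles (default 40) with 80% overlap. Per window i:
#' `wAmp_i` is the mean envelope; the window profile is the cumulative sum
#' of `envelope / wAmp_i - 1`; `wDNF_i` is the RMS of the linearly detrended
#' profile. Then `fEI = 1 - r(wAmp, wDNF)` with `r` the Pearson correlation
#' across windows. A balanced (critical) signal gives fEI = 1; inhibition
#' dominance gives fEI < 1; excitation dominance gives fEI > 1.
#'
#' fEI is only defined for signals with long-range temporal correlations:
#' when the supplied DFA exponent is <= 0.6 the statistic is returned as
#' missing, because envelopes without LRTC do not exhibit the
#' amplitude-fluctuation covariation the ratio is built on.
#'
#' @param envelope positive numeric amplitude envelope.
#' @param freq carrier (wavelet) frequency in Hz; fixes the window length
#'   `window_cycles / freq` seconds.
#' @param fs_env envelope sampling rate in Hz.
#' @param dfa_exponent the envelope's DFA scaling exponent (gate at 0.6).
#' @param window_cycles window length in carrier cycles (default 40).
#' @param overlap fractional window overlap (default 0.8).
#' @param valid optional logical mask; windows containing invalid samples
#'   (edges, splices) are excluded.
#' @param min_windows minimum number of usable windows (default 20).
#' @return list of class `fei_fit`: `fei` (NA when gated or degenerate),
#'   `valid` (FALSE when the DFA gate failed), `n_windows`, `n_dropped`
#'   (zero-amplitude windows), `window_cycles`, `overlap`.
#' @export
fei <- function(envelope, freq, fs_env, dfa_exponent, window_cycles = 40,
                overlap = 0.8, valid = NULL, min_windows = 20L) {
  envelope <- as.numeric(envelope)
  n <- length(envelope)
  if (is.null(valid)) valid <- rep(TRUE, n)
  out <- function(fei, ok, n_win = 0L, n_drop = 0L) {
    structure(list(fei = fei, valid = ok, n_windows = n_win,
                   n_dropped = n_drop, window_cycles = window_cycles,
                   overlap = overlap), class = "fei_fit")
  }
  if (is.na(dfa_exponent) || dfa_exponent <= 0.6) return(out(NA_real_, FALSE))

  L <- max(4L, round(window_cycles / freq * fs_env))
  step <- max(1L, round(L * (1 - overlap)))
  if (n < L) stop("envelope shorter than one fEI window")
  starts <- seq(1L, n - L + 1L, by = step)   # final partial window discarded
  bad_cum <- c(0L, cumsum(!valid))
  starts <- starts[bad_cum[starts + L] - bad_cum[starts] == 0L]
  if (length(starts) < min_windows) {
    stop(sprintf("need at least %d fEI windows, have %d usable",
                 min_windows, length(starts)))
  }
  idx <- outer(seq_len(L) - 1L, starts, "+")
  W <- matrix(envelope[idx], nrow = L)
  w_amp <- colMeans(W)
  drop <- w_amp <= 0
  n_drop <- sum(drop)
  if (n_drop / length(starts) > 0.2) return(out(NA_real_, TRUE, 0L, n_drop))
  W <- W[, !drop, drop = FALSE]
  w_amp <- w_amp[!drop]
  Wn <- sweep(W, 2L, w_amp, "/") - 1
  P <- apply(Wn, 2L, cumsum)
  tt <- seq_len(L)
  X <- cbind(1, tt)
  cf <- solve(crossprod(X), crossprod(X, P))
  R <- P - X %*% cf
  w_dnf <- sqrt(colMeans(R * R))
  if (stats::sd(w_amp) == 0 || stats::sd(w_dnf) == 0) return(out(NA_real_, TRUE, ncol(W), n_drop))
  out(1 - stats::cor(w_amp, w_dnf), TRUE, ncol(W), n_drop)
}

#' @export
print.fei_fit <- function(x, ...) {
  if (!x$valid) {
    cat("<fei_fit> not computed: DFA exponent <= 0.6 (no LRTC)\n")
  } else {
    cat(sprintf("<fei_fit> fEI = %.3f over %d windows (%d dropped)\n",
                x$fei, x$n_windows, x$n_dropped))
  }
  invisible(x)
}
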