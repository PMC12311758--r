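#' Detrended fluctuation analysis of an amplitude envelope
#'
#' Classic first-order DFA: the mean-centered envelope is cumulatively
#' summed into a profile; for each window size the profile is cut into
#' 50%-overlapping windows, each window is least-squares linearly detrended,
#' and the fluctuation function F(n) is the root mean square residual
#' averaged over windows. The DFA scaling exponent is the slope of
#' log F(n) vs log n. An exponent of 0.5 characterizes a temporally
#' uncorrelated envelope, values in (0.5, 1] positive long-range temporal
#' correlations, values below 0.5 anti-correlations.
#'
#' Window sizes default to 10 log-spaced values between `min_cycles` carrier
#' cycles and one tenth of the valid envelope length. The lower bound of 40
#' cycles keeps the fit above the temporal autocorrelation imposed by the
#' m = 5 Morlet kernel, which would otherwise inflate the exponent of even
#' an uncorrelated envelope (see the methods vignette).
#'
#' @param envelope positive numeric vector (amplitude envelope).
#' @param fs_env sampling rate of the envelope in Hz.
#' @param window_sizes optional window sizes in seconds (strictly
#'   increasing). When NULL they are derived from `freq`.
#' @param freq carrier (wavelet) frequency in Hz, used for the default
#'   window grid; required when `window_sizes` is NULL.
#' @param n_sizes number of log-spaced window sizes (default 10).
#' @param overlap fractional window overlap (default 0.5).
#' @param min_cycles smallest window size in carrier cycles (default 40).
#' @param valid optional logical vector marking usable samples; windows
#'   containing any invalid sample (edge transients, splices) are skipped.
#' @return object of class `dfa_fit`: list with `exponent`, `fit_r2`,
#'   `window_sizes` (seconds), `fluctuation` F(n), `n_windows`, and a
#'   `degenerate` flag (TRUE, with NA exponent, for a constant envelope).
#' @export
dfa <- function(envelope, fs_env, window_sizes = NULL, freq = NULL,
                n_sizes = 10L, overlap = 0.5, min_cycles = 40, valid = NULL) {
  envelope <- as.numeric(envelope)
  n <- length(envelope)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(valid) == n)
  nv <- sum(valid)
  if (nv < 8L) stop("too few valid samples for DFA")
  if (stats::sd(envelope[valid]) < 1e-12 * max(abs(envelope[valid]), 1e-300)) {
    return(structure(list(exponent = NA_real_, fit_r2 = NA_real_,
                          window_sizes = numeric(), fluctuation = numeric(),
                          n_windows = integer(), degenerate = TRUE),
                     class = "dfa_fit"))
  }
  if (is.null(window_sizes)) {
    if (is.null(freq)) stop("supply either `window_sizes` or `freq`")
    w_min <- min_cycles / freq
    w_max <- nv / fs_env / 10
    if (w_max <= w_min) {
      stop(sprintf(
        "valid envelope too short for DFA at %g Hz: need > %.1f s, have %.1f s",
        freq, 10 * w_min, nv / fs_env))
    }
    window_sizes <- exp(seq(log(w_min), log(w_max), length.out = n_sizes))
  }
  if (is.unsorted(window_sizes, strictly = TRUE)) stop("window_sizes must be strictly increasing")

  lens <- unique(pmax(4L, round(window_sizes * fs_env)))
  mu <- mean(envelope[valid])
  prof <- cumsum(ifelse(valid, envelope - mu, 0))
  bad_cum <- c(0L, cumsum(!valid))

  Fn <- numeric(length(lens))
  n_win <- integer(length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    step <- max(1L, round(L * (1 - overlap)))
    starts <- seq(1L, n - L + 1L, by = step)
    # keep only fully valid windows
    starts <- starts[bad_cum[starts + L] - bad_cum[starts] == 0L]
    if (length(starts) < 2L) { Fn[i] <- NA; next }
    idx <- outer(seq_len(L) - 1L, starts, "+")
    W <- matrix(prof[idx], nrow = L)
    tt <- seq_len(L)
    X <- cbind(1, tt)
    cf <- solve(crossprod(X), crossprod(X, W))
    R <- W - X %*% cf
    Fn[i] <- sqrt(mean(colMeans(R * R)))
    n_win[i] <- length(starts)
  }
  keep <- is.finite(Fn) & Fn > 0
  if (sum(keep) < 3L) stop("too few usable window sizes for the DFA fit")
  lx <- log10(lens[keep] / fs_env)
  ly <- log10(Fn[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(exponent = unname(fit$coefficients[2]), fit_r2 = r2,
                 window_sizes = lens[keep] / fs_env,
                 fluctuation = Fn[keep], n_windows = n_win[keep],
                 degenerate = FALSE),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<dfa_fit> degenerate input (constant envelope); exponent undefined\n")
  } else {
    cat(sprintf("<dfa_fit> exponent %.3f (r2 = %.4f) over %d window sizes %.2f-%.2f s\n",
                x$exponent, x$fit_r2, length(x$window_sizes),
                min(x$window_sizes), max(x$window_sizes)))
  }
  invisible(x)
}

#' Plot the DFA fluctuation function
#'
#' Log-log fluctuation function with the fitted power law; the slope is the
#' DFA scaling exponent.
#'
#' @param object a `dfa_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dfa_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_size_s, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window size (s)", y = "F(n)",
                  title = sprintf("DFA exponent %.3f (r² = %.3f)",
                                  object$exponent, object$fit_r2))
}

#' @rdname dfa
#' @param x a `dfa_fit`.
#' @param ... unused.
#' @export
tidy.dfa_fit <- function(x, ...) {
  tibble::tibble(window_size_s = x$window_sizes, fluctuation = x$fluctuation,
                 n_windows = x$n_windows)
}

#' @rdname dfa
#' @export
glance.dfa_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, fit_r2 = x$fit_r2,
                 n_sizes = length(x$window_sizes), degenerate = x$degenerate)
}
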