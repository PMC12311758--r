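#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary fractional Gaussian noise (fGn) with Hurst
#' exponent `hurst` using the Davies-Harte / circulant-embedding method: the
#' target autocovariance is embedded in a circulant matrix whose eigenvalues
#' are obtained by FFT, so the sample has exactly the fGn covariance
#' \deqn{\rho(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#' This is the ground-truth engine behind the synthetic envelope generators:
#' the DFA exponent of an fGn series equals its Hurst exponent.
#'
#' @param n number of samples.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return numeric vector of length `n`, marginally N(0, 1).
#' @export
#' @examples
#' z <- fgn(1024, hurst = 0.75, seed = 1)
fgn <- function(n, hurst, seed = NULL) {
  stopifnot(n >= 2, hurst > 0, hurst < 1)
  if (!is.null(seed)) set.seed(seed)
  if (abs(hurst - 0.5) < 1e-12) return(stats::rnorm(n))
  m <- 2L^ceiling(log2(2L * (n - 1L)))
  k <- 0:(m %/% 2L)
  acf_k <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
  # first row of the circulant embedding: acf then its mirror
  row <- c(acf_k, rev(acf_k[2:(m %/% 2L)]))
  ev <- Re(stats::fft(row))
  if (min(ev) < -1e-8 * max(ev)) {
    # embedding size too small for this H; double until nonnegative
    return(fgn_embed_grow(n, hurst, m))
  }
  ev[ev < 0] <- 0
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  w <- stats::fft(sqrt(ev / m) * z)
  # real and imaginary parts are two independent fGn samples; use the real part
  Re(w)[seq_len(n)]
}

fgn_embed_grow <- function(n, hurst, m_start) {
  m <- m_start
  repeat {
    m <- m * 2L
    k <- 0:(m %/% 2L)
    acf_k <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                      abs(k - 1)^(2 * hurst))
    row <- c(acf_k, rev(acf_k[2:(m %/% 2L)]))
    ev <- Re(stats::fft(row))
    if (min(ev) >= -1e-8 * max(ev)) {
      ev[ev < 0] <- 0
      z <- stats::rnorm(m) + 1i * stats::rnorm(m)
      w <- stats::fft(sqrt(ev / m) * z)
      return(Re(w)[seq_len(n)])
    }
    if (m > 2^26) stop("circulant embedding failed to become nonnegative")
  }
}

#' Theoretical fGn autocorrelation
#'
#' Closed-form lag-k autocorrelation of fractional Gaussian noise, used as
#' the independent oracle for the simulator.
#'
#' @param k integer lag(s).
#' @param hurst Hurst exponent in (0, 1).
#' @return numeric vector of autocorrelations.
#' @export
fgn_acf <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst))
}
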