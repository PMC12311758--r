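# shared fixtures, built in code at test time

# single-frequency wavelet bank at the 30-bank frequency nearest `freq`
bank_at <- function(fs, freq) {
  full <- make_bank(fs)
  f0 <- full$freqs[nearest_freq(full, freq)]
  make_bank(fs, n_freqs = 1L, f_range = c(f0, f0))
}

# envelope -> DFA exponent through the single-frequency wavelet path
pipeline_dfa <- function(rec, freq, ...) {
  bk <- bank_at(rec$fs, freq)
  dec <- nb_transform(rec, bk)
  dfa(Mod(dec$coeffs[1, 1, ]), rec$fs, freq = bk$freqs[1],
      valid = dec$valid[1, ], ...)
}

# direct two-state exponential-mixture envelope (no wavelet), for fast BiS
# property tests: unit-scale Rayleigh modulus switched between amplitudes
mixture_envelope <- function(n, amp_ratio, p_high = 0.5) {
  state <- stats::rbinom(n, 1, p_high)
  amp <- ifelse(state == 1, amp_ratio, 1)
  amp * sqrt(stats::rexp(n))
}

# random symmetric nonnegative weight matrix with zero diagonal
random_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# brute-force nodal metrics: explicit triple loops, the independent oracle
brute_nodal <- function(W) {
  n <- nrow(W)
  diag(W) <- 0
  strength <- numeric(n)
  clustering <- numeric(n)
  Wh <- W / max(W)
  for (i in seq_len(n)) {
    strength[i] <- sum(W[i, ])
    k <- sum(W[i, ] > 0)
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
        }
      }
    }
    clustering[i] <- if (k > 1) acc / (k * (k - 1)) else 0
  }
  ev <- eigen(W, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  list(strength = strength, clustering = clustering, eigencentrality = v / max(v))
}
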