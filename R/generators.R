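#' Specification of a synthetic narrowband oscillation
#'
#' Collects the ground-truth knobs of the single-channel signal generators:
#' the carrier frequency, the target envelope self-similarity (Hurst
#' exponent, which downstream DFA should recover), the imposed
#' amplitude-fluctuation coupling (which downstream fEI should recover as
#' excitation- or inhibition-dominance), and the two-state amplitude Markov
#' chain of the bistable generator (which downstream BiS should detect).
#'
#' @param center_freq carrier frequency in Hz.
#' @param duration length in seconds.
#' @param fs sampling rate in Hz; must exceed 4 x `center_freq`.
#' @param hurst target Hurst exponent of the amplitude envelope, in (0, 1).
#' @param ei_coupling in \[-1, 1\]: imposed coupling between window amplitude
#'   and window-normalized fluctuation. Positive values produce an
#'   excitation-dominated signal (fEI > 1), negative values an
#'   inhibition-dominated one (fEI < 1), zero a balanced one (fEI = 1).
#' @param bistable logical; use the two-state amplitude Markov chain.
#' @param switch_lh,switch_hl low-to-high / high-to-low switching rates of
#'   the amplitude chain, per second.
#' @param amp_ratio high-state / low-state mean amplitude ratio (> 1 when
#'   bistable).
#' @param noise_sd standard deviation of additive broadband measurement
#'   noise, in the amplitude units of the oscillation.
#' @param env_sigma log-envelope scale: the envelope is exp(env_sigma * z)
#'   with z standardized fGn, giving a smooth strictly positive envelope
#'   whose DFA exponent equals `hurst`.
#' @param seed integer seed; identical seeds give bit-identical signals.
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(center_freq = 8, duration = 300, fs = 512,
                        hurst = 0.75, ei_coupling = 0, bistable = FALSE,
                        switch_lh = 0.5, switch_hl = 0.5, amp_ratio = 4,
                        noise_sd = 0.05, env_sigma = 0.3, seed = 1L) {
  stopifnot(hurst > 0, hurst < 1, fs > 4 * center_freq,
            abs(ei_coupling) <= 1, duration > 0, noise_sd >= 0)
  if (bistable && amp_ratio <= 1) stop("amp_ratio must exceed 1 for a bistable signal")
  structure(
    list(center_freq = center_freq, duration = duration, fs = fs,
         hurst = hurst, ei_coupling = ei_coupling, bistable = bistable,
         switch_lh = switch_lh, switch_hl = switch_hl, amp_ratio = amp_ratio,
         noise_sd = noise_sd, env_sigma = env_sigma, seed = as.integer(seed)),
    class = "signal_spec")
}

# Smallest sensible DFA fit scale is 40 carrier cycles (see dfa()); a fit
# needs the largest window (duration/10) to exceed it.
min_lrtc_duration <- function(freq) 410 / freq

# centered moving average via cumulative sums; O(n), edges use the
# available (shorter) window
running_mean <- function(x, L) {
  n <- length(x)
  half <- L %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Envelope with target Hurst exponent and optional amplitude-fluctuation
# coupling. Positive `ei_coupling` damps the fast relative fluctuation where
# the slow amplitude level is high, so high-amplitude windows carry a SMALLER
# normalized detrended fluctuation (fEI > 1), and vice versa. The fGn is
# split at the fEI window scale into a slow level (which carries the
# long-range scaling the DFA stage reads) and a fast residual whose local
# variance is modulated by the level; the log-normal mean of the fast part
# is cancelled pointwise so the window mean amplitude tracks the slow level
# alone, not the modulated fluctuation variance.
make_lrtc_envelope <- function(n, fs, hurst, env_sigma, ei_coupling, freq) {
  z <- fgn(n, hurst)
  L <- max(3L, round(40 * fs / freq))          # one fEI window
  lev <- running_mean(z, L)
  r <- z - lev
  v_loc <- running_mean(r * r, L)
  g <- if (ei_coupling == 0) 1 else {
    u <- (lev - mean(lev)) / stats::sd(lev)
    exp(-ei_coupling * u)
  }
  # the v_loc term cancels the log-normal inflation of the window mean by
  # the locally varying fast-fluctuation variance: without it, windows with
  # larger residual variance have convexity-inflated mean amplitude, which
  # reads as a spurious amplitude-fluctuation coupling (fEI < 1) even at
  # ei_coupling = 0
  exp(env_sigma * (lev + g * r) - env_sigma^2 * g^2 * v_loc / 2)
}

# Carrier phase: integral of the center frequency plus small stationary
# (Ornstein-Uhlenbeck) jitter. A random-walk jitter would wander off the
# wavelet's center frequency and imprint spurious long-range correlations
# on the measured envelope; an OU jitter with a ~2-cycle correlation time
# keeps the line narrow and stationary.
carrier_phase <- function(n, fs, freq, jitter_sd = 0.05) {
  dt <- 1 / fs
  a <- exp(-dt * freq / 2)
  jit <- as.numeric(stats::filter(stats::rnorm(n, 0, jitter_sd * sqrt(1 - a^2)),
                                  a, method = "recursive"))
  2 * pi * freq * (seq_len(n) - 1L) / fs + jit
}

#' Synthetic oscillation with long-range temporal correlations
#'
#' Generates a single-channel narrowband oscillation whose amplitude
#' envelope is driven by fractional Gaussian noise of known Hurst exponent
#' (mapped through an exponential so it stays strictly positive and smooth).
#' The DFA exponent of the envelope approximates `spec$hurst`, making the
#' recording a calibration input for the DFA stage.
#'
#' @param spec a [signal_spec()] with `bistable = FALSE`.
#' @return an `eeg_recording` with one channel; the ground-truth envelope is
#'   attached as attribute `"envelope"`.
#' @export
gen_lrtc_oscillation <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  if (spec$bistable) stop("use gen_bistable_oscillation() for bistable specs")
  if (spec$duration < min_lrtc_duration(spec$center_freq)) {
    stop(sprintf(
      "duration %.1f s too short for DFA at %g Hz; need at least %.1f s",
      spec$duration, spec$center_freq, min_lrtc_duration(spec$center_freq)))
  }
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  env <- make_lrtc_envelope(n, spec$fs, spec$hurst, spec$env_sigma, 0,
                            spec$center_freq)
  ph <- carrier_phase(n, spec$fs, spec$center_freq)
  x <- env * cos(ph) + stats::rnorm(n, 0, spec$noise_sd)
  rec <- new_recording(matrix(x, nrow = 1L), spec$fs, labels = "sim")
  attr(rec, "envelope") <- env
  attr(rec, "spec") <- spec
  rec
}

#' Synthetic oscillation with imposed excitation-inhibition imbalance
#'
#' As [gen_lrtc_oscillation()], but the variance of the fast envelope
#' fluctuations is modulated by the slow amplitude level with strength and
#' sign given by `spec$ei_coupling`. A positive coupling yields relatively
#' quieter high-amplitude epochs, the signature of excitation dominance that
#' the fEI statistic reads as fEI > 1; a negative coupling yields fEI < 1;
#' zero coupling yields a balanced signal with fEI close to 1.
#'
#' @inheritParams gen_lrtc_oscillation
#' @return an `eeg_recording` with one channel (ground-truth envelope in
#'   attribute `"envelope"`).
#' @export
gen_ei_oscillation <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  if (spec$duration < min_lrtc_duration(spec$center_freq)) {
    stop(sprintf(
      "duration %.1f s too short; need at least %.1f s",
      spec$duration, min_lrtc_duration(spec$center_freq)))
  }
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  env <- make_lrtc_envelope(n, spec$fs, spec$hurst, spec$env_sigma,
                            spec$ei_coupling, spec$center_freq)
  ph <- carrier_phase(n, spec$fs, spec$center_freq)
  x <- env * cos(ph) + stats::rnorm(n, 0, spec$noise_sd)
  rec <- new_recording(matrix(x, nrow = 1L), spec$fs, labels = "sim")
  attr(rec, "envelope") <- env
  attr(rec, "spec") <- spec
  rec
}

#' Synthetic bistable oscillation
#'
#' The envelope mean switches between a low and a high state according to a
#' two-state continuous-time Markov chain (rates `switch_lh`, `switch_hl`);
#' within each state the complex amplitude is an Ornstein-Uhlenbeck process,
#' so within-state power is approximately exponential and the overall power
#' distribution is a two-component exponential mixture with weights equal to
#' the stationary state occupancies and rate ratio `amp_ratio^-2`. This is
#' the calibration input for the bistability index.
#'
#' @param spec a [signal_spec()] with `bistable = TRUE`.
#' @return an `eeg_recording` with one channel; attributes `"state"` (1 =
#'   low, 2 = high per sample) and `"envelope"` carry the ground truth.
#' @export
gen_bistable_oscillation <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!spec$bistable) stop("spec$bistable must be TRUE")
  f <- spec$center_freq
  if (1 / spec$switch_lh < 2 / f || 1 / spec$switch_hl < 2 / f) {
    stop("switch rates too fast: mean dwell times must exceed 2 oscillation cycles")
  }
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  dt <- 1 / spec$fs
  # dwell-time construction of the two-state chain
  state <- integer(n)
  t_pos <- 1L
  s <- if (stats::runif(1) < spec$switch_hl / (spec$switch_lh + spec$switch_hl)) 1L else 2L
  while (t_pos <= n) {
    rate <- if (s == 1L) spec$switch_lh else spec$switch_hl
    dwell <- max(1L, round(stats::rexp(1, rate) / dt))
    idx <- t_pos:min(n, t_pos + dwell - 1L)
    state[idx] <- s
    t_pos <- t_pos + dwell
    s <- 3L - s
  }
  amp <- c(1, spec$amp_ratio)[state]
  # complex OU base: Rayleigh modulus, exponential power within state
  tau <- 2 / f
  a <- exp(-dt / tau)
  b <- sqrt((1 - a^2) / 2)
  re <- as.numeric(stats::filter(b * stats::rnorm(n), a, method = "recursive"))
  im <- as.numeric(stats::filter(b * stats::rnorm(n), a, method = "recursive"))
  ph <- 2 * pi * f * (seq_len(n) - 1L) / spec$fs
  x <- amp * (re * cos(ph) - im * sin(ph)) + stats::rnorm(n, 0, spec$noise_sd)
  rec <- new_recording(matrix(x, nrow = 1L), spec$fs, labels = "sim")
  attr(rec, "state") <- state
  attr(rec, "envelope") <- amp * sqrt(re^2 + im^2)
  attr(rec, "spec") <- spec
  rec
}

#' Stationary occupancy of the two-state amplitude chain
#'
#' @param switch_lh,switch_hl switching rates per second (low-to-high and
#'   high-to-low).
#' @return named vector with the stationary probabilities of the low and
#'   high states: `low = switch_hl / (switch_lh + switch_hl)`.
#' @export
bistable_occupancy <- function(switch_lh, switch_hl) {
  c(low = switch_hl / (switch_lh + switch_hl),
    high = switch_lh / (switch_lh + switch_hl))
}

#' Pair of phase-coupled oscillations
#'
#' Each channel is a unit-variance mixture of a common oscillation (weight
#' `coupling`) and a private, independent oscillation (weight
#' `sqrt(1 - coupling^2)`); all three carriers have independent Wiener
#' phase noise, and channel b sees the common component delayed by the
#' fixed phase offset `phase_lag`. `coupling = 0` gives independent
#' channels (wPLI near 0); `coupling = 1` with a nonzero, non-pi lag gives
#' perfectly lagged channels (wPLI = 1); `coupling = 1` with zero lag
#' exercises the zero-denominator (volume-conduction) path of the wPLI
#' estimator.
#'
#' @param freq carrier frequency, Hz.
#' @param coupling shared-phase weight in \[0, 1\].
#' @param phase_lag fixed phase offset in (-pi, pi\].
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param phase_diffusion Wiener phase-noise diffusion coefficient in
#'   rad^2 per second. The default gives a ~0.25 s phase-coherence time,
#'   typical of cortical narrowband oscillations; much smaller values make
#'   "independent" channels phase-coherent over seconds, which inflates
#'   the small-sample floor of synchrony estimators.
#' @return an `eeg_recording` with two channels.
#' @export
gen_coupled_pair <- function(freq, coupling, phase_lag, duration, fs,
                             seed = 1L, phase_diffusion = 8) {
  stopifnot(coupling >= 0, coupling <= 1, phase_lag > -pi, phase_lag <= pi,
            fs > 4 * freq)
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  sdw <- sqrt(phase_diffusion / fs)
  base <- 2 * pi * freq * (seq_len(n) - 1L) / fs
  ph0 <- base + cumsum(stats::rnorm(n, 0, sdw))
  ph1 <- base + cumsum(stats::rnorm(n, 0, sdw))
  ph2 <- base + cumsum(stats::rnorm(n, 0, sdw))
  mix <- sqrt(1 - coupling^2)
  xa <- coupling * cos(ph0) + mix * cos(ph1)
  xb <- coupling * cos(ph0 - phase_lag) + mix * cos(ph2)
  new_recording(rbind(xa, xb), fs, labels = c("a", "b"))
}
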