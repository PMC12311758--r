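#' Canonical EEG frequency bands
#'
#' Aggregation grid for all cohort statistics: delta 2-4, theta 5-7,
#' alpha 8-13, beta 15-30, gamma 30-70 Hz. Wavelet frequencies falling in
#' the gaps between bands (4-5, 7-8, 13-15 Hz) belong to no band.
#'
#' @return tibble with columns `band` (factor), `lo`, `hi` in Hz.
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    lo = c(2, 5, 8, 15, 30),
    hi = c(4, 7, 13, 30, 70))
}

#' Assign frequencies to canonical bands
#'
#' @param freqs numeric frequencies in Hz.
#' @param bands band table as from [canonical_bands()].
#' @return factor of band labels, NA for frequencies in no band. Boundary
#'   frequencies go to the lower band (so 30 Hz is beta, not gamma).
#' @export
band_of <- function(freqs, bands = canonical_bands()) {
  lab <- rep(NA_character_, length(freqs))
  for (i in rev(seq_len(nrow(bands)))) {   # reverse order: ties to lower band
    hit <- freqs >= bands$lo[i] & freqs <= bands$hi[i]
    lab[hit] <- as.character(bands$band[i])
  }
  factor(lab, levels = levels(bands$band))
}

#' Per-channel, per-frequency criticality profile
#'
#' Applies the three criticality assessments to every channel x wavelet
#' frequency series of a decomposition: the DFA scaling exponent, the fEI
#' ratio (computed only where the DFA exponent exceeds 0.6), and the
#' bistability index. Missing values propagate; nothing is imputed.
#'
#' @param decomp an [nb_transform()] decomposition.
#' @param min_valid_s minimum seconds of valid signal required per channel x
#'   frequency (default 60); series with less are returned all-missing.
#' @param fei_min_windows minimum usable fEI windows (default 20).
#' @param dfa_min_cycles smallest DFA window in carrier cycles (default 40).
#' @return tibble of class `criticality_profile` with columns `channel`,
#'   `freq_hz`, `band`, `dfa`, `dfa_r2`, `fei`, `fei_valid`, `bis`, `dbic`,
#'   `gamma1`, `gamma2`, `delta1`.
#' @export
criticality_profile <- function(decomp, min_valid_s = 60,
                                fei_min_windows = 20L, dfa_min_cycles = 40) {
  stopifnot(inherits(decomp, "nb_decomposition"))
  n_ch <- dim(decomp$coeffs)[1]
  n_f <- dim(decomp$coeffs)[2]
  bands <- band_of(decomp$freqs)
  rows <- vector("list", n_ch * n_f)
  k <- 0L
  for (ch in seq_len(n_ch)) {
    for (fi in seq_len(n_f)) {
      k <- k + 1L
      f0 <- decomp$freqs[fi]
      vmask <- decomp$valid[fi, ]
      env <- Mod(decomp$coeffs[ch, fi, ])
      row <- tibble::tibble(
        channel = decomp$labels[ch], freq_hz = f0,
        band = bands[fi], dfa = NA_real_, dfa_r2 = NA_real_,
        fei = NA_real_, fei_valid = FALSE, bis = NA_real_,
        dbic = NA_real_, gamma1 = NA_real_, gamma2 = NA_real_,
        delta1 = NA_real_)
      if (sum(vmask) / decomp$fs >= min_valid_s) {
        d <- tryCatch(dfa(env, decomp$fs, freq = f0, valid = vmask,
                          min_cycles = dfa_min_cycles),
                      error = function(e) NULL)
        if (!is.null(d) && !d$degenerate) {
          row$dfa <- d$exponent; row$dfa_r2 <- d$fit_r2
          fe <- tryCatch(fei(env, f0, decomp$fs, d$exponent, valid = vmask,
                             min_windows = fei_min_windows),
                         error = function(e) NULL)
          if (!is.null(fe)) { row$fei <- fe$fei; row$fei_valid <- fe$valid }
        }
        b <- tryCatch(fit_bis(env, decomp$fs, f0, valid = vmask),
                      error = function(e) NULL)
        if (!is.null(b)) {
          row$bis <- b$bis; row$dbic <- b$dbic
          row$gamma1 <- b$gamma1; row$gamma2 <- b$gamma2; row$delta1 <- b$delta1
        }
      }
      rows[[k]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("criticality_profile", class(out))
  out
}

#' Band-averaged criticality metrics
#'
#' Averages each metric over channels, then over the wavelet frequencies
#' inside each canonical band. fEI is averaged over valid entries only and
#' the valid fraction is reported; a band with no valid fEI entry yields NA.
#'
#' @param profile a [criticality_profile()] tibble.
#' @param bands band table as from [canonical_bands()].
#' @return tibble with one row per band x metric: `band`, `metric`,
#'   `value`, `valid_fraction`.
#' @export
band_average <- function(profile, bands = canonical_bands()) {
  long <- tidyr::pivot_longer(
    dplyr::select(profile, "channel", "freq_hz", "band", "dfa", "fei", "bis"),
    cols = c("dfa", "fei", "bis"), names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$band))
  # channel average per frequency first, then average over in-band frequencies
  per_freq <- dplyr::summarise(
    dplyr::group_by(long, .data$band, .data$metric, .data$freq_hz),
    value = mean(.data$value, na.rm = TRUE),
    valid_fraction = mean(!is.na(.data$value)), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_freq, .data$band, .data$metric),
    value = mean(.data$value, na.rm = TRUE),
    valid_fraction = mean(.data$valid_fraction), .groups = "drop")
  out$value[is.nan(out$value)] <- NA_real_
  out
}

#' Plot a criticality profile
#'
#' Channel-averaged spectral profiles of the DFA exponent, fEI and BiS, the
#' standard at-a-glance view of a criticality assessment.
#'
#' @param object a [criticality_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.criticality_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "channel", "freq_hz", "dfa", "fei", "bis"),
    cols = c("dfa", "fei", "bis"), names_to = "metric", values_to = "value")
  avg <- dplyr::summarise(
    dplyr::group_by(long, .data$freq_hz, .data$metric),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$freq_hz, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = "Channel-averaged criticality profile")
}
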