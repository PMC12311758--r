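#' Study group labels
#'
#' Group factor levels in order of increasing latent disease severity:
#' healthy controls, non-converter, late-converter and early-converter
#' patients.
#' @return character vector of the four labels.
#' @export
cohort_groups <- function() c("HC", "ncRBD", "lRBD", "eRBD")

band_carriers <- function() {
  tibble::tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
                 freq = c(2.5, 6, 10.5, 20, 45),
                 weight = c(1.0, 0.8, 0.9, 0.5, 0.3))
}

#' Specification of a synthetic cohort
#'
#' Defines the study design the cohort generator emulates: group sizes
#' (defaults mirror a 46/41/10/8 HC/ncRBD/lRBD/eRBD design), a latent
#' severity axis ordered HC < ncRBD < lRBD < eRBD, linear per-band mappings
#' from severity to the signal ground-truth parameters (envelope Hurst
#' exponent, amplitude-fluctuation coupling, bistable amplitude ratio), a
#' negative linear dependence of striatal binding ratios on severity, and
#' group-dependent clinical covariates. Follow-up visits are generated for
#' the converter groups only (severity incremented by one at follow-up),
#' mirroring a partial-follow-up design; this is configurable.
#'
#' @param n_per_group named integer vector of subjects per group; names
#'   must be exactly the four labels of [cohort_groups()].
#' @param hurst_base,hurst_slope named per-band baseline and per-severity
#'   slope of the envelope Hurst exponent.
#' @param ei_base,ei_slope per-band baseline / slope of the
#'   amplitude-fluctuation coupling passed to the signal generator.
#' @param amp_slope per-band slope of the bistable amplitude ratio
#'   (amp_ratio = 1 + amp_slope * severity; 1 means no bistability).
#' @param sbr_slope decrease of the putamen binding ratio per severity unit.
#' @param severity_sd subject-level SD of latent severity around the group
#'   mean (HC 0, ncRBD 1, lRBD 2, eRBD 3).
#' @param followup_groups groups receiving a follow-up visit.
#' @param n_channels,duration,fs recording geometry for [gen_cohort()].
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 46, ncRBD = 41, lRBD = 10, eRBD = 8),
                        hurst_base = c(delta = 0.68, theta = 0.70, alpha = 0.72,
                                       beta = 0.68, gamma = 0.65),
                        hurst_slope = c(delta = 0.03, theta = 0.03, alpha = 0,
                                        beta = 0, gamma = 0),
                        ei_base = c(delta = -0.1, theta = -0.1, alpha = -0.1,
                                    beta = -0.1, gamma = -0.1),
                        ei_slope = c(delta = 0, theta = 0.2, alpha = 0,
                                     beta = 0, gamma = 0),
                        amp_slope = c(delta = 0.4, theta = 0.1, alpha = 0,
                                      beta = 0, gamma = 0),
                        sbr_slope = 0.25, severity_sd = 0.3,
                        followup_groups = c("lRBD", "eRBD"),
                        n_channels = 64L, duration = 580, fs = 512,
                        seed = 1L) {
  unknown <- setdiff(names(n_per_group), cohort_groups())
  if (length(unknown) || is.null(names(n_per_group))) {
    stop("unknown group label(s): ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         "; accepted labels are: ", paste(cohort_groups(), collapse = ", "))
  }
  structure(list(n_per_group = n_per_group, hurst_base = hurst_base,
                 hurst_slope = hurst_slope, ei_base = ei_base,
                 ei_slope = ei_slope, amp_slope = amp_slope,
                 sbr_slope = sbr_slope, severity_sd = severity_sd,
                 followup_groups = followup_groups,
                 n_channels = as.integer(n_channels), duration = duration,
                 fs = fs, seed = as.integer(seed)),
            class = "cohort_spec")
}

# subject/visit skeleton with latent severity and covariates
cohort_skeleton <- function(spec) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  sev_mean <- match(groups, cohort_groups()) - 1
  severity <- pmax(0, sev_mean + stats::rnorm(n, 0, spec$severity_sd))
  sex_p <- ifelse(groups == "HC", 0.48, 0.15)   # patient groups are male-dominated
  base <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = factor(groups, levels = cohort_groups()),
    visit = "baseline",
    severity = severity,
    age = round(stats::rnorm(n, 70, 7), 1),
    sex = factor(ifelse(stats::runif(n) < sex_p, "F", "M"), levels = c("F", "M")),
    education = ifelse(groups == "HC", NA_real_,
                       pmax(3, round(stats::rnorm(n, 10, 3.5)))),
    mmse = pmin(30, pmax(0, round(28.5 - 0.6 * severity + stats::rnorm(n, 0, 1.5)))),
    updrs3 = ifelse(groups == "HC", 0,
                    pmax(0, round(1.5 * severity - 1 + stats::rnorm(n, 0, 2)))),
    sbr_putamen = ifelse(groups == "HC", NA_real_,
                         2.2 - spec$sbr_slope * severity + stats::rnorm(n, 0, 0.25)),
    sbr_caudate = ifelse(groups == "HC", NA_real_,
                         2.8 - 0.8 * spec$sbr_slope * severity + stats::rnorm(n, 0, 0.25)))
  fu <- dplyr::filter(base, .data$group %in% spec$followup_groups)
  if (nrow(fu)) {
    fu$visit <- "followup"
    fu$severity <- fu$severity + 1
    fu$age <- fu$age + 2
    fu$mmse <- pmin(30, pmax(0, fu$mmse - round(0.6 + stats::rnorm(nrow(fu), 0, 1))))
    fu$updrs3 <- fu$updrs3 + pmax(0, round(1.5 + stats::rnorm(nrow(fu), 0, 1.5)))
    fu$sbr_putamen <- fu$sbr_putamen - spec$sbr_slope + stats::rnorm(nrow(fu), 0, 0.1)
    fu$sbr_caudate <- fu$sbr_caudate - 0.8 * spec$sbr_slope + stats::rnorm(nrow(fu), 0, 0.1)
  }
  dplyr::bind_rows(base, fu)
}

#' Table-level synthetic cohort (band metrics simulated directly)
#'
#' Fast path for statistical calibration: simulates the band-averaged EEG
#' metrics of each subject/visit directly around their severity-determined
#' ground-truth values instead of synthesizing and re-analyzing signals.
#' Effect sizes are expressed per severity unit in pooled-SD units
#' (`effect_d`, default 0.6): DFA and BiS effects load on the delta and
#' theta bands, the fEI effect on theta, matching the direction of the
#' injected signal-level effects. `effect_d = 0` yields a null cohort.
#'
#' @param spec a [cohort_spec()].
#' @param effect_d injected standardized effect per severity unit.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return tibble (class `cohort_table`) with one row per subject x visit:
#'   covariates plus `dfa_<band>`, `fei_<band>`, `bis_<band>` columns.
#' @export
gen_cohort_table <- function(spec, effect_d = 0.6, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  tab <- cohort_skeleton(spec)
  n <- nrow(tab)
  sds <- c(dfa = 0.05, fei = 0.08, bis = 0.5)
  base <- list(
    dfa = c(delta = 0.62, theta = 0.65, alpha = 0.72, beta = 0.65, gamma = 0.60),
    fei = c(delta = 0.95, theta = 0.95, alpha = 0.97, beta = 0.96, gamma = 0.95),
    bis = c(delta = 0.8, theta = 0.7, alpha = 1.2, beta = 0.6, gamma = 0.4))
  loads <- list(
    dfa = c(delta = 1, theta = 1, alpha = 0, beta = 0, gamma = 0),
    fei = c(delta = 0, theta = 1, alpha = 0, beta = 0, gamma = 0),
    bis = c(delta = 1, theta = 1, alpha = 0, beta = 0, gamma = 0))
  for (m in names(base)) {
    for (b in names(base[[m]])) {
      mu <- base[[m]][[b]] + effect_d * sds[[m]] * loads[[m]][[b]] * tab$severity
      tab[[paste(m, b, sep = "_")]] <- mu + stats::rnorm(n, 0, sds[[m]])
    }
  }
  class(tab) <- c("cohort_table", class(tab))
  tab
}

# one broadband channel: five narrowband components + pink-ish background
gen_subject_channel <- function(n, fs, params, noise_sd = 0.2) {
  x <- numeric(n)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    env <- make_lrtc_envelope(n, fs, p$hurst, 0.3, p$ei, p$freq)
    if (p$amp_ratio > 1) {
      rate <- 0.5                              # balanced 2 s dwells
      state <- integer(n); t_pos <- 1L
      s <- if (stats::runif(1) < 0.5) 1L else 2L
      while (t_pos <= n) {
        dwell <- max(1L, round(stats::rexp(1, rate) * fs))
        state[t_pos:min(n, t_pos + dwell - 1L)] <- s
        t_pos <- t_pos + dwell; s <- 3L - s
      }
      env <- env * c(1, p$amp_ratio)[state]
    }
    ph <- carrier_phase(n, fs, p$freq)
    x <- x + p$weight * env * cos(ph)
  }
  # mildly low-pass-filtered background noise
  bg <- stats::rnorm(n)
  bg <- as.numeric(stats::filter(bg, 0.7, method = "recursive"))
  x + noise_sd * bg / stats::sd(bg)
}

#' Full synthetic cohort: recordings plus metadata table
#'
#' For each subject/visit, draws a latent severity from the group, maps it
#' through the per-band linear parameter model of the [cohort_spec()], and
#' synthesizes a multichannel recording as a sum of five narrowband
#' oscillations (one per canonical band, with the subject's ground-truth
#' Hurst exponent, amplitude-fluctuation coupling and bistable amplitude
#' ratio) over a broadband noise floor; channels are independent
#' realizations of the same subject parameters. Covariates (age, sex,
#' MMSE, MDS-UPDRS-III, binding ratios) are drawn with group-dependent
#' means as in [gen_cohort_table()].
#'
#' @param spec a [cohort_spec()]; at least 2 subjects per listed group are
#'   required for any downstream group statistic.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `recordings` (named list of `eeg_recording`, names
#'   `<subject_id>_<visit>`), `table` (tibble of subject/visit covariates),
#'   and `ground_truth` (tibble of per subject/visit/band true parameters).
#' @export
gen_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n_per_group < 2)) {
    stop("need at least 2 subjects per listed group")
  }
  set.seed(seed)
  tab <- cohort_skeleton(spec)
  carriers <- band_carriers()
  n <- round(spec$duration * spec$fs)
  recordings <- list()
  gt <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sev <- tab$severity[i]
    params <- tibble::tibble(
      band = carriers$band, freq = carriers$freq, weight = carriers$weight,
      hurst = pmin(0.95, pmax(0.55,
        spec$hurst_base[carriers$band] + spec$hurst_slope[carriers$band] * sev)),
      ei = pmin(1, pmax(-1,
        spec$ei_base[carriers$band] + spec$ei_slope[carriers$band] * sev)),
      amp_ratio = 1 + pmax(0, spec$amp_slope[carriers$band] * sev))
    dat <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      dat[ch, ] <- gen_subject_channel(n, spec$fs, params)
    }
    labs <- if (spec$n_channels <= 64L) {
      montage_1010()$label[seq_len(spec$n_channels)]
    } else paste0("ch", seq_len(spec$n_channels))
    key <- paste(tab$subject_id[i], tab$visit[i], sep = "_")
    recordings[[key]] <- new_recording(dat, spec$fs, labels = labs)
    gt[[i]] <- dplyr::mutate(params, subject_id = tab$subject_id[i],
                             visit = tab$visit[i], severity = sev, .before = 1)
  }
  list(recordings = recordings, table = tab, ground_truth = dplyr::bind_rows(gt))
}

#' Write a cohort to disk
#'
#' Recordings go to `<dir>/<subject>_<visit>.edf`, the cohort table to
#' `<dir>/cohort.csv`, and the ground-truth parameters to a JSON sidecar
#' `<dir>/ground_truth.json`.
#'
#' @param cohort result of [gen_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$recordings)) {
    write_edf(cohort$recordings[[key]], file.path(dir, paste0(key, ".edf")))
  }
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
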