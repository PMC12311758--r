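#' Kruskal-Wallis screen of a demographic column
#'
#' Nonparametric across-group comparison of a demographic or clinical
#' column; `sex` (a factor) is tested with a chi-square test on counts.
#'
#' @param table a cohort table (one row per subject x visit); only baseline
#'   rows are used.
#' @param column column name to test.
#' @param alpha nominal level (default 0.05).
#' @return one-row `stat_result` tibble: `term`, `statistic`, `p_raw`,
#'   `alpha_corrected`, `n_tests`, `n_used`.
#' @export
demographics_test <- function(table, column, alpha = 0.05) {
  tab <- table[table$visit == "baseline", , drop = FALSE]
  x <- tab[[column]]
  keep <- !is.na(x)
  x <- x[keep]
  g <- droplevels(factor(tab$group[keep]))
  if (nlevels(g) < 2L) stop("need at least 2 groups with data")
  if (min(table(g)) < 2L) stop("need at least 2 observations per group")
  if (is.factor(x) || is.character(x)) {
    # small expected counts are routine with imbalanced groups
    ht <- suppressWarnings(stats::chisq.test(table(x, g)))
  } else {
    if (stats::sd(x) == 0) {
      return(stat_result(column, NA_real_, NA_real_, alpha, 1L, sum(keep),
                         flag = "constant_column"))
    }
    ht <- stats::kruskal.test(x, g)
  }
  stat_result(column, unname(ht$statistic), ht$p.value, alpha, 1L, sum(keep))
}

stat_result <- function(term, statistic, p_raw, alpha, n_tests, n_used,
                        coefficient = NA_real_, cohens_d = NA_real_,
                        band = NA_character_, metric = NA_character_,
                        flag = NA_character_) {
  out <- tibble::tibble(term = term, coefficient = coefficient,
                        statistic = statistic, p_raw = p_raw,
                        alpha_corrected = alpha / n_tests, n_tests = n_tests,
                        cohens_d = cohens_d, band = band, metric = metric,
                        n_used = n_used, flag = flag)
  class(out) <- c("stat_result", class(out))
  out
}

#' Cohen's d between two groups
#'
#' Standardized mean difference with pooled SD, computed on raw group
#' values. Classified as small / medium / large at 0.2 / 0.5 / 0.8.
#'
#' @param x,y numeric vectors.
#' @return named list with `d` and `label`.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  lab <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "medium"
         else if (abs(d) >= 0.2) "small" else "negligible"
  list(d = d, label = lab)
}

#' Covariate-adjusted two-group contrast of one band metric
#'
#' Gaussian linear model `metric ~ group + age + sex` on baseline rows of
#' two groups, reporting the group coefficient, its p-value, and Cohen's d
#' on the raw (unadjusted) group values. Bonferroni correction is over
#' `n_tests` comparisons (default 5, the canonical bands).
#'
#' @param table cohort table.
#' @param metric_col metric column name, e.g. `"fei_theta"`.
#' @param groups character vector of exactly two group labels; the second
#'   is the exposure (its coefficient is reported relative to the first).
#' @param covariates adjustment columns (default age and sex).
#' @param n_tests Bonferroni divisor (default 5 bands).
#' @param alpha nominal level.
#' @param visit visit to analyze (default baseline).
#' @return one-row `stat_result` tibble.
#' @export
group_contrast <- function(table, metric_col, groups = c("HC", "ncRBD"),
                           covariates = c("age", "sex"), n_tests = 5L,
                           alpha = 0.05, visit = "baseline") {
  stopifnot(length(groups) == 2L)
  tab <- table[table$visit == visit & table$group %in% groups, , drop = FALSE]
  tab <- tab[stats::complete.cases(tab[, c(metric_col, covariates)]), , drop = FALSE]
  if (!all(groups %in% tab$group)) stop("both groups must be present with data")
  tab$group <- factor(as.character(tab$group), levels = groups)
  fml <- stats::reformulate(c("group", covariates), response = metric_col)
  fit <- stats::lm(fml, data = tab)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  row <- paste0("group", groups[2])
  d <- cohens_d(tab[[metric_col]][tab$group == groups[2]],
                tab[[metric_col]][tab$group == groups[1]])
  parts <- strsplit(metric_col, "_")[[1]]
  stat_result(row, sm[row, "t value"], sm[row, "Pr(>|t|)"], alpha, n_tests,
              nrow(tab), coefficient = sm[row, "Estimate"], cohens_d = d$d,
              band = parts[length(parts)],
              metric = paste(parts[-length(parts)], collapse = "_"))
}

#' Baseline-versus-follow-up contrast of one band metric
#'
#' Linear model `metric ~ visit + age + sex` restricted to subjects with
#' both visits; the visit coefficient estimates the longitudinal change.
#' Bonferroni correction defaults to the 5 canonical bands (corrected alpha
#' 0.01 at the nominal 0.05).
#'
#' @inheritParams group_contrast
#' @return one-row `stat_result` tibble.
#' @export
longitudinal_contrast <- function(table, metric_col, covariates = c("age", "sex"),
                                  n_tests = 5L, alpha = 0.05) {
  paired <- names(which(table(table$subject_id) == 2L))
  tab <- table[table$subject_id %in% paired, , drop = FALSE]
  tab <- tab[stats::complete.cases(tab[, c(metric_col, covariates)]), , drop = FALSE]
  if (nrow(tab) == 0L || length(unique(tab$visit)) < 2L) {
    stop("no subjects with both visits")
  }
  tab$visit <- factor(tab$visit, levels = c("baseline", "followup"))
  fml <- stats::reformulate(c("visit", covariates), response = metric_col)
  fit <- stats::lm(fml, data = tab)
  sm <- summary(fit)$coefficients
  row <- "visitfollowup"
  parts <- strsplit(metric_col, "_")[[1]]
  stat_result(row, sm[row, "t value"], sm[row, "Pr(>|t|)"], alpha, n_tests,
              nrow(tab), coefficient = sm[row, "Estimate"],
              band = parts[length(parts)],
              metric = paste(parts[-length(parts)], collapse = "_"))
}

#' Linear mixed model with a subject random intercept
#'
#' REML fit of `response ~ predictor + covariates + (1 | subject_id)` over
#' all visits, as used for binding-ratio, clinical-score and
#' synchrony-coupling analyses. The predictor coefficient is reported with
#' a Wald p-value. A singular random-effects fit falls back to the
#' fixed-effects linear model with a flag.
#'
#' @param table cohort table (baseline and follow-up rows).
#' @param response response column name.
#' @param predictor predictor column name whose coefficient is reported.
#' @param covariates additional fixed effects (default age and sex).
#' @param n_tests Bonferroni divisor (default 5 bands).
#' @param alpha nominal level.
#' @return one-row `stat_result` tibble.
#' @export
mixed_model <- function(table, response, predictor,
                        covariates = c("age", "sex"), n_tests = 5L,
                        alpha = 0.05) {
  cols <- c(response, predictor, covariates, "subject_id")
  tab <- table[stats::complete.cases(table[, cols]), , drop = FALSE]
  if (length(unique(tab$subject_id)) < 10L) stop("need at least 10 subjects")
  fml <- stats::as.formula(paste(
    response, "~", paste(c(predictor, covariates), collapse = " + "),
    "+ (1 | subject_id)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(fml, data = tab, REML = TRUE))),
    error = function(e) NULL)
  flag <- NA_character_
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    flag <- "singular_random_effect_fixed_effects_fallback"
    fml2 <- stats::reformulate(c(predictor, covariates), response = response)
    lmfit <- stats::lm(fml2, data = tab)
    sm <- summary(lmfit)$coefficients
    est <- sm[predictor, "Estimate"]; tv <- sm[predictor, "t value"]
    p <- sm[predictor, "Pr(>|t|)"]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[predictor, "Estimate"]; tv <- sm[predictor, "t value"]
    p <- 2 * stats::pnorm(-abs(tv))           # Wald
  }
  stat_result(predictor, tv, p, alpha, n_tests, nrow(tab), coefficient = est,
              flag = flag)
}

#' Rank correlation between two cohort columns
#'
#' @param table cohort table.
#' @param x,y column names.
#' @param method `"spearman"` or `"kendall"`.
#' @return one-row `stat_result` tibble with the rank correlation as
#'   `coefficient`.
#' @export
correlation_summary <- function(table, x, y, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  xv <- table[[x]]; yv <- table[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  if (sum(keep) < 5L) stop("need at least 5 paired observations")
  if (stats::sd(xv[keep]) == 0 || stats::sd(yv[keep]) == 0) {
    return(stat_result(paste(x, y, sep = "~"), NA_real_, NA_real_, 0.05, 1L,
                       sum(keep), flag = "constant_input"))
  }
  ct <- suppressWarnings(stats::cor.test(xv[keep], yv[keep], method = method))
  stat_result(paste(x, y, sep = "~"), unname(ct$statistic), ct$p.value, 0.05,
              1L, sum(keep), coefficient = unname(ct$estimate))
}

#' Baseline contrast battery over bands
#'
#' Runs [group_contrast()] for one metric across all five canonical bands
#' with Bonferroni correction over the bands, the analysis family used for
#' the patients-versus-controls comparison.
#'
#' @inheritParams group_contrast
#' @param metric metric prefix (`"dfa"`, `"fei"` or `"bis"`).
#' @return `stat_result` tibble with one row per band.
#' @export
baseline_battery <- function(table, metric, groups = c("HC", "ncRBD"),
                             covariates = c("age", "sex"), alpha = 0.05) {
  bands <- as.character(canonical_bands()$band)
  dplyr::bind_rows(lapply(bands, function(b) {
    group_contrast(table, paste(metric, b, sep = "_"), groups, covariates,
                   n_tests = length(bands), alpha = alpha)
  }))
}
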