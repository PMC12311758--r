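stats_spec <- cohort_spec(n_per_group = c(HC = 46, ncRBD = 41, lRBD = 10,
                                          eRBD = 8), seed = 123)

test_that("demographic screens behave across shifted and null groups", {
  tab <- gen_cohort_table(stats_spec)
  r_age <- demographics_test(tab, "age")
  expect_true(r_age$p_raw > 0 && r_age$p_raw <= 1)
  # groups shifted by 3 SD: decisive rejection
  tab2 <- tab
  tab2$age <- tab2$age + 21 * (as.integer(tab2$group) - 1)
  expect_lt(demographics_test(tab2, "age")$p_raw, 0.001)
  r_sex <- demographics_test(tab, "sex")
  expect_false(is.na(r_sex$p_raw))
  tab3 <- tab; tab3$age <- 70
  expect_equal(demographics_test(tab3, "age")$flag, "constant_column")
  tab4 <- tab[tab$group == "HC", ]
  expect_error(demographics_test(tab4, "age"), "2 groups")
})

test_that("Cohen's d has the printed thresholds and a zero at equality", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(rnorm(50) + 100, rnorm(50))$label, "large")
  expect_equal(cohens_d(1:4, 1:4)$label, "negligible")
})

test_that("group contrasts recover an injected shift of known size", {
  tab <- gen_cohort_table(stats_spec)          # d = 0.6 per severity unit
  res <- group_contrast(tab, "dfa_delta", c("HC", "ncRBD"))
  expect_lt(res$p_raw, 0.05)
  expect_gt(res$coefficient, 0)
  # ncRBD sits ~1 severity unit above HC: d-hat within a wide sampling CI
  expect_lt(abs(res$cohens_d - 0.6), 0.5)
  expect_equal(res$alpha_corrected, 0.01)
  expect_equal(res$band, "delta"); expect_equal(res$metric, "dfa")
  # equal groups: d near 0, coefficient near 0
  null_tab <- gen_cohort_table(stats_spec, effect_d = 0)
  res0 <- group_contrast(null_tab, "dfa_delta", c("HC", "ncRBD"))
  expect_lt(abs(res0$cohens_d), 0.45)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  tab <- gen_cohort_table(stats_spec)
  tab$age2 <- 2 * tab$age
  expect_error(group_contrast(tab, "dfa_delta", c("HC", "ncRBD"),
                              covariates = c("age", "age2")), "collinear")
})

test_that("longitudinal contrasts detect decline and honor Bonferroni", {
  tab <- gen_cohort_table(stats_spec)
  res <- longitudinal_contrast(tab, "bis_delta")
  expect_equal(res$alpha_corrected, 0.01)      # alpha 0.05 over 5 bands
  # identical visits: coefficient exactly 0
  tab2 <- tab[tab$visit == "baseline" & table(tab$subject_id)[tab$subject_id] == 2, ]
  tab2b <- tab2; tab2b$visit <- "followup"
  res0 <- longitudinal_contrast(rbind(tab2, tab2b), "bis_delta")
  expect_equal(res0$coefficient, 0, tolerance = 1e-10)
  hc <- tab[tab$group == "HC", ]
  expect_error(longitudinal_contrast(hc, "bis_delta"), "both visits")
})

test_that("the mixed model recovers the injected metric-SBR association", {
  tab <- gen_cohort_table(stats_spec)
  res <- mixed_model(tab, response = "sbr_putamen", predictor = "fei_theta")
  expect_lt(res$coefficient, 0)                # higher fEI, lower binding
  expect_lt(res$p_raw, 0.05)
  expect_error(mixed_model(tab[1:8, ], "sbr_putamen", "fei_theta"), "10 subjects")
})

test_that("duplicated-visit rows degrade gracefully to the fixed-effects fit", {
  tab <- gen_cohort_table(stats_spec)
  base <- tab[tab$visit == "baseline" & tab$group != "HC", ]
  dup <- base; dup$visit <- "followup"
  both <- rbind(base, dup)
  res <- mixed_model(both, "sbr_putamen", "fei_theta")
  ref <- stats::lm(sbr_putamen ~ fei_theta + age + sex, data = base)
  expect_equal(res$coefficient, unname(stats::coef(ref)["fei_theta"]),
               tolerance = 1e-6)
})

test_that("rank correlations report coefficient, sign and degenerate inputs", {
  tab <- tibble::tibble(x = 1:20, y = (1:20)^3, z = -(1:20) + rnorm(20, 0, 2),
                        c = rep(1, 20))
  expect_equal(correlation_summary(tab, "x", "y", "spearman")$coefficient, 1)
  expect_lt(correlation_summary(tab, "x", "z", "kendall")$coefficient, 0)
  expect_equal(correlation_summary(tab, "x", "c")$flag, "constant_input")
  expect_error(correlation_summary(tab[1:3, ], "x", "y"), "5 paired")
})

test_that("statistics are invariant to row order and covariate rescaling", {
  tab <- gen_cohort_table(stats_spec)
  res1 <- group_contrast(tab, "fei_theta", c("HC", "eRBD"))
  set.seed(1)
  res2 <- group_contrast(tab[sample(nrow(tab)), ], "fei_theta", c("HC", "eRBD"))
  expect_equal(res1$p_raw, res2$p_raw, tolerance = 1e-12)
  tab3 <- tab; tab3$age <- (tab3$age - 70) / 7
  res3 <- group_contrast(tab3, "fei_theta", c("HC", "eRBD"))
  expect_equal(res1$p_raw, res3$p_raw, tolerance = 1e-9)
  expect_equal(res1$coefficient, res3$coefficient, tolerance = 1e-9)
})

test_that("band averaging collapses channels then in-band frequencies", {
  bank <- make_bank(512)
  prof <- tidyr::expand_grid(channel = c("a", "b"), freq_hz = bank$freqs)
  prof$band <- band_of(prof$freq_hz)
  prof$dfa <- 0.7; prof$fei <- 1; prof$bis <- 0.5
  prof$dfa_r2 <- 0.99; prof$fei_valid <- TRUE
  ba <- band_average(prof)
  expect_equal(unique(ba$value[ba$metric == "dfa"]), 0.7)
  expect_equal(unique(ba$valid_fraction), 1)
  # theta collects exactly the bank frequencies in [5, 7]
  theta_freqs <- bank$freqs[bank$freqs >= 5 & bank$freqs <= 7]
  expect_equal(sum(!is.na(band_of(bank$freqs)) & band_of(bank$freqs) == "theta"),
               length(theta_freqs))
  # half-valid fEI: average of the valid half, valid fraction 0.5
  prof2 <- prof[prof$channel == "a" & !is.na(prof$band) & prof$band == "theta", ]
  prof2$fei <- c(1.2, NA, 1.2)
  prof2$fei[is.na(prof2$fei)] <- NA
  ba2 <- band_average(prof2)
  fei_row <- ba2[ba2$metric == "fei", ]
  expect_equal(fei_row$value, 1.2)
  expect_equal(fei_row$valid_fraction, 2 / 3)
})

test_that("the baseline battery spans the five bands with corrected alpha", {
  tab <- gen_cohort_table(stats_spec)
  res <- baseline_battery(tab, "bis", c("HC", "ncRBD"))
  expect_equal(nrow(res), 5)
  expect_equal(unique(res$alpha_corrected), 0.01)
  expect_setequal(res$band, c("delta", "theta", "alpha", "beta", "gamma"))
})
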