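small_spec <- function(...) {
  cohort_spec(n_per_group = c(HC = 12, ncRBD = 12, lRBD = 6, eRBD = 6),
              seed = 99, ...)
}

test_that("unknown group labels are rejected with the accepted list", {
  expect_error(cohort_spec(n_per_group = c(HC = 5, RBD = 5)),
               "HC, ncRBD, lRBD, eRBD")
})

test_that("the table generator is deterministic and structurally sound", {
  sp <- small_spec()
  t1 <- gen_cohort_table(sp)
  t2 <- gen_cohort_table(sp)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(sum(t1$visit == "baseline"), 36)
  # HC baseline only; converters have both visits
  expect_false(any(t1$group == "HC" & t1$visit == "followup"))
  fu <- t1[t1$visit == "followup", ]
  expect_setequal(as.character(unique(fu$group)), c("lRBD", "eRBD"))
  expect_equal(nrow(fu), 12)
  expect_true(all(t1$mmse >= 0 & t1$mmse <= 30))
  expect_true(all(t1$updrs3 >= 0))
  expect_true(all(is.na(t1$sbr_putamen[t1$group == "HC"])))
  expect_true(all(table(t1$subject_id) <= 2))
  expect_true(all(c("dfa_delta", "fei_theta", "bis_gamma") %in% names(t1)))
})

test_that("binding ratios decrease with latent severity", {
  tab <- gen_cohort_table(small_spec())
  pat <- tab[tab$group != "HC", ]
  expect_lt(stats::cor(pat$severity, pat$sbr_putamen), 0)
  expect_lt(stats::cor(pat$severity, pat$sbr_caudate), 0)
})

test_that("injected effects shift the loaded bands, null cohorts do not", {
  tab <- gen_cohort_table(small_spec())
  null_tab <- gen_cohort_table(small_spec(), effect_d = 0)
  # patients (severity ~1+) vs HC in a loaded band
  d_eff <- mean(tab$dfa_delta[tab$group != "HC" & tab$visit == "baseline"]) -
    mean(tab$dfa_delta[tab$group == "HC"])
  expect_gt(d_eff, 0)
  # unloaded band stays put
  d_un <- abs(mean(tab$dfa_gamma[tab$group != "HC" & tab$visit == "baseline"]) -
                mean(tab$dfa_gamma[tab$group == "HC"]))
  expect_lt(d_un, 0.06)
  expect_lt(abs(mean(null_tab$fei_theta[null_tab$group != "HC"]) -
                  mean(null_tab$fei_theta[null_tab$group == "HC"])), 0.1)
})

test_that("the full cohort generator yields recordings with ground truth", {
  sp <- cohort_spec(n_per_group = c(HC = 2, ncRBD = 2, lRBD = 2, eRBD = 2),
                    n_channels = 2, duration = 30, fs = 200, seed = 5)
  coh <- gen_cohort(sp)
  expect_length(coh$recordings, 8 + 4)          # 8 baseline + 4 follow-up
  rec <- coh$recordings[[1]]
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(2, 30 * 200))
  expect_equal(nrow(coh$ground_truth), 12 * 5)  # per visit x band
  expect_true(all(c("hurst", "ei", "amp_ratio") %in% names(coh$ground_truth)))
  # severity ordering propagates to the theta coupling ground truth
  gt <- coh$ground_truth[coh$ground_truth$band == "theta" &
                           coh$ground_truth$visit == "baseline", ]
  m <- merge(gt, coh$table[coh$table$visit == "baseline",
                           c("subject_id", "group")])
  agg <- stats::aggregate(ei ~ group, m, mean)
  agg <- agg[match(cohort_groups(), agg$group), ]
  expect_true(all(diff(agg$ei) > 0))
  expect_error(gen_cohort(cohort_spec(n_per_group = c(HC = 1, ncRBD = 2,
                                                      lRBD = 2, eRBD = 2))),
               "at least 2")
})

test_that("cohort export writes EDF, CSV and a ground-truth JSON sidecar", {
  sp <- cohort_spec(n_per_group = c(HC = 2, ncRBD = 2, lRBD = 2, eRBD = 2),
                    followup_groups = character(), n_channels = 1,
                    duration = 5, fs = 128, seed = 6)
  coh <- gen_cohort(sp)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  edfs <- list.files(dir, pattern = "\\.edf$")
  expect_length(edfs, 8)
  back <- read_edf(file.path(dir, edfs[1]))
  expect_equal(back$fs, 128)
  unlink(dir, recursive = TRUE)
})

test_that("profile and graph exports write the documented CSV layouts", {
  prof <- tibble::tibble(channel = "a", freq_hz = 6, band = factor("theta"),
                         dfa = 0.7, dfa_r2 = 0.99, fei = 1, fei_valid = TRUE,
                         bis = 0.2, dbic = 1.6, gamma1 = 0.5, gamma2 = 2,
                         delta1 = 0.5)
  p <- tempfile(fileext = ".csv")
  write_profile(prof, p, "S009", "followup")
  back <- utils::read.csv(p)
  expect_equal(back$subject_id, "S009")
  expect_equal(back$freq_hz, 6)
  W <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  graphs <- list(theta = nodal_metrics(W))
  stem <- tempfile()
  write_graphs(graphs, stem, "S009", "baseline")
  edges <- utils::read.csv(paste0(stem, "_edges.csv"))
  nodes <- utils::read.csv(paste0(stem, "_nodes.csv"))
  expect_equal(edges$wpli, 0.4)
  expect_equal(nrow(nodes), 2)
  expect_true(all(c("strength", "clustering", "eigencentrality") %in% names(nodes)))
  unlink(c(p, paste0(stem, c("_edges.csv", "_nodes.csv"))))
})
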