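test_that("wPLI is symmetric, bounded, and invariant to scaling/rotation", {
  rec <- gen_coupled_pair(8, 0.6, pi / 3, 60, 256, seed = 71)
  bank <- bank_at(256, 8)
  dec <- nb_transform(rec, bank)
  w_ab <- wpli(dec, 1, 2, 1)
  w_ba <- wpli(dec, 2, 1, 1)
  expect_identical(as.numeric(w_ab), as.numeric(w_ba))
  expect_gte(w_ab, 0); expect_lte(w_ab, 1)
  # channel-wise amplitude scaling
  dec2 <- dec; dec2$coeffs[1, 1, ] <- 3.7 * dec2$coeffs[1, 1, ]
  expect_equal(as.numeric(wpli(dec2, 1, 2, 1)), as.numeric(w_ab),
               tolerance = 1e-12)
  # common phase rotation of both channels
  dec3 <- dec; dec3$coeffs <- dec3$coeffs * exp(1i * 0.9)
  expect_equal(as.numeric(wpli(dec3, 1, 2, 1)), as.numeric(w_ab),
               tolerance = 1e-12)
})

test_that("identical or zero-lag channels give a missing wPLI with reason", {
  rec <- gen_coupled_pair(8, 1, 0, 60, 256, seed = 72)
  dec <- nb_transform(rec, bank_at(256, 8))
  w <- wpli(dec, 1, 2, 1)
  expect_true(is.na(w))
  expect_equal(attr(w, "reason"), "zero_denominator")
  w2 <- wpli(dec, 1, 2, 1, min_samples = 1e7)
  expect_equal(attr(w2, "reason"), "insufficient_samples")
})

test_that("a quarter-cycle lag with full coupling saturates wPLI at 1", {
  rec <- gen_coupled_pair(8, 1, pi / 2, 60, 256, seed = 73)
  dec <- nb_transform(rec, bank_at(256, 8))
  expect_equal(as.numeric(wpli(dec, 1, 2, 1)), 1, tolerance = 1e-12)
})

test_that("time-shifting one channel of a coupled pair destroys wPLI", {
  bank <- bank_at(256, 8)
  shifted <- sapply(1:8, function(s) {
    rec <- gen_coupled_pair(8, 1, pi / 2, 200, 256, seed = s)
    shift <- 256 * 5                         # >= 10 cycles at 8 Hz
    rec$data[2, ] <- c(rec$data[2, -seq_len(shift)], rec$data[2, seq_len(shift)])
    wpli(nb_transform(rec, bank), 1, 2, 1)
  })
  indep <- sapply(1:8, function(s) {
    wpli(nb_transform(gen_coupled_pair(8, 0, pi / 2, 200, 256, seed = 100 + s),
                      bank), 1, 2, 1)
  })
  # shifted coupled pairs fall to the independent-pair null level, far from
  # the coupled value of 1 (both null levels scale with 1/sqrt duration)
  expect_lt(mean(shifted), 0.25)
  expect_lt(mean(shifted), mean(indep) + 0.2)
})

test_that("nodal metrics on closed-form graphs", {
  W <- matrix(0.7, 4, 4); diag(W) <- 0
  g <- nodal_metrics(W)
  expect_equal(g$nodes$strength, rep(2.1, 4))
  expect_equal(g$nodes$clustering, rep(1, 4))
  expect_equal(g$nodes$eigencentrality, rep(1, 4), tolerance = 1e-9)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star[2:4, 1] <- 1
  gs <- nodal_metrics(star)
  expect_equal(gs$nodes$strength, c(3, 1, 1, 1))
  expect_equal(gs$nodes$clustering, rep(0, 4))
  expect_equal(gs$nodes$eigencentrality[1], 1)
})

test_that("nodal metrics equal brute-force triple-loop computation", {
  for (s in 1:5) {
    W <- random_graph(10, seed = s)
    g <- nodal_metrics(W)
    o <- brute_nodal(W)
    expect_equal(g$nodes$strength, o$strength, tolerance = 1e-12)
    expect_equal(g$nodes$clustering, o$clustering, tolerance = 1e-12)
    expect_equal(g$nodes$eigencentrality, o$eigencentrality, tolerance = 1e-8)
  }
})

test_that("missing entries are zero-filled and counted; empty graphs degrade", {
  W <- random_graph(5, seed = 6)
  W[1, 2] <- W[2, 1] <- NA
  g <- nodal_metrics(W)
  expect_equal(g$n_missing, 1)
  expect_equal(g$wpli[1, 2], 0)
  gz <- nodal_metrics(matrix(0, 3, 3))
  expect_equal(gz$nodes$strength, rep(0, 3))
  expect_true(all(is.na(gz$nodes$eigencentrality)))
})

test_that("band assignment honors the canonical edges and gaps", {
  bank <- make_bank(512)
  b <- band_of(bank$freqs)
  expect_equal(as.character(b[1]), "delta")      # 2.0 Hz
  expect_true(is.na(b[bank$freqs > 7 & bank$freqs < 8][1]))   # 7.7 Hz gap
  expect_true(is.na(band_of(7.5)))
  expect_equal(as.character(band_of(30)), "beta")  # boundary to lower band
  expect_equal(sort(unique(as.character(stats::na.omit(b)))),
               sort(c("delta", "theta", "alpha", "beta", "gamma")))
})

test_that("band graphs average matrices over in-band frequencies", {
  rec <- gen_coupled_pair(6, 0.7, pi / 2, 90, 256, seed = 74)
  bank <- make_bank(256)
  dec <- nb_transform(rec, bank)
  theta_idx <- which(!is.na(band_of(bank$freqs)) & band_of(bank$freqs) == "theta")
  mats <- sapply(theta_idx, function(fi) wpli_matrix(dec, fi)[1, 2])
  graphs <- band_graphs(dec)
  expect_equal(graphs$theta$wpli[1, 2], mean(mats), tolerance = 1e-12)
  tab <- nodal_table(graphs)
  expect_equal(nrow(tab), 5 * 2)
  expect_true(all(c("band", "channel", "strength", "clustering",
                    "eigencentrality") %in% names(tab)))
  # a band with no bank frequency inside raises a named error
  narrow <- tibble::tibble(band = factor("theta", levels = "theta"),
                           lo = 7.2, hi = 7.4)
  expect_error(band_graphs(dec, narrow), "theta")
})
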