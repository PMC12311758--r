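steady <- function(x, drop = 2000) x[(drop + 1):(length(x) - drop)]

test_that("the notch removes mains and preserves neighbors", {
  fs <- 512; t <- (0:(fs * 20 - 1)) / fs
  r50 <- new_recording(matrix(sin(2 * pi * 50 * t), 1), fs)
  out <- notch_filter(r50)
  expect_lt(stats::sd(steady(out$data[1, ])) / stats::sd(r50$data[1, ]), 0.01)
  r10 <- new_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  expect_lt(abs(stats::sd(steady(notch_filter(r10)$data[1, ])) /
                  stats::sd(steady(r10$data[1, ])) - 1), 0.01)
  rz <- new_recording(matrix(numeric(fs * 20), 1), fs)
  expect_equal(max(abs(notch_filter(rz)$data)), 0)
  expect_error(notch_filter(r50, freq = 300), "Nyquist")
})

test_that("the FIR band-pass attenuates drift and DC, passes the band", {
  fs <- 512; t <- (0:(fs * 30 - 1)) / fs
  rd <- new_recording(matrix(sin(2 * pi * 0.2 * t), 1), fs)
  att <- stats::sd(steady(bandpass_fir(rd)$data[1, ])) / stats::sd(rd$data[1, ])
  expect_lt(att, 10^(-20 / 20))
  r10 <- new_recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  expect_lt(abs(stats::sd(steady(bandpass_fir(r10)$data[1, ])) /
                  stats::sd(steady(r10$data[1, ])) - 1), 0.01)
  rdc <- new_recording(matrix(rep(3, fs * 30), 1), fs)
  expect_lt(max(abs(steady(bandpass_fir(rdc)$data[1, ]))) / 3, 0.01)
  expect_error(bandpass_fir(new_recording(matrix(rnorm(1000), 1), fs)), "short")
})

test_that("filters are linear operators", {
  fs <- 512
  set.seed(51)
  x <- stats::rnorm(fs * 12); y <- stats::rnorm(fs * 12)
  lin <- function(f) {
    fx <- f(new_recording(matrix(x, 1), fs))$data
    fy <- f(new_recording(matrix(y, 1), fs))$data
    fxy <- f(new_recording(matrix(2 * x + 5 * y, 1), fs))$data
    max(abs(fxy - 2 * fx - 5 * fy)) / max(abs(fxy))
  }
  expect_lt(lin(notch_filter), 1e-9)
  expect_lt(lin(bandpass_fir), 1e-9)
})

test_that("the surface Laplacian kills constants and common offsets", {
  mon <- montage_1010()
  set.seed(52)
  dat <- matrix(stats::rnorm(64 * 50), 64)
  rec <- new_recording(dat, 256, labels = mon$label, positions = mon)
  lap1 <- surface_laplacian(rec)
  rec2 <- rec; rec2$data <- rec2$data + 7.3     # channel-common offset
  lap2 <- surface_laplacian(rec2)
  expect_lt(max(abs(lap1$data - lap2$data)) / max(abs(lap1$data)), 1e-9)
  recc <- new_recording(matrix(rep(1, 64 * 10), 64), 256,
                        labels = mon$label, positions = mon)
  expect_lt(max(abs(surface_laplacian(recc)$data)), 1e-10)
})

test_that("the Laplacian of a dipolar field matches the analytic sign pattern", {
  mon <- montage_1010()
  field <- mon$z                       # first-order spherical harmonic
  rec <- new_recording(matrix(field, ncol = 1), 256,
                       labels = mon$label, positions = mon)
  out <- surface_laplacian(rec)$data[, 1]
  # surface Laplacian of Y_1 is proportional to Y_1: same spatial pattern
  expect_gt(abs(stats::cor(out, field)), 0.99)
  expect_true(all(sign(out[abs(field) > 0.5]) ==
                    sign(sign(stats::cor(out, field)) * field[abs(field) > 0.5])))
})

test_that("over-regularization drives the Laplacian to zero monotonically", {
  mon <- montage_1010()
  set.seed(53)
  rec <- new_recording(matrix(stats::rnorm(64 * 10), 64), 256,
                       labels = mon$label, positions = mon)
  amp <- sapply(c(1e-5, 1e-2, 10, 1e4), function(l) {
    max(abs(surface_laplacian(rec, lambda = l)$data))
  })
  expect_true(all(diff(amp) < 0))
})

test_that("bad channels are spline-interpolated from their neighbors", {
  mon <- montage_1010()
  smooth_field <- 2 * mon$z + mon$y - 0.5 * mon$x    # spatially smooth
  dat <- smooth_field %o% rep(1, 20)
  rec <- new_recording(dat, 256, labels = mon$label, positions = mon,
                       bad_channels = c("Cz", "P3"))
  out <- interpolate_bad_channels(rec)
  for (ch in c("Cz", "P3")) {
    i <- match(ch, mon$label)
    err <- sqrt(mean((out$data[i, ] - dat[i, ])^2)) / sqrt(mean(dat[i, ]^2))
    expect_lt(err, 0.1)
  }
  # good channels untouched
  good <- setdiff(mon$label, c("Cz", "P3"))
  expect_identical(out$data[match(good, mon$label), ],
                   dat[match(good, mon$label), ])
  expect_length(out$bad_channels, 0)
  # identity on empty bad list; error when everything is bad or unplaced
  rec0 <- new_recording(dat, 256, labels = mon$label, positions = mon)
  expect_identical(interpolate_bad_channels(rec0), rec0)
  rec_all <- new_recording(dat[1:5, ], 256, labels = mon$label[1:5],
                           positions = mon, bad_channels = mon$label[1:4])
  expect_error(interpolate_bad_channels(rec_all), "good channels")
  rec_np <- new_recording(dat, 256, labels = mon$label, bad_channels = "Cz")
  expect_error(interpolate_bad_channels(rec_np), "montage")
})

test_that("condition selection concatenates segments and records splices", {
  fs <- 100
  ann <- tibble::tibble(onset_s = c(0, 300, 700), duration_s = c(200, 200, 200),
                        label = c("eyes-closed", "eyes-closed", "eyes-closed"))
  rec <- new_recording(matrix(stats::rnorm(fs * 1000), 1), fs, annotations = ann)
  out <- select_condition(rec)
  expect_equal(ncol(out$data), fs * 600)
  expect_equal(out$splices, c(fs * 200, fs * 400))
  # too little data: subject rejected
  ann2 <- tibble::tibble(onset_s = 0, duration_s = 50, label = "eyes-closed")
  rec2 <- new_recording(matrix(stats::rnorm(fs * 100), 1), fs, annotations = ann2)
  expect_error(select_condition(rec2), "rejected")
  expect_error(select_condition(rec, label = "hyperventilation"), "available")
  rec3 <- new_recording(matrix(stats::rnorm(fs * 100), 1), fs)
  expect_error(select_condition(rec3), "no annotations")
})

test_that("the pipeline wrapper records the applied stage order", {
  fs <- 512
  set.seed(54)
  rec <- new_recording(matrix(stats::rnorm(fs * 12, sd = 10), 1), fs)
  out <- preprocess_pipeline(rec, laplacian = FALSE, select = FALSE)
  expect_equal(attr(out, "pipeline"), c("notch", "bandpass"))
  expect_equal(dim(out$data), dim(rec$data))
})
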