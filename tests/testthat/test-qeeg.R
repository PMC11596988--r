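test_that("slice quality mask rejects flat-lines and clipping", {
  rate <- 128
  good <- rep(tone(5, rate, 30, 40), 1) + stats::rnorm(30 * rate, sd = 0.01)
  e <- eeg_recording(good, rate, clip_min = -100, clip_max = 100)
  expect_true(all(slice_quality_mask(e, 1)))
  expect_length(slice_quality_mask(e, 1), 15)

  # flat-line in slice 3 (three identical consecutive samples)
  bad <- good
  bad[(2 * 256 + 10):(2 * 256 + 12)] <- 1.5
  e2 <- eeg_recording(bad, rate, clip_min = -100, clip_max = 100)
  m <- slice_quality_mask(e2, 1)
  expect_false(m[3])
  expect_equal(sum(!m), 1)

  # clipping in slice 5
  bad2 <- good
  bad2[4 * 256 + 7] <- 100
  e3 <- eeg_recording(bad2, rate, clip_min = -100, clip_max = 100)
  expect_false(slice_quality_mask(e3, 1)[5])

  # constant slice is a flat-line
  e4 <- eeg_recording(c(rep(1, 256), good[-(1:256)]), rate,
                      clip_min = -100, clip_max = 100)
  expect_false(slice_quality_mask(e4, 1)[1])
})

test_that("adding clipping never increases the number of valid slices", {
  set.seed(21)
  rate <- 128
  x <- stats::rnorm(30 * rate, sd = 20)
  e <- eeg_recording(x, rate, clip_min = -90, clip_max = 90)
  n0 <- sum(slice_quality_mask(e, 1))
  for (i in 1:5) {
    x[sample(length(x), 10)] <- 90
    e2 <- eeg_recording(x, rate, clip_min = -90, clip_max = 90)
    n1 <- sum(slice_quality_mask(e2, 1))
    expect_lte(n1, n0)
    n0 <- n1
  }
})

test_that("pure 10 Hz tone concentrates in alpha", {
  rp <- multitaper_relative_power(tone(10), 128)
  expect_gt(rp[["alpha"]], 0.95)
  expect_equal(sum(rp), 1, tolerance = 1e-9)
})

test_that("relative powers are amplitude-scale invariant", {
  set.seed(4)
  x <- stats::rnorm(256)
  r1 <- multitaper_relative_power(x, 128)
  r2 <- multitaper_relative_power(x * 1234.5, 128)
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("equal-amplitude 2 Hz + 20 Hz tones split delta/beta evenly", {
  x <- tone(2) + tone(20)
  rp <- multitaper_relative_power(x, 128)
  expect_equal(rp[["delta"]], 0.5, tolerance = 0.02)
  expect_equal(rp[["beta"]], 0.5, tolerance = 0.02)
})

test_that("all-zero slice raises an undefined-power error", {
  expect_error(multitaper_relative_power(rep(0, 256), 128),
               class = "quartersleep_undefined_power")
})

test_that("epoch band powers average valid slices only", {
  rate <- 128
  # identical tone in every slice: epoch mean equals single-slice value
  x <- rep(tone(10, rate, 2, 40), 15) + stats::rnorm(30 * rate, sd = 0.005)
  e <- eeg_recording(x, rate, clip_min = -1e3, clip_max = 1e3)
  ep <- epoch_band_powers(e, 1)
  expect_true(ep$valid)
  expect_equal(ep$n_valid_slices, 15)
  sl <- multitaper_relative_power(x[1:256], rate)
  expect_equal(ep$rel, sl, tolerance = 1e-3)

  # all slices flat -> invalid epoch
  e2 <- eeg_recording(rep(3, 30 * rate), rate,
                      clip_min = -1e3, clip_max = 1e3)
  ep2 <- epoch_band_powers(e2, 1)
  expect_false(ep2$valid)
  expect_equal(ep2$n_valid_slices, 0)
  expect_true(all(is.na(ep2$rel)))

  # 5 valid tone slices + 10 flat slices: alpha-dominated from the 5
  x3 <- c(rep(tone(10, rate, 2, 40), 5) + stats::rnorm(5 * 256, sd = 0.005),
          rep(0.7, 10 * 256))
  e3 <- eeg_recording(x3, rate, clip_min = -1e3, clip_max = 1e3)
  ep3 <- epoch_band_powers(e3, 1)
  expect_equal(ep3$n_valid_slices, 5)
  expect_gt(ep3$rel[["alpha"]], 0.95)
})

test_that("quarter qEEG features have the 120-name schema", {
  set.seed(31)
  pr <- default_profiles()$control
  s <- generate_subject("q1", pr, n_epochs = 48, seed = 5,
                        components = "eeg")
  v <- qeeg_quarter_features(s$eeg, s$hypnogram)
  expect_length(v, 120)
  expect_identical(names(v), feature_names("qeeg"))
})

test_that("single-stage night with a single tone fills only that stage", {
  set.seed(41)
  h <- hypnogram(rep("N2", 40))
  e <- tone_eeg(10, n_ep = 40)
  v <- qeeg_quarter_features(e, h)
  for (k in 1:4) {
    expect_gt(v[[paste0("alpha_N2_Q", k)]], 0.95)
    expect_true(is.na(v[[paste0("alpha_W_Q", k)]]))
    expect_true(is.na(v[[paste0("delta_R_Q", k)]]))
  }
})

test_that("stage-dependent generator spectra are recovered", {
  set.seed(51)
  pr <- default_profiles()$control
  # fixed-stage blocks so every stage x quarter cell is populated
  lab <- rep(rep(c("W", "N1", "N2", "N3", "R"), each = 4), 4)
  h <- hypnogram(lab)
  e <- generate_eeg(h, pr, seed = 52)
  qp <- partition_quarters(structure(list(onset = 1L, end = 80L,
                                          n_epochs = 80L),
                                     class = "sleep_period"))
  v <- qeeg_quarter_features(e, h, qp)
  for (s in sleep_stages()) {
    got <- sapply(band_scheme()$band, function(b) {
      mean(v[paste0(b, "_", s, "_Q", 1:4)])
    })
    # multitaper smoothing (+/- 1 Hz) leaks power across band edges, so
    # recovery of sharp synthetic spectra carries a known bias of up to
    # ~0.1 for the narrow delta band; profile shape must survive it
    expect_lt(max(abs(got - pr$band_weights[s, ])), 0.12)
    expect_equal(which.max(got),
                 which.max(pr$band_weights[s, ]), ignore_attr = TRUE)
    expect_gt(stats::cor(got, pr$band_weights[s, ]), 0.95)
  }
})

test_that("no-score epochs are excluded from qEEG aggregation", {
  h <- hypnogram(rep("N2", 40), no_score = c(rep(TRUE, 39), FALSE))
  e <- tone_eeg(10, n_ep = 40)
  v <- qeeg_quarter_features(e, h)
  # only Q4 retains a scored N2 epoch
  expect_true(all(is.na(v[paste0("alpha_N2_Q", 1:3)])))
  expect_gt(v[["alpha_N2_Q4"]], 0.95)
})
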