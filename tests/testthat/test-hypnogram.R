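test_that("hypnogram CSV reading maps labels and rejects bad input", {
  p <- write_hypnogram_csv(c("W", "N1", "N2"))
  h <- read_hypnogram(p)
  expect_s3_class(h, "hypnogram")
  expect_equal(n_epochs(h), 3)
  expect_equal(h$labels, c("W", "N1", "N2"))

  # alternative spellings via the default mapping
  p2 <- write_hypnogram_csv(c("Wake", "REM", "NREM2"))
  expect_equal(read_hypnogram(p2)$labels, c("W", "R", "N2"))

  p3 <- write_hypnogram_csv(c("W", "N4"))
  expect_error(read_hypnogram(p3), class = "quartersleep_format_error")

  p4 <- tempfile(fileext = ".csv")
  writeLines("epoch_index,stage", p4)
  expect_error(read_hypnogram(p4), class = "quartersleep_empty_input")

  expect_error(hypnogram(character(0)), class = "quartersleep_empty_input")
  expect_error(hypnogram(c("W", "N9")), class = "quartersleep_format_error")
})

test_that("stage mapping can be loaded from YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("SLEEP-REM: R", "SLEEP-S0: W", "SLEEP-S2: N2"), yml)
  m <- stage_mapping_from_yaml(yml)
  p <- write_hypnogram_csv(c("SLEEP-S0", "SLEEP-S2", "SLEEP-REM"))
  expect_equal(read_hypnogram(p, mapping = m)$labels, c("W", "N2", "R"))
})

test_that("persistent sleep onset finds the first >=5 min sleep run", {
  expect_equal(find_persistent_sleep_onset(hypnogram(rep("N2", 10))), 1)

  # a 2-epoch sleep run does not qualify; the 10-epoch run starting at
  # epoch 7 does
  lab <- c("W", "W", "W", "N1", "N2", "W",
           "N1", rep("N2", 9), "W")
  expect_equal(find_persistent_sleep_onset(hypnogram(lab)), 7)

  expect_error(find_persistent_sleep_onset(hypnogram(rep("W", 20))),
               class = "quartersleep_no_sleep_onset")
})

test_that("sleep period trims trailing wake and keeps final REM", {
  sp <- sleep_period(hypnogram(c(rep("N2", 10), "W", "W")))
  expect_equal(c(sp$onset, sp$end), c(1, 10))

  sp2 <- sleep_period(hypnogram(c("W", rep("N2", 10), "W", "R", "W")))
  expect_equal(c(sp2$onset, sp2$end), c(2, 13))

  sp3 <- sleep_period(hypnogram(rep("N2", 10)))
  expect_equal(c(sp3$onset, sp3$end), c(1, 10))
})

test_that("quarter partition is exact with remainder to earliest quarters", {
  qp <- partition_quarters(sleep_period(hypnogram(rep("N2", 40))))
  expect_equal(qp$n_epochs, rep(10, 4))

  qp2 <- partition_quarters(sleep_period(hypnogram(rep("N2", 42))))
  expect_equal(qp2$n_epochs, c(11, 11, 10, 10))

  sp <- list(onset = 1L, end = 3L, n_epochs = 3L)
  class(sp) <- "sleep_period"
  expect_error(partition_quarters(sp), class = "quartersleep_too_short")
})

test_that("quarter partition covers the period disjointly (property)", {
  set.seed(42)
  for (n in sample(4:400, 30)) {
    sp <- structure(list(onset = 5L, end = 4L + n, n_epochs = n),
                    class = "sleep_period")
    qp <- partition_quarters(sp)
    covered <- unlist(lapply(1:4, function(k) qp$start[k]:qp$end[k]))
    expect_equal(covered, 5:(4 + n))          # union, ordered, disjoint
    expect_lte(diff(range(qp$n_epochs)), 1)   # near-equal lengths
  }
})

test_that("stage shift index counts changes per hour", {
  expect_equal(stage_shift_index(hypnogram(rep("N2", 120)), c(1, 120)), 0)
  expect_equal(stage_shift_index(hypnogram(rep(c("N1", "N2"), 60)),
                                 c(1, 120)), 119)
  lab <- c("N1", "N1", "N2", "N2", "N3", "N3", "N3", "N3", "R", "R", "R",
           "R", "W", "N1", "N1", "N1", "N2", "N2", "N2", "N2")
  expect_equal(stage_shift_index(hypnogram(lab), c(1, 20)), 36)
})

test_that("SSI is invariant under stage relabelling", {
  set.seed(7)
  lab <- random_labels(60)
  perm <- setNames(sample(sleep_stages()), sleep_stages())
  h1 <- hypnogram(lab)
  h2 <- hypnogram(unname(perm[lab]))
  expect_equal(stage_shift_index(h1, c(1, 60)),
               stage_shift_index(h2, c(1, 60)))
})

test_that("whole-night metrics match the worked example", {
  h <- hypnogram(c("N1", "N2", "N2", "N2", "R", "R", "N2", "N2", "N2", "N2"))
  m <- whole_night_metrics(h)
  expect_equal(unname(m["N1"]), 0.1)
  expect_equal(unname(m["N2"]), 0.7)
  expect_equal(unname(m["R"]), 0.2)
  expect_equal(unname(m["TST"]), 5.0)
  expect_equal(unname(m["REMonSet"]), 2.0)
  expect_equal(unname(m["SSI"]), 36.0)
  expect_false(attr(m, "rem_missing"))
  expect_identical(names(m), feature_names("whole"))
})

test_that("missing REM uses the full-period sentinel", {
  h <- hypnogram(rep("N2", 10))
  m <- whole_night_metrics(h)
  expect_equal(unname(m["N2"]), 1.0)
  expect_equal(unname(m["TST"]), 5.0)
  expect_equal(unname(m["SSI"]), 0)
  expect_equal(unname(m["REMonSet"]), 5.0)  # 10 epochs = 5 min
  expect_true(attr(m, "rem_missing"))
})

test_that("quarter metrics have 28 names and consistent totals", {
  h <- hypnogram(rep("N2", 40))
  qm <- quarter_night_metrics(h)
  expect_length(qm, 28)
  expect_identical(names(qm), feature_names("quarter"))
  expect_equal(unname(qm[paste0("N2-Q", 1:4)]), rep(1, 4))
  expect_equal(unname(qm[paste0("TST-Q", 1:4)]), rep(5, 4))
  expect_equal(unname(qm[paste0("SSI-Q", 1:4)]), rep(0, 4))

  set.seed(11)
  lab <- c(rep("N2", 10), random_labels(70, p_w = 0.2))
  h2 <- hypnogram(lab)
  sp <- sleep_period(h2)
  qm2 <- quarter_night_metrics(h2, partition_quarters(sp))
  for (k in 1:4) {
    expect_equal(sum(qm2[paste0(sleep_stages(), "-Q", k)]), 1,
                 tolerance = 1e-9)
  }
  wm <- whole_night_metrics(h2, sp)
  # whole-night TST equals the sum of quarter TSTs
  expect_equal(unname(wm["TST"]), sum(qm2[paste0("TST-Q", 1:4)]),
               tolerance = 1e-9)
})

test_that("proportions always sum to one with an onset (property)", {
  set.seed(13)
  for (i in 1:20) {
    lab <- c(random_labels(10), rep("N1", 10), random_labels(20))
    h <- hypnogram(lab)
    m <- whole_night_metrics(h)
    expect_equal(sum(m[sleep_stages()]), 1, tolerance = 1e-9)
  }
})

test_that("non-30s hypnograms are resampled at read time", {
  p <- write_hypnogram_csv(c("W", "W", "N1", "N1", "N2", "N2"))
  expect_message(h <- read_hypnogram(p, epoch_seconds = 15),
                 "resampled")
  expect_equal(h$labels, c("W", "N1", "N2"))
  p2 <- write_hypnogram_csv(c("W", "N2"))
  expect_message(h2 <- read_hypnogram(p2, epoch_seconds = 60))
  expect_equal(h2$labels, c("W", "W", "N2", "N2"))
})
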