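test_that("task tables restrict rows and recode labels", {
  tab <- toy_table(10, 5)
  tt <- build_task_table(tab, "nt1_vs_control")
  expect_equal(nrow(tt), 15)
  expect_equal(levels(tt$label), c("negative", "positive"))
  expect_equal(sum(tt$label == "positive"), 10)

  tab2 <- rbind(tab, transform(toy_table(4, 4, seed = 2),
                               group = rep(c("NT2", "IH"), each = 4)))
  tt2 <- build_task_table(tab2, "nt1_vs_all")
  expect_equal(nrow(tt2), nrow(tab2))
  expect_equal(sum(tt2$label == "negative"), nrow(tab2) - 10)

  expect_error(build_task_table(tab, "nt1_vs_ih"),
               class = "quartersleep_empty_class")
  expect_error(build_task_table(tab, "not_a_task"),
               class = "quartersleep_config_error")
  expect_error(task_spec("bad", negative = character(0)),
               class = "quartersleep_config_error")
  expect_error(task_spec("bad", positive = "NT1",
                         negative = c("NT1", "IH")),
               class = "quartersleep_config_error")
})

test_that("stratified split preserves class proportions and determinism", {
  tab <- build_task_table(toy_table(70, 30), "nt1_vs_control")
  sp <- split_70_30(tab, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sum(sp$train$label == "positive"), 49)
  expect_equal(sum(sp$test$label == "positive"), 21)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)

  sp2 <- split_70_30(tab, seed = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)

  tiny <- build_task_table(toy_table(5, 1), "nt1_vs_control")
  expect_error(split_70_30(tiny, seed = 1),
               class = "quartersleep_split_error")
})

test_that("median imputation uses training statistics only", {
  tab <- build_task_table(toy_table(6, 6), "nt1_vs_control")
  tab$gap <- c(1, 2, 3, NA, NA, 100, 200, 300, NA, NA, NA, 4)
  tr <- tab[1:6, ]; te <- tab[7:12, ]
  imp <- impute_from_train(tr, te)
  med <- stats::median(c(1, 2, 3, 100), na.rm = TRUE)
  expect_equal(imp$medians[["gap"]], med)
  expect_equal(imp$test$gap[3], med)   # test NA filled from train median
  expect_false(anyNA(imp$train$gap))
})

test_that("SMOTE balances counts and interpolates within the minority", {
  tab <- build_task_table(toy_table(40, 10), "nt1_vs_control")
  out <- smote_balance(tab, k_neighbors = 5, seed = 2)
  expect_equal(unname(table(out$label)), c(40, 40), ignore_attr = TRUE)

  balanced <- build_task_table(toy_table(10, 10), "nt1_vs_control")
  expect_identical(smote_balance(balanced, seed = 2), balanced)

  # synthetic points lie on segments between minority points (2D check)
  set.seed(3)
  d2 <- data.frame(subject_id = sprintf("d%02d", 1:15),
                   group = c(rep("NT1", 12), rep("control", 3)),
                   age = 30, rem_missing = FALSE,
                   x = c(stats::rnorm(12), c(10, 11, 12)),
                   y = c(stats::rnorm(12), c(10, 12, 11)))
  tt <- build_task_table(d2, "nt1_vs_control")
  out2 <- smote_balance(tt, k_neighbors = 2, seed = 4)
  syn <- out2[grepl("^syn", out2$subject_id), ]
  expect_equal(nrow(syn), 9)
  expect_true(all(syn$label == "negative"))
  # inside the minority bounding box, far from the majority cluster
  expect_true(all(syn$x >= 10 & syn$x <= 12 & syn$y >= 10 & syn$y <= 12))

  single <- build_task_table(toy_table(5, 2), "nt1_vs_control")[1:6, ]
  expect_error(smote_balance(single, seed = 1),
               class = "quartersleep_cannot_augment")

  expect_warning(smote_balance(build_task_table(toy_table(9, 3),
                                                "nt1_vs_control"),
                               k_neighbors = 5, seed = 1),
                 "reduced")
})

test_that("correlated-feature removal keeps one of each duplicate group", {
  set.seed(5)
  df <- data.frame(subject_id = as.character(1:30), group = "NT1",
                   age = 30, rem_missing = FALSE,
                   a = stats::rnorm(30))
  df$b <- df$a                        # duplicate pair
  df$c <- stats::rnorm(30)
  sel <- remove_correlated(df, threshold = 0.9)
  expect_length(intersect(sel, c("a", "b")), 1)
  expect_true("c" %in% sel)

  # three mutual duplicates leave exactly one survivor
  df$a2 <- df$a; df$a3 <- df$a
  sel3 <- remove_correlated(df, threshold = 0.9)
  expect_length(intersect(sel3, c("a", "b", "a2", "a3")), 1)

  # orthogonal noise is untouched
  big <- as.data.frame(matrix(stats::rnorm(50 * 8), 50, 8))
  big <- cbind(data.frame(subject_id = as.character(1:50), group = "x",
                          age = 1, rem_missing = FALSE), big)
  expect_length(remove_correlated(big, threshold = 0.9), 8)

  # importance hint decides which duplicate survives
  hint <- c(a = 0.1, b = 0.9, c = 0.5)
  sel_h <- remove_correlated(df[, 1:7], threshold = 0.9, importance = hint)
  expect_true("b" %in% sel_h)
  expect_false("a" %in% sel_h)
})

test_that("metrics match hand-computed values", {
  truth <- factor(c("positive", "negative", "positive", "negative"),
                  levels = c("negative", "positive"))
  scores <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(auc_roc(truth, scores), 0.75)
  expect_equal(auc_pr(truth, scores), 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(f1_score(truth, scores), 2 * 2 / (2 * 2 + 1 + 0))
  expect_error(auc_pr(factor(rep("positive", 3),
                             levels = c("negative", "positive")),
                      c(0.1, 0.2, 0.3)),
               class = "quartersleep_metric_error")
})

test_that("fit_and_score is perfect on separable data, null on shuffled", {
  tab <- build_task_table(toy_table(30, 30, delta = 8), "nt1_vs_control")
  sp <- split_70_30(tab, seed = 6)
  res <- fit_and_score(sp$train, sp$test, model = "rf", seed = 7)
  expect_equal(unname(res$metrics["F1"]), 1)
  expect_equal(unname(res$metrics["AUC_ROC"]), 1)

  # shuffled labels: AUC near 1/2
  set.seed(8)
  null_tab <- tab
  null_tab$label <- sample(null_tab$label)
  aucs <- vapply(1:10, function(i) {
    spn <- split_70_30(null_tab, seed = i)
    fit_and_score(spn$train, spn$test, model = "rf",
                  seed = i)$metrics[["AUC_ROC"]]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)

  # determinism for rf given a seed
  r1 <- fit_and_score(sp$train, sp$test, model = "rf", seed = 11)
  r2 <- fit_and_score(sp$train, sp$test, model = "rf", seed = 11)
  expect_identical(r1$metrics, r2$metrics)

  # degenerate single-class test set
  bad_test <- sp$test[sp$test$label == "positive", ]
  expect_error(fit_and_score(sp$train, bad_test, model = "rf"),
               class = "quartersleep_metric_error")
})

test_that("xgboost and gp backends produce valid scores", {
  tab <- build_task_table(toy_table(25, 25, delta = 6), "nt1_vs_control")
  sp <- split_70_30(tab, seed = 12)
  for (m in c("xgboost", "gp")) {
    res <- fit_and_score(sp$train, sp$test, model = m, seed = 13)
    expect_true(all(res$metrics >= 0 & res$metrics <= 1))
    expect_gt(res$metrics[["AUC_ROC"]], 0.9)  # easy separable problem
  }
})

test_that("realization loop is reproducible and summarised correctly", {
  tab <- toy_table(25, 12, delta = 2.5)
  run <- run_realizations(tab, "nt1_vs_control", model = "rf",
                          n_realizations = 5, seed = 21)
  expect_length(run$results, 5)
  run2 <- run_realizations(tab, "nt1_vs_control", model = "rf",
                           n_realizations = 5, seed = 21)
  expect_identical(run$summary, run2$summary)
  f1s <- vapply(run$results, function(r) r$metrics[["F1"]], numeric(1))
  expect_equal(run$summary$mean[run$summary$metric == "F1"], mean(f1s))
  expect_gte(run$summary$mean[1], min(f1s) - 1e-12)

  it <- importance_table(run)
  expect_true(is.data.frame(it))
  expect_equal(it$rank, seq_len(nrow(it)))
  expect_equal(sum(it$n_top), 5)
  # the label-defining feature dominates removal importance
  expect_equal(it$feature[1], "signal")
  expect_gt(it$mean_drop[1], 0)
  # pure-noise features have near-zero importance
  noise_rows <- it[grepl("^noise", it$feature), ]
  expect_true(all(abs(noise_rows$mean_drop) < 0.15))
})

test_that("permutation importance mode also ranks the signal first", {
  tab <- toy_table(25, 12, delta = 2.5)
  run <- run_realizations(tab, "nt1_vs_control", model = "rf",
                          n_realizations = 3, seed = 22,
                          options = list(importance_mode = "permutation"))
  it <- importance_table(run)
  expect_equal(it$feature[1], "signal")
})

test_that("training-only preprocessing blocks held-out leakage", {
  # marker feature carries the label, but only on held-out rows: all
  # training values are missing, so imputation (train medians), SMOTE and
  # selection never see usable signal, and test AUC must stay at chance.
  set.seed(23)
  n <- 60
  base <- toy_table(n / 2, n / 2, k_noise = 6, delta = 0)  # pure noise
  base$signal <- NULL
  aucs_base <- aucs_marker <- numeric(5)
  for (i in 1:5) {
    tt <- build_task_table(base, "nt1_vs_control")
    sp <- split_70_30(tt, seed = 100 + i)
    sp_m <- sp
    sp_m$train$marker <- NA_real_
    sp_m$test$marker <- as.numeric(sp_m$test$label == "positive")
    run_once <- function(spx) {
      imp <- impute_from_train(spx$train, spx$test)
      bal <- smote_balance(imp$train, seed = 200 + i)
      sel <- remove_correlated(bal)
      fit_and_score(bal, imp$test, model = "rf", features = sel,
                    seed = 300 + i)$metrics[["AUC_ROC"]]
    }
    aucs_base[i] <- run_once(sp)
    aucs_marker[i] <- run_once(sp_m)
  }
  expect_lt(mean(aucs_marker), mean(aucs_base) + 0.1)
  expect_lt(abs(mean(aucs_marker) - 0.5), 0.2)
})
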