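`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification task specifications
#'
#' A task pits NT1 (the positive class) against a non-empty set of
#' negative groups.  [classification_tasks()] returns the five standard
#' tasks: NT1 vs clinical controls, NT1 vs NT2, NT1 vs IH, NT1 vs
#' NT2 + IH, and NT1 vs All.
#'
#' @param name Task name.
#' @param positive Positive-class group (default `"NT1"`).
#' @param negative Character vector of negative-class groups.
#' @return Object of class `"task_spec"`.
#' @export
task_spec <- function(name, positive = "NT1", negative) {
  if (length(negative) == 0) {
    qs_stop("negative class set must be non-empty",
            "quartersleep_config_error")
  }
  if (positive %in% negative) {
    qs_stop("positive class cannot be in the negative set",
            "quartersleep_config_error")
  }
  structure(list(name = name, positive = positive, negative = negative),
            class = "task_spec")
}

#' @rdname task_spec
#' @export
classification_tasks <- function() {
  list(
    nt1_vs_control = task_spec("nt1_vs_control", negative = "control"),
    nt1_vs_nt2 = task_spec("nt1_vs_nt2", negative = "NT2"),
    nt1_vs_ih = task_spec("nt1_vs_ih", negative = "IH"),
    nt1_vs_nt2_ih = task_spec("nt1_vs_nt2_ih", negative = c("NT2", "IH")),
    nt1_vs_all = task_spec("nt1_vs_all",
                           negative = c("NT2", "IH", "control"))
  )
}

as_task <- function(task) {
  if (inherits(task, "task_spec")) return(task)
  tasks <- classification_tasks()
  if (!task %in% names(tasks)) {
    qs_stop(sprintf("unknown task '%s'", task), "quartersleep_config_error")
  }
  tasks[[task]]
}

#' Restrict a feature table to a classification task
#'
#' Keeps the rows belonging to the task's groups and recodes the group
#' into a binary `label` factor with levels `negative`/`positive`.
#'
#' @param table Feature table ([cohort_feature_table()]).
#' @param task A [task_spec()] or the name of a standard task.
#' @return The task table (feature table with a `label` column).
#' @export
build_task_table <- function(table, task) {
  task <- as_task(task)
  unknown <- setdiff(c(task$positive, task$negative), unique(table$group))
  if (length(unknown) > 0) {
    qs_stop(sprintf("group(s) with no subjects in the table: %s",
                    paste(unknown, collapse = ", ")),
            "quartersleep_empty_class")
  }
  out <- table[table$group %in% c(task$positive, task$negative), ,
               drop = FALSE]
  out$label <- factor(ifelse(out$group == task$positive,
                             "positive", "negative"),
                      levels = c("negative", "positive"))
  rownames(out) <- NULL
  out
}

#' Stratified 70/30 split
#'
#' Splits a task table into training and held-out parts, stratified by
#' label: per class, 70% of subjects (rounded) go to training and the
#' rest are held out.
#'
#' @param table Task table with a `label` column.
#' @param seed Optional integer seed.
#' @param train_frac Training fraction (default 0.7).
#' @return List with `train` and `test` data frames (disjoint).
#' @export
split_70_30 <- function(table, seed = NULL, train_frac = 0.7) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot("label" %in% names(table))
  counts <- table(table$label)
  if (any(counts < 2)) {
    qs_stop("every class needs at least 2 subjects to stratify",
            "quartersleep_split_error")
  }
  train_idx <- integer(0)
  for (cl in levels(table$label)) {
    idx <- which(table$label == cl)
    n_train <- min(max(round(train_frac * length(idx)), 1L),
                   length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), ,
                    drop = FALSE])
}

#' Median imputation from training statistics only
#'
#' Computes per-feature medians on the training rows and fills missing
#' values in both training and held-out rows with them, so no held-out
#' information leaks into the fit.  Features missing in every training row
#' are filled with 0.
#'
#' @param train,test Task tables from [split_70_30()].
#' @return List with imputed `train`, `test` and the `medians` used.
#' @export
impute_from_train <- function(train, test) {
  feats <- feature_cols(train)
  med <- vapply(train[feats], function(x) {
    m <- stats::median(x, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  fill <- function(df) {
    for (f in feats) {
      miss <- is.na(df[[f]])
      if (any(miss)) df[[f]][miss] <- med[[f]]
    }
    df
  }
  list(train = fill(train), test = fill(test), medians = med)
}

#' SMOTE class balancing of a training table
#'
#' Oversamples the minority class by synthetic-minority interpolation:
#' each synthetic row lies on the segment between a minority row and one
#' of its `k_neighbors` nearest minority neighbours (Euclidean distance in
#' feature space), until the two classes have equal counts.  Applied to
#' training rows only, never to held-out data.
#'
#' @param train Imputed task table (no missing feature values).
#' @param k_neighbors Number of nearest neighbours (default 5; reduced
#'   with a warning when the minority class is too small).
#' @param seed Optional integer seed.
#' @return The augmented training table; synthetic rows have
#'   `subject_id` `"syn<i>"`.
#' @export
smote_balance <- function(train, k_neighbors = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- table(train$label)
  n_needed <- max(counts) - min(counts)
  if (n_needed == 0) return(train)
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(train$label == minority)
  n_min <- length(min_idx)
  if (n_min < 2) {
    qs_stop("cannot SMOTE-augment a single-member minority class",
            "quartersleep_cannot_augment")
  }
  if (n_min - 1 < k_neighbors) {
    warning(sprintf("k_neighbors reduced from %d to %d (minority size %d)",
                    k_neighbors, n_min - 1, n_min))
    k_neighbors <- n_min - 1
  }
  feats <- feature_cols(train)
  x <- as.matrix(train[min_idx, feats, drop = FALSE])
  if (anyNA(x)) {
    qs_stop("SMOTE requires imputed (complete) training features",
            "quartersleep_format_error")
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  base <- rep_len(seq_len(n_min), n_needed)
  syn <- matrix(NA_real_, n_needed, length(feats),
                dimnames = list(NULL, feats))
  for (j in seq_len(n_needed)) {
    b <- base[j]
    nb <- nn[b, sample.int(k_neighbors, 1)]
    u <- stats::runif(1)
    syn[j, ] <- x[b, ] + u * (x[nb, ] - x[b, ])
  }
  meta <- train[min_idx[base], setdiff(names(train), feats), drop = FALSE]
  meta$subject_id <- sprintf("syn%03d", seq_len(n_needed))
  syn_df <- cbind(meta, as.data.frame(syn, check.names = FALSE))
  out <- rbind(train, syn_df[, names(train)])
  rownames(out) <- NULL
  out
}

#' Recursive removal of correlated features
#'
#' While any pair of surviving features has absolute Spearman rank
#' correlation above `threshold`, drops one member of the most correlated
#' pair: the one with the lower preliminary importance when an
#' `importance` hint is given, otherwise the one with the higher mean
#' absolute correlation with all other features (ties broken by name
#' order, so the result is deterministic).
#'
#' @param train Imputed training table (or any data frame of features).
#' @param threshold Correlation threshold (default 0.9).
#' @param importance Optional named numeric vector of preliminary
#'   importances (larger = keep).
#' @param features Candidate features (default: all feature columns).
#' @return Character vector of surviving feature names, in original order.
#' @export
remove_correlated <- function(train, threshold = 0.9, importance = NULL,
                              features = feature_cols(train)) {
  x <- as.matrix(train[, features, drop = FALSE])
  if (ncol(x) < 2) return(features)
  suppressWarnings(cm <- stats::cor(x, method = "spearman"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  keep <- rep(TRUE, ncol(cm))
  names(keep) <- features
  repeat {
    a <- abs(cm)
    a[!keep, ] <- 0
    a[, !keep] <- 0
    mx <- max(a)
    if (mx <= threshold) break
    pair <- which(a == mx, arr.ind = TRUE)[1, ]
    i <- pair[["row"]]; j <- pair[["col"]]
    imp_of <- function(f) {
      if (f %in% names(importance)) importance[[f]] else -Inf
    }
    drop_i <- if (!is.null(importance)) {
      ii <- imp_of(features[i])
      jj <- imp_of(features[j])
      if (ii < jj) TRUE else if (jj < ii) FALSE else i > j
    } else {
      mi <- mean(abs(cm[i, keep])); mj <- mean(abs(cm[j, keep]))
      if (mi > mj) TRUE else if (mj > mi) FALSE else i > j
    }
    keep[if (drop_i) i else j] <- FALSE
  }
  features[keep]
}

# ---- metrics --------------------------------------------------------------

#' Binary classification metrics
#'
#' `f1_score` thresholds the scores at 0.5; `auc_roc` is the area under
#' the ROC curve; `auc_pr` is the area under the precision-recall curve
#' (step interpolation, i.e. average precision).  The positive class is
#' the `"positive"` level of `truth`.
#'
#' @param truth Factor with levels `negative`/`positive`.
#' @param scores Numeric scores (probability of the positive class).
#' @param threshold Decision threshold for `f1_score`.
#' @return A number in `[0, 1]`.
#' @export
f1_score <- function(truth, scores, threshold = 0.5) {
  pred <- scores >= threshold
  pos <- truth == "positive"
  tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @rdname f1_score
#' @export
auc_roc <- function(truth, scores) {
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' @rdname f1_score
#' @export
auc_pr <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- truth[ord] == "positive"
  n_pos <- sum(pos)
  if (n_pos == 0 || n_pos == length(pos)) {
    qs_stop("PR AUC undefined for a single-class test set",
            "quartersleep_metric_error")
  }
  # evaluate only at distinct-score cut points
  s <- scores[ord]
  cut <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(pos)[cut]
  prec <- tp / cut
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# ---- model backends -------------------------------------------------------

fit_backend <- function(train, model, features, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(train[, features, drop = FALSE])
  y <- train$label
  if (model == "rf") {
    fit <- randomForest::randomForest(
      x = x, y = y,
      ntree = params$ntree %||% 300,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(x)))))
    list(model = "rf", fit = fit, features = features)
  } else if (model == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "positive"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.1,
                    nthread = 1),
      data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0)
    list(model = "xgboost", fit = fit, features = features)
  } else if (model == "gp") {
    # drop zero-variance columns: gausspr scales inputs internally
    keep <- features[apply(x, 2, stats::sd) > 0]
    fit <- kernlab::gausspr(x = x[, keep, drop = FALSE], y = y,
                            kernel = "rbfdot")
    list(model = "gp", fit = fit, features = keep)
  } else {
    qs_stop(sprintf("unknown model '%s'", model),
            "quartersleep_config_error")
  }
}

predict_scores <- function(fit, newdata) {
  x <- as.matrix(newdata[, fit$features, drop = FALSE])
  if (fit$model == "rf") {
    unname(stats::predict(fit$fit, x, type = "prob")[, "positive"])
  } else if (fit$model == "xgboost") {
    unname(stats::predict(fit$fit, xgboost::xgb.DMatrix(x)))
  } else {
    p <- kernlab::predict(fit$fit, x, type = "probabilities")
    p <- as.matrix(p)
    unname(p[, which(colnames(p) == "positive")])
  }
}

#' Fit a classifier and score it on held-out data
#'
#' Fits the chosen backend (random forest, gradient boosting or Gaussian
#' process) on a prepared (imputed, class-balanced) training table and
#' computes F1 (at the 0.5 threshold), AUC_ROC and AUC_PR on the held-out
#' rows.
#'
#' @param train Prepared training table.
#' @param test Held-out table (imputed from training statistics only).
#' @param model `"rf"`, `"xgboost"` or `"gp"`.
#' @param features Features to use (default: all feature columns).
#' @param params Backend hyperparameters (list).
#' @param seed Optional integer seed (RF and boosting are deterministic
#'   given it).
#' @return List with `metrics` (named vector `F1`, `AUC_ROC`, `AUC_PR`),
#'   `scores`, and the fitted backend.
#' @export
fit_and_score <- function(train, test, model = "rf",
                          features = feature_cols(train),
                          params = list(), seed = NULL) {
  if (length(unique(test$label)) < 2) {
    qs_stop("held-out set contains a single class; metrics undefined",
            "quartersleep_metric_error")
  }
  fit <- fit_backend(train, model, features, params, seed)
  scores <- predict_scores(fit, test)
  metrics <- c(F1 = f1_score(test$label, scores),
               AUC_ROC = auc_roc(test$label, scores),
               AUC_PR = auc_pr(test$label, scores))
  list(metrics = metrics, scores = scores, fit = fit)
}

# ---- realization loop -----------------------------------------------------

default_ml_options <- function() {
  list(cor_threshold = 0.9, smote_k = 5, params = list(),
       importance = TRUE,
       importance_metric = "f1",       # or "auc"
       importance_mode = "refit",      # or "permutation" (approximation)
       train_frac = 0.7, max_fail_frac = 0.1)
}

# One split -> impute -> SMOTE -> selection -> fit -> score -> importance
# cycle.  Exposed via run_realizations(); also usable directly.
#' @rdname run_realizations
#' @param task_table A [build_task_table()] result.
#' @export
classify_once <- function(task_table, seed, model = "rf",
                          options = default_ml_options()) {
  options <- utils::modifyList(default_ml_options(), options)
  set.seed(seed)
  sp <- split_70_30(task_table, train_frac = options$train_frac)
  imp <- impute_from_train(sp$train, sp$test)
  train_b <- smote_balance(imp$train, options$smote_k)
  feats <- feature_cols(train_b)
  ylab <- as.numeric(train_b$label == "positive")
  suppressWarnings(
    hint <- abs(apply(train_b[, feats, drop = FALSE], 2,
                      function(v) stats::cor(v, ylab, method = "spearman"))))
  hint[is.na(hint)] <- 0
  selected <- remove_correlated(train_b, options$cor_threshold, hint)
  # one fit seed per realization, shared by the baseline fit and every
  # leave-one-feature-out refit: importance then reflects the removal,
  # not forest-resampling noise
  fit_seed <- sample.int(.Machine$integer.max - 1L, 1)
  base <- fit_and_score(train_b, imp$test, model, selected,
                        options$params, seed = fit_seed)
  importance <- NULL
  if (isTRUE(options$importance)) {
    metric_fn <- if (options$importance_metric == "auc") {
      function(truth, s) auc_roc(truth, s)
    } else {
      function(truth, s) f1_score(truth, s)
    }
    base_val <- metric_fn(imp$test$label, base$scores)
    importance <- vapply(selected, function(f) {
      if (options$importance_mode == "refit") {
        reduced <- setdiff(selected, f)
        if (length(reduced) == 0) return(base_val)
        r <- fit_backend(train_b, model, reduced, options$params,
                         seed = fit_seed)
        base_val - metric_fn(imp$test$label, predict_scores(r, imp$test))
      } else {
        perm <- imp$test
        perm[[f]] <- sample(perm[[f]])
        base_val - metric_fn(perm$label, predict_scores(base$fit, perm))
      }
    }, numeric(1))
  }
  list(seed = seed, selected = selected, metrics = base$metrics,
       importance = importance)
}

#' Resampled classification with removal-based feature importance
#'
#' The core evaluation loop: `n_realizations` independent cycles of
#' stratified 70/30 split, training-side median imputation and SMOTE
#' balancing, recursive correlated-feature removal, model fitting and
#' held-out scoring (F1, AUC_ROC, AUC_PR).  Per-realization feature
#' importance is the drop in held-out score (F1 by default; AUC
#' optionally) when the feature is removed from the classifier and the
#' model refit.  Per-realization seeds derive from the master seed, so a
#' run is fully reproducible.
#'
#' Realizations that fail (e.g. degenerate splits on tiny cohorts) are
#' skipped with a warning; the run aborts if more than
#' `options$max_fail_frac` of them fail.
#'
#' @param table Feature table ([cohort_feature_table()]).
#' @param task A [task_spec()] or standard task name.
#' @param model `"rf"` (primary), `"xgboost"` or `"gp"`.
#' @param n_realizations Number of split/fit cycles (200 for full runs).
#' @param seed Master integer seed.
#' @param features Optional restriction to a feature subset (e.g.
#'   `feature_names("whole")`).
#' @param options List of options; see `default_ml_options()` in the
#'   package source (correlation threshold 0.9, SMOTE k = 5, refit-based
#'   F1-drop importance).
#' @return Object of class `"qs_realizations"`: list with `results` (one
#'   [classify_once()] result per realization), `summary` (mean and SD of
#'   each metric), `task`, `model`, `n_failed`.
#' @export
run_realizations <- function(table, task, model = "rf",
                             n_realizations = 200, seed = 1,
                             features = NULL,
                             options = list()) {
  options <- utils::modifyList(default_ml_options(), options)
  task <- as_task(task)
  tt <- build_task_table(table, task)
  if (!is.null(features)) {
    tt <- tt[, c(intersect(meta_cols(), names(tt)), features),
             drop = FALSE]
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_realizations)
  results <- vector("list", n_realizations)
  failed <- 0L
  for (i in seq_len(n_realizations)) {
    results[[i]] <- tryCatch(
      classify_once(tt, seeds[i], model, options),
      quartersleep_error = function(e) {
        warning(sprintf("realization %d failed: %s", i,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(results[[i]])) failed <- failed + 1L
  }
  if (failed > options$max_fail_frac * n_realizations) {
    qs_stop(sprintf("%d/%d realizations failed", failed, n_realizations),
            "quartersleep_run_error")
  }
  results <- Filter(Negate(is.null), results)
  m <- do.call(rbind, lapply(results, function(r) r$metrics))
  summary <- data.frame(metric = colnames(m),
                        mean = colMeans(m),
                        sd = apply(m, 2, stats::sd),
                        row.names = NULL)
  structure(list(results = results, summary = summary,
                 task = task$name, model = model, n_failed = failed),
            class = "qs_realizations")
}

#' @export
print.qs_realizations <- function(x, ...) {
  cat(sprintf("<qs_realizations> task %s, model %s, %d realizations (%d failed)\n",
              x$task, x$model, length(x$results), x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Aggregate removal importance across realizations
#'
#' Averages each feature's per-realization score drop across *all*
#' realizations: a feature eliminated as redundant in a realization is
#' absent from that classifier, so it contributes a drop of zero there.
#' (The conditional mean over selected-only realizations is reported as
#' `mean_drop_selected`.)  Also counts how often each feature was the
#' top-ranked (largest-drop) feature of its realization.  Features are
#' ranked by `mean_drop` (larger = more important).
#'
#' @param run A [run_realizations()] result with importance enabled.
#' @return Data frame sorted by rank: `feature`, `mean_drop`, `sd_drop`,
#'   `mean_drop_selected`, `n_selected`, `n_top`, `rank`.
#' @export
importance_table <- function(run) {
  imps <- lapply(run$results, function(r) r$importance)
  imps <- Filter(Negate(is.null), imps)
  if (length(imps) == 0) {
    qs_stop("run has no importance values (importance disabled?)",
            "quartersleep_config_error")
  }
  all_feats <- unique(unlist(lapply(imps, names)))
  mat <- matrix(NA_real_, length(imps), length(all_feats),
                dimnames = list(NULL, all_feats))
  for (i in seq_along(imps)) mat[i, names(imps[[i]])] <- imps[[i]]
  top <- vapply(imps, function(v) names(v)[which.max(v)], character(1))
  zero_filled <- mat
  zero_filled[is.na(zero_filled)] <- 0
  out <- data.frame(
    feature = all_feats,
    mean_drop = colMeans(zero_filled),
    sd_drop = apply(zero_filled, 2, stats::sd),
    mean_drop_selected = colMeans(mat, na.rm = TRUE),
    n_selected = colSums(!is.na(mat)),
    n_top = as.integer(table(factor(top, levels = all_feats))))
  out <- out[order(-out$mean_drop), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
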