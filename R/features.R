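#' Feature-set name registry
#'
#' Canonical names and order of every feature emitted by the extractors.
#' The five sets are: `whole` (8 whole-night sleep metrics), `quarter`
#' (28 quarter-night sleep metrics), `transitions` (100 quarter-night
#' transition-matrix entries), `qeeg` (120 stage-conditional relative band
#' powers) and `hypnodensity` (64 hypnodensity marginals, mixtures and
#' entropies).  `all` is their 320-name union.
#'
#' @param set One of `"whole"`, `"quarter"`, `"transitions"`, `"qeeg"`,
#'   `"hypnodensity"`, `"all"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(set = c("all", "whole", "quarter", "transitions",
                                  "qeeg", "hypnodensity")) {
  set <- match.arg(set)
  st <- sleep_stages()
  q <- function(x) as.vector(vapply(1:4, function(k) paste0(x, "-Q", k),
                                    character(length(x))))
  out <- switch(
    set,
    whole = c(st, "TST", "SSI", "REMonSet"),
    quarter = q(c(st, "TST", "SSI")),
    transitions = q(as.vector(t(outer(st, st,
                                      function(a, b) paste0(a, "to", b))))),
    qeeg = {
      v <- character(0)
      for (k in 1:4) for (s in st) {
        v <- c(v, paste0(band_scheme()$band, "_", s, "_Q", k))
      }
      v
    },
    hypnodensity = q(c(paste0("p", st), hd_pair_names(), "H")),
    all = c(feature_names("whole"), feature_names("quarter"),
            feature_names("transitions"), feature_names("qeeg"),
            feature_names("hypnodensity"))
  )
  out
}

#' Which feature set does each feature belong to
#'
#' @param features Character vector of feature names.
#' @return Character vector of set labels.
#' @export
feature_set_of <- function(features) {
  sets <- c("whole", "quarter", "transitions", "qeeg", "hypnodensity")
  lookup <- stats::setNames(
    rep(sets, vapply(sets, function(s) length(feature_names(s)),
                     integer(1))),
    unlist(lapply(sets, feature_names)))
  unname(lookup[features])
}

#' Extract all features for one subject
#'
#' Runs every extractor on a subject record: whole-night and quarter-night
#' sleep metrics from the hypnogram, quarter-night transition features,
#' stage-conditional qEEG features (when an EEG is present) and
#' hypnodensity features (when a hypnodensity is present; 15-s inputs are
#' averaged to 30 s first).  Missing input channels yield `NA` features.
#'
#' @param record A [generate_subject()] record, or any list with elements
#'   `hypnogram` and optionally `eeg` (an [eeg_recording()]) and
#'   `hypnodensity` (a [hypnodensity()]).
#' @param scheme A [band_scheme()].
#' @return Named numeric vector over `feature_names("all")`, with
#'   attribute `rem_missing`.
#' @export
extract_subject_features <- function(record, scheme = band_scheme()) {
  h <- record$hypnogram
  sp <- sleep_period(h)
  qp <- partition_quarters(sp)
  whole <- whole_night_metrics(h, sp)
  quarter <- quarter_night_metrics(h, qp)
  trans <- quarter_transition_features(h, qp)
  qeeg <- if (!is.null(record$eeg)) {
    qeeg_quarter_features(record$eeg, h, qp, scheme)
  } else {
    stats::setNames(rep(NA_real_, 120), feature_names("qeeg"))
  }
  hdf <- if (!is.null(record$hypnodensity)) {
    hd <- record$hypnodensity
    if (hd$epoch_seconds == 15) hd <- downsample_to_30s(hd)
    hypnodensity_quarter_features(hd, qp)
  } else {
    stats::setNames(rep(NA_real_, 64), feature_names("hypnodensity"))
  }
  out <- c(whole, quarter, trans, qeeg, hdf)
  stopifnot(identical(names(out), feature_names("all")))
  attr(out, "rem_missing") <- attr(whole, "rem_missing")
  out
}

#' Build the subjects-by-features table for a cohort
#'
#' Extracts all features for every subject and assembles the interchange
#' table used by the statistics and classification modules: one row per
#' subject with metadata columns `subject_id`, `group`, `age`,
#' `rem_missing`, followed by the 320 feature columns.  Subjects without a
#' persistent sleep onset are skipped with a warning.
#'
#' @param cohort A [generate_cohort()] result, or a plain list of subject
#'   records.
#' @param scheme A [band_scheme()].
#' @return Data frame (one row per usable subject).
#' @export
cohort_feature_table <- function(cohort, scheme = band_scheme()) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  rows <- list()
  for (s in subjects) {
    feats <- tryCatch(extract_subject_features(s, scheme),
                      quartersleep_no_sleep_onset = function(e) {
                        warning(sprintf("subject %s skipped: %s", s$id,
                                        conditionMessage(e)), call. = FALSE)
                        NULL
                      })
    if (is.null(feats)) next
    meta <- data.frame(subject_id = s$id, group = s$group, age = s$age,
                       rem_missing = isTRUE(attr(feats, "rem_missing")))
    rows[[length(rows) + 1L]] <- cbind(meta, as.data.frame(as.list(feats),
                                                           check.names = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a cohort and extract its feature table, one subject at a time
#'
#' Equivalent to `cohort_feature_table(generate_cohort(config, seed))` but
#' each subject's raw signals are discarded as soon as its features are
#' extracted, keeping memory flat for large cohorts.
#'
#' @inheritParams generate_cohort
#' @param scheme A [band_scheme()].
#' @return Data frame as in [cohort_feature_table()].
#' @export
simulate_feature_table <- function(config = cohort_config(), seed = 1,
                                   scheme = band_scheme()) {
  set.seed(seed)
  groups <- rep(names(config$n), config$n)
  n_total <- length(groups)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  ids <- sprintf("S%03d", seq_len(n_total))
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    s <- generate_subject(ids[i], config$profiles[[groups[i]]],
                          n_epochs = config$n_epochs, rate = config$rate,
                          seed = subj_seeds[i],
                          components = config$components)
    rows[[i]] <- cohort_feature_table(list(s), scheme)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metadata column names of a feature table
#' @keywords internal
meta_cols <- function() c("subject_id", "group", "age", "rem_missing",
                          "label")

feature_cols <- function(table) setdiff(names(table), meta_cols())
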