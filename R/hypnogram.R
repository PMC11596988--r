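#' @keywords internal
"_PACKAGE"

#' Sleep stage alphabet
#'
#' The five-stage alphabet used throughout the package, in canonical order:
#' wake, N1, N2, N3 and REM.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "R")`.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

qs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "quartersleep_error"),
                      call = call))
}

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of sleep-stage labels, one per scoring
#' epoch (30 s by convention).  All sleep-metric, transition and
#' stage-conditional features in this package are computed from hypnograms.
#'
#' @param labels Character vector of stage labels, each one of
#'   [sleep_stages()].
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @param no_score Optional logical vector (same length as `labels`) marking
#'   epochs excluded from qEEG aggregation (e.g. arousal or high-noise
#'   epochs).
#' @param start_clock_time Optional `POSIXct` timestamp of the first epoch.
#' @return An object of class `"hypnogram"`.
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N2", "R"))
#' n_epochs(h)
#' @export
hypnogram <- function(labels, epoch_seconds = 30, no_score = NULL,
                      start_clock_time = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    qs_stop("hypnogram must contain at least one epoch",
            "quartersleep_empty_input")
  }
  bad <- setdiff(unique(labels), sleep_stages())
  if (length(bad) > 0L) {
    qs_stop(sprintf("unknown stage label(s): %s",
                    paste(bad, collapse = ", ")),
            "quartersleep_format_error")
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0) {
    qs_stop("epoch_seconds must be a single positive number",
            "quartersleep_format_error")
  }
  if (is.null(no_score)) {
    no_score <- rep(FALSE, length(labels))
  } else {
    stopifnot(is.logical(no_score), length(no_score) == length(labels))
    no_score[is.na(no_score)] <- FALSE
  }
  structure(list(labels = labels,
                 epoch_seconds = as.numeric(epoch_seconds),
                 no_score = no_score,
                 start_clock_time = start_clock_time),
            class = "hypnogram")
}

#' @rdname hypnogram
#' @param h A `hypnogram`.
#' @export
n_epochs <- function(h) length(h$labels)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = sleep_stages()))
  cat(sprintf("<hypnogram> %d epochs of %gs (%.1f min)\n",
              n_epochs(x), x$epoch_seconds,
              n_epochs(x) * x$epoch_seconds / 60))
  print(tab)
  invisible(x)
}

#' Default stage-label mapping for hypnogram files
#'
#' Maps common label spellings (AASM names, numeric export codes) onto the
#' five-stage alphabet.  Extend or replace it to accommodate lab-specific
#' export formats, or load a mapping from YAML with
#' [stage_mapping_from_yaml()].
#'
#' @return Named character vector: names are input labels, values are
#'   canonical stages.
#' @export
default_stage_mapping <- function() {
  c("W" = "W", "N1" = "N1", "N2" = "N2", "N3" = "N3", "R" = "R",
    "WAKE" = "W", "REM" = "R", "NREM1" = "N1", "NREM2" = "N2",
    "NREM3" = "N3", "S1" = "N1", "S2" = "N2", "S3" = "N3", "S4" = "N3",
    "0" = "W", "1" = "N1", "2" = "N2", "3" = "N3", "4" = "N3", "5" = "R")
}

#' @rdname default_stage_mapping
#' @param path Path to a YAML file of `input_label: stage` pairs.
#' @export
stage_mapping_from_yaml <- function(path) {
  m <- yaml::read_yaml(path)
  out <- vapply(m, as.character, character(1))
  bad <- setdiff(unique(out), sleep_stages())
  if (length(bad) > 0L) {
    qs_stop(sprintf("mapping targets outside the stage alphabet: %s",
                    paste(bad, collapse = ", ")),
            "quartersleep_format_error")
  }
  out
}

#' Read a hypnogram from file
#'
#' Reads a per-epoch stage-label file and validates it against the
#' five-stage alphabet.  The CSV dialect expects one row per epoch with a
#' `stage` column (an `epoch_index` column and an optional logical
#' `no_score` column are honoured; a headerless single column of labels is
#' also accepted).
#'
#' @param path Path to the file.
#' @param dialect Input dialect.  Only `"csv"` is implemented; hypnograms
#'   exported from EDF+ annotation tracks should be converted to per-epoch
#'   CSV first.
#' @param mapping Named character vector mapping file labels onto
#'   [sleep_stages()]; see [default_stage_mapping()].
#' @param epoch_seconds Scoring epoch length of the file, seconds.  Files
#'   scored at other epoch lengths than 30 s are resampled to 30 s at read
#'   time (label repetition when shorter, majority vote when longer), with
#'   a message.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("csv", "edf_annotations"),
                           mapping = default_stage_mapping(),
                           epoch_seconds = 30) {
  dialect <- match.arg(dialect)
  if (dialect == "edf_annotations") {
    qs_stop("the edf_annotations dialect is not available in this build; export the annotation track to per-epoch CSV",
            "quartersleep_format_error")
  }
  if (!file.exists(path)) {
    qs_stop(sprintf("file not found: %s", path), "quartersleep_io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("stage", first, ignore.case = TRUE)
  if (has_header) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    raw <- as.character(df$stage)
    no_score <- if ("no_score" %in% names(df)) {
      as.logical(df$no_score)
    } else NULL
  } else {
    raw <- utils::read.csv(path, header = FALSE,
                           stringsAsFactors = FALSE)[[if (grepl(",", first)) 2L else 1L]]
    raw <- as.character(raw)
    no_score <- NULL
  }
  raw <- trimws(raw)
  if (length(raw) == 0L) {
    qs_stop("empty hypnogram file", "quartersleep_empty_input")
  }
  key <- toupper(raw)
  names(mapping) <- toupper(names(mapping))
  unknown <- setdiff(unique(key), names(mapping))
  if (length(unknown) > 0L) {
    qs_stop(sprintf("unmappable stage label(s): %s",
                    paste(unknown, collapse = ", ")),
            "quartersleep_format_error")
  }
  labels <- unname(mapping[key])
  if (epoch_seconds != 30) {
    res <- resample_labels_30s(labels, epoch_seconds)
    message(sprintf("resampled hypnogram from %gs to 30s epochs (%d -> %d)",
                    epoch_seconds, length(labels), length(res)))
    labels <- res
    no_score <- NULL
  }
  hypnogram(labels, epoch_seconds = 30, no_score = no_score)
}

# Repeat labels when source epochs are shorter than 30 s divides evenly;
# majority vote over each 30-s window otherwise.
resample_labels_30s <- function(labels, epoch_seconds) {
  if (epoch_seconds < 30 && (30 %% epoch_seconds) == 0) {
    k <- 30 %/% epoch_seconds
    n <- (length(labels) %/% k) * k
    grp <- rep(seq_len(n %/% k), each = k)
    vapply(split(labels[seq_len(n)], grp), function(x) {
      names(sort(table(x), decreasing = TRUE))[1L]
    }, character(1), USE.NAMES = FALSE)
  } else if (epoch_seconds > 30 && (epoch_seconds %% 30) == 0) {
    rep(labels, each = epoch_seconds %/% 30)
  } else {
    qs_stop(sprintf("cannot resample %gs epochs to 30s", epoch_seconds),
            "quartersleep_format_error")
  }
}

#' Persistent sleep onset
#'
#' Finds the first epoch that begins a run of at least `min_sleep_minutes`
#' of continuous sleep (consecutive non-wake epochs).  All analysis windows
#' in this package start at persistent sleep onset.
#'
#' @param h A [hypnogram()].
#' @param min_sleep_minutes Minimum continuous sleep, minutes (default 5,
#'   i.e. 10 consecutive 30-s epochs).
#' @return 1-based epoch index of the onset epoch.
#' @export
find_persistent_sleep_onset <- function(h, min_sleep_minutes = 5) {
  min_epochs <- min_sleep_minutes * 60 / h$epoch_seconds
  if (abs(min_epochs - round(min_epochs)) > 1e-9) {
    qs_stop("min_sleep_minutes must be a whole number of epochs",
            "quartersleep_format_error")
  }
  min_epochs <- as.integer(round(min_epochs))
  asleep <- h$labels != "W"
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_epochs)
  if (length(ok) == 0L) {
    qs_stop(sprintf("no run of >= %d consecutive sleep epochs found",
                    min_epochs),
            "quartersleep_no_sleep_onset")
  }
  starts[ok[1L]]
}

#' Sleep period (analysis window)
#'
#' The analysis window runs from persistent sleep onset to the final
#' sleep epoch of the recording; trailing wake is excluded.
#'
#' @inheritParams find_persistent_sleep_onset
#' @return An object of class `"sleep_period"`: list with 1-based inclusive
#'   epoch indices `onset` and `end`, and `n_epochs = end - onset + 1`.
#' @export
sleep_period <- function(h, min_sleep_minutes = 5) {
  onset <- find_persistent_sleep_onset(h, min_sleep_minutes)
  last_sleep <- max(which(h$labels != "W"))
  structure(list(onset = onset, end = last_sleep,
                 n_epochs = last_sleep - onset + 1L),
            class = "sleep_period")
}

#' @export
print.sleep_period <- function(x, ...) {
  cat(sprintf("<sleep_period> epochs [%d, %d], %d epochs (%.1f min)\n",
              x$onset, x$end, x$n_epochs, x$n_epochs / 2))
  invisible(x)
}

#' Partition a sleep period into quarter-nights
#'
#' Divides the sleep period into four contiguous segments of equal epoch
#' count.  When the period length is not divisible by 4, the remainder
#' epochs are assigned one each to the earliest quarters, so quarter
#' lengths never differ by more than one epoch.
#'
#' @param sp A [sleep_period()].
#' @return An object of class `"quarter_partition"`: data frame with
#'   columns `quarter`, `start`, `end` (1-based inclusive) and `n_epochs`.
#' @export
partition_quarters <- function(sp) {
  n <- sp$n_epochs
  if (n < 4L) {
    qs_stop(sprintf("sleep period too short to quarter (%d epochs)", n),
            "quartersleep_too_short")
  }
  base <- n %/% 4L
  lens <- base + as.integer(seq_len(4L) <= (n %% 4L))
  ends <- sp$onset - 1L + cumsum(lens)
  starts <- ends - lens + 1L
  structure(data.frame(quarter = 1:4, start = starts, end = ends,
                       n_epochs = lens),
            class = c("quarter_partition", "data.frame"))
}

as_epoch_range <- function(range) {
  if (inherits(range, "sleep_period")) {
    c(range$onset, range$end)
  } else {
    stopifnot(is.numeric(range), length(range) == 2L, range[1] <= range[2])
    as.integer(range)
  }
}

#' Stage shift index
#'
#' Number of changes between sleep stages (wake counted as a stage) per
#' hour over an epoch range; a measure of sleep fragmentation.
#'
#' @param h A [hypnogram()].
#' @param range A [sleep_period()] or integer `c(start, end)` (1-based
#'   inclusive).
#' @return Stage changes per hour.
#' @export
stage_shift_index <- function(h, range) {
  r <- as_epoch_range(range)
  lab <- h$labels[r[1]:r[2]]
  n <- length(lab)
  hours <- n * h$epoch_seconds / 3600
  if (n < 2L) return(0)
  sum(lab[-1L] != lab[-n]) / hours
}

#' Whole-night sleep metrics
#'
#' The eight whole-night sleep-metric features computed over the analysis
#' window: the proportion of epochs spent in each of W, N1, N2, N3 and REM
#' (fractions of the window, summing to 1), total sleep time (`TST`,
#' minutes in any non-wake stage), stage shift index (`SSI`, changes/hour)
#' and REM sleep-onset latency (`REMonSet`, minutes from persistent sleep
#' onset to the first REM epoch).
#'
#' When the window contains no REM epoch, `REMonSet` is set to the full
#' window duration in minutes (so later always means larger) and the
#' result carries `attr(x, "rem_missing") = TRUE`.
#'
#' @param h A [hypnogram()].
#' @param sp A [sleep_period()]; computed from `h` if missing.
#' @return Named numeric vector of length 8.
#' @examples
#' h <- hypnogram(c("N1", "N2", "N2", "N2", "R", "R", "N2", "N2", "N2", "N2"))
#' whole_night_metrics(h, sleep_period(h))
#' @export
whole_night_metrics <- function(h, sp = sleep_period(h)) {
  lab <- h$labels[sp$onset:sp$end]
  mins_per_epoch <- h$epoch_seconds / 60
  props <- as.numeric(table(factor(lab, levels = sleep_stages()))) /
    length(lab)
  tst <- sum(lab != "W") * mins_per_epoch
  ssi <- stage_shift_index(h, sp)
  first_r <- which(lab == "R")[1L]
  rem_missing <- is.na(first_r)
  remonset <- if (rem_missing) {
    length(lab) * mins_per_epoch
  } else {
    (first_r - 1) * mins_per_epoch
  }
  out <- c(props, tst, ssi, remonset)
  names(out) <- c(sleep_stages(), "TST", "SSI", "REMonSet")
  attr(out, "rem_missing") <- rem_missing
  out
}

#' Quarter-night sleep metrics
#'
#' The 28 quarter-night sleep-metric features: for each quarter, the five
#' stage proportions (fractions of the quarter's epochs), TST within the
#' quarter (minutes) and SSI within the quarter (changes/hour).  Names are
#' suffixed `-Q1` .. `-Q4`.
#'
#' @param h A [hypnogram()].
#' @param qp A [partition_quarters()] partition.
#' @return Named numeric vector of length 28.
#' @export
quarter_night_metrics <- function(h, qp = partition_quarters(sleep_period(h))) {
  mins_per_epoch <- h$epoch_seconds / 60
  out <- numeric(0)
  for (k in 1:4) {
    lab <- h$labels[qp$start[k]:qp$end[k]]
    props <- as.numeric(table(factor(lab, levels = sleep_stages()))) /
      length(lab)
    tst <- sum(lab != "W") * mins_per_epoch
    ssi <- stage_shift_index(h, c(qp$start[k], qp$end[k]))
    v <- c(props, tst, ssi)
    names(v) <- paste0(c(sleep_stages(), "TST", "SSI"), "-Q", k)
    out <- c(out, v)
  }
  out
}
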