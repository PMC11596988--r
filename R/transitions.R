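#' Sleep-stage transition matrix
#'
#' Row-conditional transition probabilities between the five stages over an
#' epoch range.  Adjacent ordered epoch pairs within the range are counted
#' (self-transitions on the diagonal included); each row with at least one
#' outgoing pair is normalised to probabilities, and rows for stages never
#' visited as a "from" state are left as zeros.
#'
#' @param h A [hypnogram()].
#' @param range A [sleep_period()] or integer `c(start, end)` (1-based
#'   inclusive), length at least 2 epochs.
#' @param normalize `"probability"` (default) for row-conditional
#'   probabilities, or `"per_hour"` for transition counts per hour of the
#'   range.
#' @return 5x5 numeric matrix with dimnames over [sleep_stages()] and an
#'   attribute `"visited"`: logical vector marking rows with outgoing
#'   pairs.
#' @examples
#' h <- hypnogram(c("N1", "N2", "N1", "N2", "N1"))
#' transition_matrix(h, c(1, 5))
#' @export
transition_matrix <- function(h, range,
                              normalize = c("probability", "per_hour")) {
  normalize <- match.arg(normalize)
  r <- as_epoch_range(range)
  lab <- h$labels[r[1]:r[2]]
  n <- length(lab)
  if (n < 2L) {
    qs_stop("range must contain at least 2 epochs to count transitions",
            "quartersleep_degenerate_range")
  }
  st <- sleep_stages()
  from <- factor(lab[-n], levels = st)
  to <- factor(lab[-1L], levels = st)
  counts <- table(from, to)
  m <- matrix(as.numeric(counts), 5, 5, dimnames = list(st, st))
  visited <- rowSums(m) > 0
  if (normalize == "probability") {
    m[visited, ] <- m[visited, , drop = FALSE] /
      rowSums(m[visited, , drop = FALSE])
  } else {
    hours <- n * h$epoch_seconds / 3600
    m <- m / hours
  }
  attr(m, "visited") <- visited
  m
}

#' Quarter-night transition features
#'
#' Flattens the four quarter-night transition matrices into the 100-entry
#' feature vector (25 per quarter), named `XtoY-Qk`.  Pairs straddling a
#' quarter boundary are not counted, so quarters remain independent.
#'
#' @inheritParams quarter_night_metrics
#' @param normalize Passed to [transition_matrix()].
#' @return Named numeric vector of length 100.
#' @export
quarter_transition_features <- function(h,
                                        qp = partition_quarters(sleep_period(h)),
                                        normalize = "probability") {
  st <- sleep_stages()
  nm <- as.vector(t(outer(st, st, function(a, b) paste0(a, "to", b))))
  out <- numeric(0)
  for (k in 1:4) {
    m <- transition_matrix(h, c(qp$start[k], qp$end[k]),
                           normalize = normalize)
    v <- as.vector(t(m))  # row-major: WtoW, WtoN1, ..., RtoR
    names(v) <- paste0(nm, "-Q", k)
    out <- c(out, v)
  }
  out
}
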