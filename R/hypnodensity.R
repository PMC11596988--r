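#' Construct a hypnodensity
#'
#' A hypnodensity is a per-epoch probability distribution over the five
#' sleep stages, as produced by probabilistic sleep-staging models, rather
#' than a hard stage label.  Mixed sleep/wake states show up as probability
#' mass spread over several stages.
#'
#' @param p Numeric matrix, epochs x 5, columns in [sleep_stages()] order
#'   (a data frame with those columns is accepted).  Every row must sum to
#'   1 within 1e-6.
#' @param epoch_seconds 15 or 30.
#' @return Object of class `"hypnodensity"`.
#' @export
hypnodensity <- function(p, epoch_seconds = 30) {
  if (is.data.frame(p)) p <- as.matrix(p[, sleep_stages()])
  stopifnot(is.matrix(p), ncol(p) == 5)
  if (!epoch_seconds %in% c(15, 30)) {
    qs_stop("epoch_seconds must be 15 or 30", "quartersleep_format_error")
  }
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    qs_stop("probabilities must lie in [0, 1]", "quartersleep_format_error")
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    qs_stop("every hypnodensity row must sum to 1",
            "quartersleep_format_error")
  }
  p <- unname(p)
  colnames(p) <- sleep_stages()
  structure(list(p = p, epoch_seconds = epoch_seconds),
            class = "hypnodensity")
}

#' @export
print.hypnodensity <- function(x, ...) {
  cat(sprintf("<hypnodensity> %d epochs of %gs\n", nrow(x$p),
              x$epoch_seconds))
  invisible(x)
}

#' Read a hypnodensity from CSV
#'
#' Expects one row per epoch with columns `W,N1,N2,N3,R`.
#'
#' @param path CSV path.
#' @param epoch_seconds Epoch length of the file (15 or 30 s).
#' @return A [hypnodensity()].
#' @export
read_hypnodensity <- function(path, epoch_seconds = 30) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(sleep_stages(), names(df))
  if (length(missing_cols) > 0) {
    qs_stop(sprintf("hypnodensity CSV lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "quartersleep_format_error")
  }
  hypnodensity(df, epoch_seconds)
}

#' Average a 15-s hypnodensity down to 30-s epochs
#'
#' Averages consecutive pairs of 15-s rows, matching the 30-s grid of the
#' hypnogram; a trailing odd epoch is dropped with a message.
#'
#' @param hd A [hypnodensity()] at 15-s epochs.
#' @return A [hypnodensity()] at 30-s epochs.
#' @export
downsample_to_30s <- function(hd) {
  stopifnot(inherits(hd, "hypnodensity"))
  if (hd$epoch_seconds != 15) {
    qs_stop("downsample_to_30s expects a 15-s hypnodensity",
            "quartersleep_format_error")
  }
  n <- nrow(hd$p)
  if (n %% 2 == 1) {
    message("odd trailing 15-s epoch dropped during downsampling")
    n <- n - 1L
  }
  odd <- seq(1L, n, by = 2L)
  p <- (hd$p[odd, , drop = FALSE] + hd$p[odd + 1L, , drop = FALSE]) / 2
  hypnodensity(p, 30)
}

hd_pair_names <- function() {
  st <- sleep_stages()
  pairs <- utils::combn(st, 2)
  paste0(pairs[1, ], pairs[2, ])
}

#' Quarter-night hypnodensity features
#'
#' The 64 quarter-night hypnodensity features (16 per quarter): the mean
#' marginal probability of each of the five stages; the mean of each of
#' the ten pairwise mixed-state products `p_X * p_Y` (X < Y in stage
#' order), computed per epoch and then averaged; and the mean per-epoch
#' Shannon entropy of the stage probabilities (natural log, nats).
#'
#' Names: marginals `pW-Qk` .. `pR-Qk`; mixtures concatenate the two stage
#' names, e.g. `WR-Q1` is the mean of Pr(Wake)*Pr(REM) over quarter 1;
#' entropy `H-Qk`.
#'
#' @param hd A [hypnodensity()] at 30-s epochs, aligned to the hypnogram
#'   used to build `qp`.
#' @param qp A [partition_quarters()] partition.
#' @param mixture How to aggregate pairwise products: `"per_epoch"`
#'   (default; average the per-epoch products, sensitive to within-epoch
#'   state mixing) or `"of_means"` (product of the quarter-mean marginals).
#' @param entropy_base Base of the entropy logarithm (default `exp(1)`,
#'   nats).
#' @return Named numeric vector of length 64.
#' @export
hypnodensity_quarter_features <- function(hd, qp,
                                          mixture = c("per_epoch", "of_means"),
                                          entropy_base = exp(1)) {
  mixture <- match.arg(mixture)
  stopifnot(inherits(hd, "hypnodensity"))
  if (hd$epoch_seconds != 30) {
    qs_stop("quarter features require a 30-s hypnodensity (see downsample_to_30s)",
            "quartersleep_format_error")
  }
  if (nrow(hd$p) < max(qp$end)) {
    qs_stop("hypnodensity shorter than the hypnogram sleep period",
            "quartersleep_alignment_error")
  }
  st <- sleep_stages()
  pairs <- utils::combn(5, 2)
  pnames <- hd_pair_names()
  out <- numeric(0)
  for (q in 1:4) {
    p <- hd$p[qp$start[q]:qp$end[q], , drop = FALSE]
    marg <- colMeans(p)
    mix <- if (mixture == "per_epoch") {
      vapply(seq_len(ncol(pairs)), function(j) {
        mean(p[, pairs[1, j]] * p[, pairs[2, j]])
      }, numeric(1))
    } else {
      vapply(seq_len(ncol(pairs)), function(j) {
        marg[pairs[1, j]] * marg[pairs[2, j]]
      }, numeric(1))
    }
    plogp <- p * log(p, base = entropy_base)
    plogp[p == 0] <- 0
    ent <- mean(-rowSums(plogp))
    v <- c(marg, mix, ent)
    names(v) <- paste0(c(paste0("p", st), pnames, "H"), "-Q", q)
    out <- c(out, v)
  }
  out
}
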