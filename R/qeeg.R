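#' EEG band scheme
#'
#' The six-band partition of the 0.5-47 Hz range used for relative band
#' powers: delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-16, beta 16-30 and
#' gamma 30-47 Hz.  Bands are contiguous and half-open `[low, high)`.
#'
#' @param low,high Optional numeric vectors of band edges (Hz) to override
#'   the defaults; must be contiguous and non-overlapping.
#' @param names Band names.
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
band_scheme <- function(low = c(0.5, 4, 8, 12, 16, 30),
                        high = c(4, 8, 12, 16, 30, 47),
                        names = c("delta", "theta", "alpha", "sigma",
                                  "beta", "gamma")) {
  stopifnot(length(low) == length(high), length(names) == length(low))
  if (any(high <= low)) {
    qs_stop("band edges must satisfy low < high", "quartersleep_format_error")
  }
  if (length(low) > 1 && any(abs(low[-1] - high[-length(high)]) > 1e-9)) {
    qs_stop("bands must be contiguous and non-overlapping",
            "quartersleep_format_error")
  }
  data.frame(band = names, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' Construct an epoch-aligned EEG recording
#'
#' Single-channel EEG samples aligned to a hypnogram's 30-s epoch grid.
#' Samples beyond a whole number of epochs are truncated (with a message).
#'
#' @param samples Numeric vector of samples (microvolts).
#' @param rate Sampling rate, samples/s.
#' @param epoch_seconds Epoch length, seconds (default 30).
#' @param clip_min,clip_max Recorder saturation limits (same units as
#'   `samples`).  If `NULL`, the observed extrema of the recording are used
#'   as limits, with a warning, so saturated-at-range slices are still
#'   caught.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(samples, rate, epoch_seconds = 30,
                          clip_min = NULL, clip_max = NULL) {
  stopifnot(is.numeric(samples), rate > 0)
  if (any(!is.finite(samples))) {
    qs_stop("EEG samples must be finite", "quartersleep_format_error")
  }
  spe <- as.integer(round(rate * epoch_seconds))
  n_ep <- length(samples) %/% spe
  if (n_ep < 1L) {
    qs_stop("recording shorter than one epoch", "quartersleep_empty_input")
  }
  if (length(samples) > n_ep * spe) {
    message(sprintf("truncating %d trailing samples (partial epoch)",
                    length(samples) - n_ep * spe))
    samples <- samples[seq_len(n_ep * spe)]
  }
  if (is.null(clip_min) || is.null(clip_max)) {
    warning("no clip limits supplied; using observed extrema as recorder limits")
    if (is.null(clip_min)) clip_min <- min(samples)
    if (is.null(clip_max)) clip_max <- max(samples)
  }
  structure(list(samples = samples, rate = rate,
                 epoch_seconds = epoch_seconds, n_epochs = n_ep,
                 clip_min = clip_min, clip_max = clip_max),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d epochs at %g Hz (%.1f min)\n",
              x$n_epochs, x$rate, x$n_epochs * x$epoch_seconds / 60))
  invisible(x)
}

# Discrete prolate spheroidal (Slepian) sequences via the symmetric
# tridiagonal formulation; eigenvectors ordered by concentration.
# Cached per (n, nw, k) -- the eigen decomposition is only done once.
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  m <- matrix(0, n, n)
  m[cbind(t + 1, t + 1)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- off
  m[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so each taper has positive mean (even tapers)
  # or positive initial slope (odd tapers)
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) < 1e-8) s <- tap[2, j] - tap[1, j]
    if (s < 0) tap[, j] <- -tap[, j]
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
  }
  dpss_cache[[key]] <- tap
  tap
}

# Multitaper PSD of the columns of a samples-by-slices matrix.
# Returns (n %/% 2 + 1) x n_slices matrix of one-sided power estimates.
multitaper_psd_matrix <- function(x, nw = 2, k = 3) {
  n <- nrow(x)
  tap <- dpss_tapers(n, nw, k)
  nf <- n %/% 2 + 1
  psd <- matrix(0, nf, ncol(x))
  for (j in seq_len(k)) {
    ft <- stats::mvfft(x * tap[, j])
    psd <- psd + Mod(ft[seq_len(nf), , drop = FALSE])^2
  }
  psd / k
}

band_bin_index <- function(n, rate, scheme) {
  freqs <- (seq_len(n %/% 2 + 1) - 1) * rate / n
  idx <- rep(NA_integer_, length(freqs))
  for (b in seq_len(nrow(scheme))) {
    idx[freqs >= scheme$low[b] & freqs < scheme$high[b]] <- b
  }
  idx
}

#' Multitaper relative band powers of one slice
#'
#' Multitaper power spectral density of a short analysis slice (2 s by
#' convention), integrated over the bands of a [band_scheme()] and
#' normalised by the total power over all bands of interest, so the six
#' values sum to 1.
#'
#' @param slice Numeric vector of samples (one slice).
#' @param rate Sampling rate, samples/s.
#' @param scheme A [band_scheme()].
#' @param nw Time-bandwidth product of the Slepian tapers (default 2).
#' @param k Number of tapers (default 3).
#' @return Named numeric vector of relative band powers, summing to 1.
#' @examples
#' t <- seq(0, 2, length.out = 257)[-257]
#' multitaper_relative_power(sin(2 * pi * 10 * t), 128, band_scheme())
#' @export
multitaper_relative_power <- function(slice, rate, scheme = band_scheme(),
                                      nw = 2, k = 3) {
  if (all(slice == 0)) {
    qs_stop("all-zero slice has undefined relative power",
            "quartersleep_undefined_power")
  }
  psd <- multitaper_psd_matrix(matrix(slice, ncol = 1), nw, k)[, 1]
  idx <- band_bin_index(length(slice), rate, scheme)
  bp <- vapply(seq_len(nrow(scheme)),
               function(b) sum(psd[which(idx == b)]), numeric(1))
  out <- bp / sum(bp)
  names(out) <- scheme$band
  out
}

epoch_slice_matrix <- function(e, epoch, slice_seconds = 2) {
  spe <- as.integer(round(e$rate * e$epoch_seconds))
  sps <- as.integer(round(e$rate * slice_seconds))
  n_slices <- spe %/% sps
  off <- (epoch - 1L) * spe
  matrix(e$samples[off + seq_len(n_slices * sps)], nrow = sps)
}

# Vectorised quality check on a samples-by-slices matrix: a slice is bad if
# any sample reaches the clip limits or any 3 consecutive samples are equal.
slice_mask_matrix <- function(x, clip_min, clip_max) {
  clipped <- colSums(x >= clip_max | x <= clip_min) > 0
  d0 <- x[-1, , drop = FALSE] == x[-nrow(x), , drop = FALSE]
  flat <- colSums(d0[-1, , drop = FALSE] &
                    d0[-nrow(d0), , drop = FALSE]) > 0
  !(clipped | flat)
}

#' Per-slice artifact mask for one epoch
#'
#' Splits a 30-s epoch into non-overlapping 2-s slices and marks each slice
#' valid or not.  A slice is rejected if it contains any clipping (samples
#' at or beyond the recorder limits) or any flat-line run of three or more
#' identical consecutive samples.
#'
#' @param e An [eeg_recording()].
#' @param epoch 1-based epoch index.
#' @param slice_seconds Slice length, seconds (default 2).
#' @return Logical vector, one entry per slice (`TRUE` = valid).
#' @export
slice_quality_mask <- function(e, epoch, slice_seconds = 2) {
  stopifnot(epoch >= 1, epoch <= e$n_epochs)
  x <- epoch_slice_matrix(e, epoch, slice_seconds)
  slice_mask_matrix(x, e$clip_min, e$clip_max)
}

#' Relative band powers of one epoch
#'
#' Mean relative band power over the valid 2-s slices of a 30-s epoch.
#' The epoch is invalid when no slice survives artifact rejection.
#'
#' @inheritParams slice_quality_mask
#' @inheritParams multitaper_relative_power
#' @return List with `rel` (named 6-vector, `NA` when invalid),
#'   `n_valid_slices` and `valid`.
#' @export
epoch_band_powers <- function(e, epoch, scheme = band_scheme(),
                              slice_seconds = 2, nw = 2, k = 3) {
  x <- epoch_slice_matrix(e, epoch, slice_seconds)
  ok <- slice_quality_mask(e, epoch, slice_seconds)
  ok <- ok & colSums(x != 0) > 0
  if (!any(ok)) {
    rel <- stats::setNames(rep(NA_real_, nrow(scheme)), scheme$band)
    return(list(rel = rel, n_valid_slices = 0L, valid = FALSE))
  }
  psd <- multitaper_psd_matrix(x[, ok, drop = FALSE], nw, k)
  idx <- band_bin_index(nrow(x), e$rate, scheme)
  bp <- rowsum(psd[!is.na(idx), , drop = FALSE], idx[!is.na(idx)])
  rel_slices <- sweep(bp, 2, colSums(bp), "/")
  rel <- rowMeans(rel_slices)
  names(rel) <- scheme$band
  list(rel = rel, n_valid_slices = sum(ok), valid = TRUE)
}

# Band powers for every epoch at once (chunked over slices for memory).
# Returns list(rel = n_epochs x n_bands matrix, valid = logical).
all_epoch_band_powers <- function(e, scheme = band_scheme(),
                                  slice_seconds = 2, nw = 2, k = 3,
                                  chunk_slices = 4000L) {
  spe <- as.integer(round(e$rate * e$epoch_seconds))
  sps <- as.integer(round(e$rate * slice_seconds))
  spq <- spe %/% sps                      # slices per epoch
  n_sl <- e$n_epochs * spq
  idx <- band_bin_index(sps, e$rate, scheme)
  keep <- !is.na(idx)
  nb <- nrow(scheme)
  rel_sum <- matrix(0, e$n_epochs, nb)
  n_valid <- integer(e$n_epochs)
  for (start in seq(1L, n_sl, by = chunk_slices)) {
    cols <- start:min(start + chunk_slices - 1L, n_sl)
    x <- matrix(e$samples[((cols[1] - 1L) * sps + 1L):(cols[length(cols)] * sps)],
                nrow = sps)
    ok <- slice_mask_matrix(x, e$clip_min, e$clip_max)
    ok <- ok & colSums(x != 0) > 0
    if (!any(ok)) next
    psd <- multitaper_psd_matrix(x[, ok, drop = FALSE], nw, k)
    bp <- rowsum(psd[keep, , drop = FALSE], idx[keep])
    rel <- sweep(bp, 2, colSums(bp), "/")
    ep <- (cols[ok] - 1L) %/% spq + 1L
    rs <- rowsum(t(rel), ep)
    rows <- as.integer(rownames(rs))
    rel_sum[rows, ] <- rel_sum[rows, , drop = FALSE] + rs
    n_valid <- n_valid + tabulate(ep, nbins = e$n_epochs)
  }
  valid <- n_valid > 0
  rel <- rel_sum / ifelse(n_valid > 0, n_valid, NA_real_)
  colnames(rel) <- scheme$band
  list(rel = rel, valid = valid, n_valid_slices = n_valid)
}

#' Quarter-night stage-conditional qEEG features
#'
#' The 120 quarter-night qEEG features: for each quarter, sleep stage
#' (wake included) and frequency band, the mean relative band power over
#' valid epochs scored as that stage within the quarter.  Epochs marked
#' `no_score` in the hypnogram and epochs with no valid slices are
#' excluded.  Stage-by-quarter cells with no contributing epoch are `NA`
#' (downstream models impute them from training data only).
#'
#' Names follow the `band_stage_Qk` convention, e.g. `sigma_N1_Q1` is
#' sigma-band power during N1 sleep in the first quarter-night.
#'
#' @param e An [eeg_recording()] aligned to `h`.
#' @param h A [hypnogram()].
#' @param qp A [partition_quarters()] partition.
#' @param scheme A [band_scheme()].
#' @inheritParams multitaper_relative_power
#' @return Named numeric vector of length 120 (possibly with `NA`s).
#' @export
qeeg_quarter_features <- function(e, h,
                                  qp = partition_quarters(sleep_period(h)),
                                  scheme = band_scheme(), nw = 2, k = 3) {
  if (e$n_epochs < max(qp$end)) {
    qs_stop("EEG recording shorter than the hypnogram sleep period",
            "quartersleep_alignment_error")
  }
  bp <- all_epoch_band_powers(e, scheme, nw = nw, k = k)
  usable <- bp$valid & !h$no_score[seq_len(e$n_epochs)]
  st <- sleep_stages()
  out <- numeric(0)
  for (q in 1:4) {
    in_q <- seq(qp$start[q], qp$end[q])
    for (s in st) {
      sel <- in_q[h$labels[in_q] == s & usable[in_q]]
      v <- if (length(sel) > 0) {
        colMeans(bp$rel[sel, , drop = FALSE])
      } else {
        rep(NA_real_, nrow(scheme))
      }
      names(v) <- paste0(scheme$band, "_", s, "_Q", q)
      out <- c(out, v)
    }
  }
  out
}
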