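#' Group profiles for the synthetic cohort generator
#'
#' A group profile parameterises the generator for one diagnostic group:
#' the initial stage distribution, four quarter-specific 5x5 row-stochastic
#' transition matrices, the REM-onset latency distribution (gamma, with a
#' mean scale in minutes), a stage-by-band EEG spectral weight table, the
#' hypnodensity concentration (sharpness of per-epoch stage probabilities)
#' and an age distribution.
#'
#' The default profiles encode the group contrasts the generator is meant
#' to emulate: narcolepsy type 1 (NT1) has a short REM latency scale
#' (30 min), elevated off-diagonal transition mass (fragmented sleep, high
#' stage shift index), transition mass into N1 that grows from the first
#' to the last quarter, and low hypnodensity concentration (mixed states);
#' NT2 is intermediate; idiopathic hypersomnia (IH) and clinical controls
#' have long REM latency (90 min), stable stage-sticky architecture and
#' sharp hypnodensities.  Age distributions follow the cohort means and
#' SDs of the four groups (NT1 37.0 +/- 14.5 y, NT2 30.0 +/- 10.8 y,
#' IH 30.3 +/- 10.6 y, controls 34.4 +/- 12.0 y).
#'
#' @param group Group label.
#' @param init Initial stage distribution (length 5, sums to 1).
#' @param trans List of four 5x5 row-stochastic matrices (one per quarter
#'   of the recording).
#' @param rem_latency_scale Mean of the REM-onset latency distribution,
#'   minutes.
#' @param rem_latency_shape Gamma shape of the latency distribution.
#' @param band_weights 5x6 stage-by-band relative spectral weight matrix
#'   (rows sum to 1).
#' @param concentration Dirichlet concentration of the generated
#'   hypnodensity on the true stage (> 0; higher = closer to one-hot).
#' @param age_mean,age_sd Age distribution parameters, years.
#' @param subject_kappa Dirichlet concentration governing between-subject
#'   variation around the group's transition rows (and, scaled up 3x, its
#'   band-weight rows) when subjects are drawn with [generate_subject()].
#'   Smaller values give a more heterogeneous group; `Inf` disables
#'   jitter.  The profile itself is always the population mean.
#' @param conc_sdlog Log-normal SD of per-subject hypnodensity
#'   concentration around the group value.
#' @param inst_sdlog Log-normal SD of a per-subject instability
#'   multiplier applied to the off-diagonal transition mass, emulating
#'   the broad between-subject spread of sleep fragmentation seen in
#'   clinical cohorts.
#' @return Object of class `"group_profile"`.
#' @export
group_profile <- function(group, init, trans, rem_latency_scale,
                          rem_latency_shape = 4, band_weights,
                          concentration, age_mean, age_sd,
                          subject_kappa = 30, conc_sdlog = 0.4,
                          inst_sdlog = 0.5) {
  st <- sleep_stages()
  stopifnot(length(init) == 5, abs(sum(init) - 1) < 1e-9,
            length(trans) == 4, rem_latency_scale > 0,
            concentration > 0)
  for (m in trans) {
    stopifnot(is.matrix(m), all(dim(m) == c(5, 5)), all(m >= 0),
              all(abs(rowSums(m) - 1) < 1e-9))
  }
  stopifnot(is.matrix(band_weights), all(dim(band_weights) == c(5, 6)),
            all(abs(rowSums(band_weights) - 1) < 1e-9))
  trans <- lapply(trans, function(m) {
    dimnames(m) <- list(st, st); m
  })
  names(init) <- st
  rownames(band_weights) <- st
  structure(list(group = group, init = init, trans = trans,
                 rem_latency_scale = rem_latency_scale,
                 rem_latency_shape = rem_latency_shape,
                 band_weights = band_weights,
                 concentration = concentration,
                 age_mean = age_mean, age_sd = age_sd,
                 subject_kappa = subject_kappa,
                 conc_sdlog = conc_sdlog,
                 inst_sdlog = inst_sdlog),
            class = "group_profile")
}

# Draw one row from Dirichlet(kappa * p); structural zeros stay zero.
rdirichlet_row <- function(p, kappa) {
  g <- numeric(length(p))
  nz <- p > 0
  g[nz] <- stats::rgamma(sum(nz), shape = kappa * p[nz])
  g / sum(g)
}

# Individualise a group profile: jitter transition and band-weight rows
# around the group means and draw a subject-level hypnodensity
# concentration.  Gives realistic between-subject overlap of feature
# distributions within and across groups.
sample_subject_profile <- function(profile) {
  if (!is.finite(profile$subject_kappa)) return(profile)
  out <- profile
  inst <- stats::rlnorm(1, 0, profile$inst_sdlog)
  out$trans <- lapply(profile$trans, function(m) {
    for (r in seq_len(nrow(m))) {
      off <- m[r, -r] * inst
      if (sum(off) > 0.9) off <- off * 0.9 / sum(off)
      m[r, -r] <- off
      m[r, r] <- 1 - sum(off)
      m[r, ] <- rdirichlet_row(m[r, ], profile$subject_kappa)
    }
    m
  })
  for (r in seq_len(nrow(out$band_weights))) {
    out$band_weights[r, ] <- rdirichlet_row(profile$band_weights[r, ],
                                            3 * profile$subject_kappa)
  }
  out$concentration <- stats::rlnorm(1, log(profile$concentration),
                                     profile$conc_sdlog)
  out
}

# Move `delta` transition mass into the `to` column from each row's
# diagonal (rows other than `to` itself), keeping rows stochastic.
shift_mass_to <- function(m, to, delta) {
  for (r in setdiff(seq_len(nrow(m)), to)) {
    d <- min(delta, m[r, r])
    m[r, r] <- m[r, r] - d
    m[r, to] <- m[r, to] + d
  }
  m
}

stage_band_weights <- function(variant = c("typical", "nt1")) {
  variant <- match.arg(variant)
  w <- rbind(
    W  = c(0.15, 0.15, 0.35, 0.10, 0.15, 0.10),
    N1 = c(0.25, 0.35, 0.15, 0.10, 0.10, 0.05),
    N2 = c(0.35, 0.25, 0.10, 0.20, 0.07, 0.03),
    N3 = c(0.70, 0.15, 0.05, 0.05, 0.03, 0.02),
    R  = c(0.25, 0.30, 0.15, 0.08, 0.15, 0.07))
  if (variant == "nt1") {
    # slightly drowsier wake and N1: theta up, alpha down
    w["W", ] <- c(0.155, 0.175, 0.325, 0.100, 0.145, 0.100)
    w["N1", ] <- c(0.255, 0.365, 0.135, 0.095, 0.095, 0.055)
  }
  colnames(w) <- band_scheme()$band
  w
}

#' @rdname group_profile
#' @export
default_profiles <- function() {
  st <- sleep_stages()
  base <- matrix(c(
    # W     N1     N2     N3     R
    0.88, 0.090, 0.030, 0.000, 0.000,   # from W
    0.05, 0.720, 0.210, 0.000, 0.020,   # from N1
    0.02, 0.030, 0.895, 0.045, 0.010,   # from N2
    0.01, 0.005, 0.065, 0.920, 0.000,   # from N3
    0.03, 0.020, 0.020, 0.000, 0.930),  # from R
    nrow = 5, byrow = TRUE, dimnames = list(st, st))
  # controls/IH: deeper sleep early, progressively easier REM access
  # (the REM-latency suppression window, ~90 min on average, is what
  # keeps their early night REM-free; once it has elapsed normal cycling
  # produces REM, so first-quarter REM content overlaps with patients)
  ctrl_q <- lapply(1:4, function(q) {
    m <- shift_mass_to(base, 5L, 0.01)             # baseline REM access
    if (q <= 2) m <- shift_mass_to(m, 4L, 0.01)    # extra N3 early
    if (q >= 3) m <- shift_mass_to(m, 5L, 0.01)    # extra REM late
    m
  })
  unstable <- matrix(c(
    0.80, 0.140, 0.040, 0.000, 0.020,
    0.12, 0.600, 0.200, 0.000, 0.080,
    0.06, 0.090, 0.770, 0.030, 0.050,
    0.03, 0.020, 0.100, 0.850, 0.000,
    0.08, 0.060, 0.040, 0.000, 0.820),
    nrow = 5, byrow = TRUE, dimnames = list(st, st))
  # NT1: moderately elevated instability (the group mean shift is small
  # relative to between-subject spread, as in clinical cohorts) plus N1
  # mass rising from Q1 to Q4
  nt1_m <- 0.35 * unstable + 0.65 * base
  nt1_q <- lapply(1:4, function(q) {
    shift_mass_to(nt1_m, 2L, 0.015 * (q - 1))
  })
  mid_m <- 0.2 * unstable + 0.8 * base
  mid_q <- lapply(1:4, function(q) {
    shift_mass_to(mid_m, 2L, 0.0075 * (q - 1))
  })
  init_sleepy <- c(W = 0.10, N1 = 0.35, N2 = 0.50, N3 = 0.05, R = 0)
  init_ctrl <- c(W = 0.20, N1 = 0.30, N2 = 0.45, N3 = 0.05, R = 0)
  bw <- stage_band_weights()
  list(
    NT1 = group_profile("NT1", init_sleepy, nt1_q,
                        rem_latency_scale = 30,
                        band_weights = stage_band_weights("nt1"),
                        concentration = 5.5, age_mean = 37.0, age_sd = 14.5),
    NT2 = group_profile("NT2", init_sleepy, mid_q,
                        rem_latency_scale = 45, band_weights = bw,
                        concentration = 6, age_mean = 30.0, age_sd = 10.8),
    IH = group_profile("IH", init_sleepy, ctrl_q,
                       rem_latency_scale = 90, band_weights = bw,
                       concentration = 7, age_mean = 30.3, age_sd = 10.6),
    control = group_profile("control", init_ctrl, ctrl_q,
                            rem_latency_scale = 90, band_weights = bw,
                            concentration = 7, age_mean = 34.4, age_sd = 12.0)
  )
}

#' Generate a synthetic hypnogram
#'
#' Simulates a night of sleep as a time-inhomogeneous Markov chain over
#' the five stages, using the profile's quarter-specific transition
#' matrices (quarters of the full recording).  REM is suppressed (its
#' column zeroed and rows renormalised) until the subject's sampled
#' REM-onset latency has elapsed, emulating the REM-latency distribution
#' of the group.
#'
#' @param profile A [group_profile()].
#' @param n_epochs Number of 30-s epochs (default 960, an 8-h recording).
#' @param seed Optional integer seed (the surrounding RNG state is used
#'   when `NULL`).
#' @param rem_latency_minutes Optional fixed REM-onset latency; sampled
#'   from the profile's gamma distribution when `NULL`.
#' @return A [hypnogram()] with attributes `rem_latency_minutes` and
#'   `group`.
#' @export
generate_hypnogram <- function(profile, n_epochs = 960, seed = NULL,
                               rem_latency_minutes = NULL) {
  stopifnot(n_epochs >= 40)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rem_latency_minutes)) {
    rem_latency_minutes <- stats::rgamma(
      1, shape = profile$rem_latency_shape,
      rate = profile$rem_latency_shape / profile$rem_latency_scale)
  }
  lat_epochs <- round(rem_latency_minutes * 2)
  qlen <- ceiling(n_epochs / 4)
  labels <- integer(n_epochs)
  p0 <- profile$init
  if (lat_epochs >= 1) p0 <- zero_rem(p0)
  labels[1] <- sample.int(5, 1, prob = p0)
  seen_rem <- labels[1] == 5L
  for (i in 2:n_epochs) {
    q <- min((i - 1) %/% qlen + 1, 4)
    row <- profile$trans[[q]][labels[i - 1], ]
    if (i <= lat_epochs) {
      row <- zero_rem(row)
    } else if (lat_epochs >= 1 && !seen_rem && labels[i - 1] != 1L) {
      # accumulated REM pressure: once the latency window has elapsed,
      # gate the first REM entry up (from sleep, not wake) so realised
      # latency tracks the sampled value instead of the chain's
      # baseline REM accessibility
      row <- boost_rem(row, 0.12)
    }
    labels[i] <- sample.int(5, 1, prob = row)
    if (labels[i] == 5L) seen_rem <- TRUE
  }
  h <- hypnogram(sleep_stages()[labels])
  attr(h, "rem_latency_minutes") <- rem_latency_minutes
  attr(h, "group") <- profile$group
  h
}

zero_rem <- function(p) {
  p[5] <- 0
  if (sum(p) == 0) p[3] <- 1  # degenerate row: fall back to N2
  p / sum(p)
}

boost_rem <- function(p, floor_p) {
  if (p[5] >= floor_p) return(p)
  p[-5] <- p[-5] * (1 - floor_p) / sum(p[-5])
  p[5] <- floor_p
  p
}

#' Generate stage-dependent synthetic EEG for a hypnogram
#'
#' Each epoch's signal is coloured Gaussian noise whose spectrum is shaped
#' by the profile's stage-dependent band weights (e.g. N3 delta-heavy),
#' built by shaping white noise in the frequency domain.  Optionally
#' injects flat-line artifacts into a fraction of 2-s slices so artifact
#' rejection can be exercised.
#'
#' @param h A [hypnogram()].
#' @param profile A [group_profile()] supplying the band weights.
#' @param rate Sampling rate, samples/s (default 128).
#' @param seed Optional integer seed.
#' @param amplitude RMS scale of the signal, microvolts.
#' @param artifact_rate Probability that a 2-s slice receives an injected
#'   flat-line artifact (default 0).
#' @param clip_limits Recorder saturation limits passed to
#'   [eeg_recording()].
#' @return An [eeg_recording()] aligned to `h`.
#' @export
generate_eeg <- function(h, profile, rate = 128, seed = NULL,
                         amplitude = 30, artifact_rate = 0,
                         clip_limits = c(-250, 250)) {
  if (!is.null(seed)) set.seed(seed)
  scheme <- band_scheme()
  n <- as.integer(round(rate * h$epoch_seconds))
  idx <- band_bin_index(n, rate, scheme)
  # per-stage amplitude mask over rfft bins: power w_b spread over the
  # band's bins; mirror onto negative frequencies
  nf <- n %/% 2 + 1
  masks <- lapply(sleep_stages(), function(s) {
    w <- profile$band_weights[s, ]
    a <- numeric(nf)
    for (b in seq_len(nrow(scheme))) {
      bins <- which(idx == b)
      a[bins] <- sqrt(w[b] / length(bins))
    }
    full <- numeric(n)
    full[seq_len(nf)] <- a
    if (n %% 2 == 0) full[n:(nf + 1)] <- a[2:(nf - 1)]
    else full[n:(nf + 1)] <- a[2:nf]
    full
  })
  names(masks) <- sleep_stages()
  samples <- numeric(n_epochs(h) * n)
  for (i in seq_len(n_epochs(h))) {
    z <- stats::fft(stats::rnorm(n))
    x <- Re(stats::fft(z * masks[[h$labels[i]]], inverse = TRUE)) / sqrt(n)
    samples[((i - 1) * n + 1):(i * n)] <- x * amplitude
  }
  if (artifact_rate > 0) {
    sps <- as.integer(round(rate * 2))
    n_slices <- length(samples) %/% sps
    hit <- which(stats::runif(n_slices) < artifact_rate)
    for (s in hit) {
      at <- (s - 1) * sps + sample.int(sps - 6, 1)
      samples[at:(at + 5)] <- samples[at]
    }
  }
  eeg_recording(samples, rate, h$epoch_seconds,
                clip_min = clip_limits[1], clip_max = clip_limits[2])
}

#' Generate a synthetic hypnodensity for a hypnogram
#'
#' Draws each epoch's stage-probability row from a Dirichlet distribution
#' centred on the true stage: the true stage gets concentration
#' `concentration`, all stages a baseline of 0.4.  Low concentration
#' produces the diffuse, mixed-state rows typical of unstable sleep;
#' as concentration grows the rows approach one-hot.
#'
#' @param h A [hypnogram()].
#' @param concentration Dirichlet concentration on the true stage (> 0).
#' @param seed Optional integer seed.
#' @param epoch_seconds 15 (two rows per 30-s hypnogram epoch, the native
#'   resolution of probabilistic staging models) or 30.
#' @return A [hypnodensity()].
#' @export
generate_hypnodensity <- function(h, concentration = 6, seed = NULL,
                                  epoch_seconds = 15) {
  if (!is.null(seed)) set.seed(seed)
  rows_per_epoch <- if (epoch_seconds == 15) 2L else 1L
  stage_idx <- rep(match(h$labels, sleep_stages()), each = rows_per_epoch)
  n <- length(stage_idx)
  alpha <- matrix(0.4, n, 5)
  alpha[cbind(seq_len(n), stage_idx)] <- alpha[cbind(seq_len(n), stage_idx)] +
    concentration
  g <- matrix(stats::rgamma(n * 5, shape = as.vector(alpha)), n, 5)
  p <- g / rowSums(g)
  hypnodensity(p, epoch_seconds)
}

#' Generate one synthetic subject
#'
#' Draws a subject-level profile around the group profile (Dirichlet
#' jitter of transition and band-weight rows, log-normal jitter of the
#' hypnodensity concentration; see `subject_kappa` in [group_profile()]),
#' then generates the hypnogram and optional EEG and hypnodensity from
#' it.  The jitter gives groups realistic within-group spread so feature
#' distributions overlap across groups instead of separating perfectly.
#'
#' @param id Subject identifier.
#' @param profile A [group_profile()].
#' @param n_epochs Night length in 30-s epochs.
#' @param rate EEG sampling rate (samples/s).
#' @param seed Integer seed; the full record is reproducible from it.
#' @param components Which optional signals to generate, a subset of
#'   `c("eeg", "hypnodensity")`.
#' @param age Optional fixed age; sampled from the profile when `NULL`.
#' @return Object of class `"subject_record"`: list with `id`, `group`,
#'   `age`, `hypnogram`, and optionally `eeg` and `hypnodensity` (15-s).
#' @export
generate_subject <- function(id, profile, n_epochs = 960, rate = 128,
                             seed = NULL,
                             components = c("eeg", "hypnodensity"),
                             age = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(age)) {
    age <- max(18, round(stats::rnorm(1, profile$age_mean, profile$age_sd)))
  }
  subj <- sample_subject_profile(profile)
  h <- generate_hypnogram(subj, n_epochs)
  rec <- list(id = id, group = profile$group, age = age, hypnogram = h)
  if ("eeg" %in% components) {
    rec$eeg <- generate_eeg(h, subj, rate)
  }
  if ("hypnodensity" %in% components) {
    rec$hypnodensity <- generate_hypnodensity(h, subj$concentration)
  }
  structure(rec, class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s, age %g): %d epochs%s%s\n",
              x$id, x$group, x$age, n_epochs(x$hypnogram),
              if (!is.null(x$eeg)) ", EEG" else "",
              if (!is.null(x$hypnodensity)) ", hypnodensity" else ""))
  invisible(x)
}

#' Cohort configuration
#'
#' @param n Named integer vector of subjects per group.  The default
#'   mirrors the 114:90:105:41 NT1:NT2:IH:control imbalance of a clinical
#'   referral cohort, scaled down by a factor of 5.
#' @param n_epochs,rate,components Passed to [generate_subject()].
#' @param profiles Named list of [group_profile()]s.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n = c(NT1 = 23, NT2 = 18, IH = 21, control = 8),
                          n_epochs = 960, rate = 128,
                          components = c("eeg", "hypnodensity"),
                          profiles = default_profiles()) {
  stopifnot(all(names(n) %in% names(profiles)), all(n >= 0))
  structure(list(n = n, n_epochs = n_epochs, rate = rate,
                 components = components, profiles = profiles),
            class = "cohort_config")
}

#' Generate a labelled synthetic cohort
#'
#' Generates `sum(config$n)` subject records plus a manifest recording
#' each subject's id, group, age and per-subject seed.  The cohort is
#' fully reproducible from `(config, seed)`, and any single subject can be
#' regenerated bit-identically from its manifest row via
#' [generate_subject()].
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return List of class `"cohort"` with elements `subjects` (list of
#'   [generate_subject()] records) and `manifest` (data frame).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  groups <- rep(names(config$n), config$n)
  n_total <- length(groups)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  ids <- sprintf("S%03d", seq_len(n_total))
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    subjects[[i]] <- generate_subject(
      ids[i], config$profiles[[groups[i]]],
      n_epochs = config$n_epochs, rate = config$rate,
      seed = subj_seeds[i], components = config$components)
  }
  manifest <- data.frame(
    subject_id = ids, group = groups,
    age = vapply(subjects, function(s) s$age, numeric(1)),
    seed = subj_seeds)
  structure(list(subjects = subjects, manifest = manifest,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects\n", nrow(x$manifest)))
  print(table(x$manifest$group))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `manifest.csv`, one hypnogram CSV and one hypnodensity CSV per
#' subject (plain text), and one `.rds` per EEG recording (samples are too
#' large for text formats).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    hg <- data.frame(epoch_index = seq_len(n_epochs(s$hypnogram)),
                     stage = s$hypnogram$labels)
    utils::write.csv(hg, file.path(dir, paste0(s$id, "_hypnogram.csv")),
                     row.names = FALSE)
    if (!is.null(s$hypnodensity)) {
      hd <- as.data.frame(s$hypnodensity$p)
      utils::write.csv(hd, file.path(dir, paste0(s$id, "_hypnodensity.csv")),
                       row.names = FALSE)
    }
    if (!is.null(s$eeg)) {
      saveRDS(s$eeg, file.path(dir, paste0(s$id, "_eeg.rds")))
    }
  }
  invisible(dir)
}
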