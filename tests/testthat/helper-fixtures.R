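# Small fixtures built in code.

write_hypnogram_csv <- function(labels, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(epoch_index = seq_along(labels),
                              stage = labels),
                   path, row.names = FALSE)
  path
}

tone <- function(freq, rate = 128, seconds = 2, amplitude = 1) {
  amplitude * sin(2 * pi * freq * seq(0, seconds, by = 1 / rate)[-1])
}

# EEG recording whose every epoch is the same 10 Hz tone (plus tiny noise
# to avoid accidental flat-lines), aligned to `n_ep` epochs.
tone_eeg <- function(freq = 10, n_ep = 4, rate = 128, amplitude = 50) {
  x <- rep(tone(freq, rate, 30, amplitude), n_ep)
  x <- x + stats::rnorm(length(x), sd = amplitude * 1e-4)
  eeg_recording(x, rate, clip_min = -1e4, clip_max = 1e4)
}

# Toy two-group feature table: `k_noise` N(0,1) noise features plus one
# feature separated by `delta` between groups.
toy_table <- function(n_pos = 20, n_neg = 20, k_noise = 5, delta = 3,
                      seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  grp <- c(rep("NT1", n_pos), rep("control", n_neg))
  tab <- data.frame(subject_id = sprintf("T%03d", 1:n), group = grp,
                    age = round(stats::runif(n, 20, 60)),
                    rem_missing = FALSE)
  for (j in seq_len(k_noise)) {
    tab[[paste0("noise", j)]] <- stats::rnorm(n)
  }
  tab$signal <- stats::rnorm(n) + ifelse(grp == "NT1", delta, 0)
  tab
}
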