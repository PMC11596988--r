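# Brute-force reference implementations written directly from the
# definitions, independent of the package internals.  Used to verify the
# extractors on random hypnograms.

oracle_onset <- function(labels, min_epochs = 10) {
  n <- length(labels)
  for (i in seq_len(n - min_epochs + 1)) {
    if (all(labels[i:(i + min_epochs - 1)] != "W")) return(i)
  }
  NA_integer_
}

oracle_period <- function(labels, min_epochs = 10) {
  onset <- oracle_onset(labels, min_epochs)
  if (is.na(onset)) return(NULL)
  end <- max(which(labels != "W"))
  c(onset = onset, end = end)
}

oracle_metrics <- function(labels, onset, end) {
  lab <- labels[onset:end]
  n <- length(lab)
  props <- vapply(c("W", "N1", "N2", "N3", "R"),
                  function(s) sum(lab == s) / n, numeric(1))
  tst <- sum(lab != "W") * 0.5
  changes <- 0
  for (i in seq_len(n - 1)) if (lab[i] != lab[i + 1]) changes <- changes + 1
  ssi <- changes / (n * 30 / 3600)
  first_r <- NA_integer_
  for (i in seq_len(n)) if (lab[i] == "R") { first_r <- i; break }
  rem <- if (is.na(first_r)) n * 0.5 else (first_r - 1) * 0.5
  c(props, TST = tst, SSI = ssi, REMonSet = rem)
}

oracle_transition_counts <- function(labels, from_idx, to_idx) {
  st <- c("W", "N1", "N2", "N3", "R")
  m <- matrix(0, 5, 5, dimnames = list(st, st))
  for (i in from_idx:(to_idx - 1)) {
    m[labels[i], labels[i + 1]] <- m[labels[i], labels[i + 1]] + 1
  }
  m
}

oracle_transition_probs <- function(labels, from_idx, to_idx) {
  m <- oracle_transition_counts(labels, from_idx, to_idx)
  for (r in 1:5) if (sum(m[r, ]) > 0) m[r, ] <- m[r, ] / sum(m[r, ])
  m
}

random_labels <- function(n, p_w = 0.25) {
  sample(c("W", "N1", "N2", "N3", "R"), n, replace = TRUE,
         prob = c(p_w, rep((1 - p_w) / 4, 4)))
}
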