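# Shared fixtures and independent oracles, built in code.

# rr_series from intervals alone (times = cumulative sum, as the readers do)
make_rr <- function(intervals, labels = rep("normal", length(intervals)),
                    id = "test") {
  rr_series(id, cumsum(intervals) / 1000, intervals, labels)
}

# nn_series constructed directly, bypassing the filter, for PRSA unit tests
make_nn <- function(intervals, gaps = rep(FALSE, length(intervals))) {
  structure(list(patient_id = "test",
                 times = cumsum(intervals) / 1000,
                 intervals = intervals,
                 gap_flags = gaps),
            class = "nn_series")
}

# beat series whose intervals follow NN(t) at its own beat times
make_signal_rr <- function(duration, f, base = 800) {
  t <- 0; tt <- rr <- numeric(0)
  repeat {
    r <- f(t)
    t <- t + r / 1000
    if (t > duration) break
    tt <- c(tt, t); rr <- c(rr, r)
  }
  rr_series("signal", tt, rr)
}

# Brute-force PRSA oracle: direct enumeration, no vectorized tricks.
oracle_anchors <- function(x, gaps, mri = 0.05, L = 2L) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i < 2) next
    if (!(x[i] > x[i - 1])) next
    if (x[i] > (1 + mri) * x[i - 1]) next
    if (gaps[i] || gaps[i - 1]) next
    if (i - L < 1 || i + L - 1 > n) next
    win_ok <- TRUE
    for (j in (i - L + 1):(i + L - 1)) if (gaps[j]) win_ok <- FALSE
    if (win_ok) out <- c(out, i)
  }
  out
}

oracle_profile <- function(x, anchors, L = 2L) {
  ks <- (-L):(L - 1L)
  X <- numeric(length(ks))
  for (m in seq_along(ks)) {
    s <- 0
    for (a in anchors) s <- s + x[a + ks[m]]
    X[m] <- s / length(anchors)
  }
  names(X) <- as.character(ks)
  X
}

# trapezoidal ROC area oracle
oracle_trapezoid_auc <- function(score, outcome) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[outcome == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[outcome == 0] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
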