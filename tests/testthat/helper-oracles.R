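# Independent oracles and shared fixtures for the test suite.

# Brute-force feature oracle: deliberately written sample-by-sample with
# plain loops/primitives, independent of the package's vectorized path.
oracle_features <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  if (v > 0) {
    sk <- (sum((x - m)^3) / n) / sqrt(v)^3
    ku <- (sum((x - m)^4) / n) / v^2 - 3
  } else {
    sk <- 0
    ku <- 0
  }
  wl <- 0
  for (i in 2:n) wl <- wl + abs(x[i] - x[i - 1])
  c(MEAN = m, VAR = v, SKEW = sk, KUR = ku,
    MAV = sum(abs(x)) / n, WL = wl,
    MAX = max(x), AMP = max(x) - min(x), POW = sum(x^2) / n)
}

# Brute-force window-count oracle: walk the signal start by start.
oracle_window_count <- function(L, w, o) {
  step <- w - o
  count <- 0L
  s <- 1L
  while (s + w - 1L <= L) {
    count <- count + 1L
    s <- s + step
  }
  count
}

# Analytic magnitude response of the bilinear-transform Butterworth
# band-pass at frequency f (Hz): analog prototype formula evaluated at
# prewarped frequencies, exact for the digital design.
oracle_butter_gain <- function(f, f_lo, f_hi, fs, order) {
  warp <- function(fr) 2 * fs * tan(pi * fr / fs)
  W <- warp(f)
  W1 <- warp(f_lo)
  W2 <- warp(f_hi)
  B <- W2 - W1
  W0sq <- W1 * W2
  1 / sqrt(1 + ((W^2 - W0sq) / (W * B))^(2 * order))
}

# Brute-force balanced accuracy: explicit per-class recall loop.
oracle_ba <- function(cm) {
  rec <- numeric(nrow(cm))
  for (i in seq_len(nrow(cm))) rec[i] <- cm[i, i] / sum(cm[i, ])
  sum(rec) / length(rec)
}

# Small synthetic session shared by several tests: 6 channels (1 dead),
# short segments, full-rate sampling.
small_session <- function(seed = 101L, segment_s = 8, n_channels = 6L,
                          n_dead = 1L,
                          rates = c(baseline = 10, full = 40, micturition = 90),
                          amps = c(baseline = 8, full = 10, micturition = 12)) {
  generate_session(synth_config(
    n_channels = n_channels, n_dead_channels = n_dead,
    segment_duration_s = segment_s,
    state_rates = rates, state_amplitudes = amps,
    physio = FALSE, seed = seed
  ))
}

# Feature table from a small preprocessed session (timeline order).
small_table <- function(session = small_session(),
                        length_s = 0.3, overlap_s = 0.06) {
  sf <- preprocess_session(session)
  make_table_for_tests(sf, length_s, overlap_s)
}

make_table_for_tests <- function(sf, length_s, overlap_s) {
  # window the full labeled timeline (no holdout split) for CV tests
  tb <- featurize_session(sf, window_spec(length_s, overlap_s),
                          test_fraction = 0.02)
  # use the train side only; the tiny test slice is discarded
  tb$train
}

# Feature table whose classes differ only in window variance: two-point
# magnitude distributions with random signs, matched in mean absolute value
# (1) and kurtosis (2.5), variances 1.15 / 1.5 / 2.0; one +3 and one -3
# planted per window pin MAX and AMP, and sorting the samples makes the
# waveform length equal the range. Only VAR and POW retain class contrast.
variance_only_table <- function(n_channels = 4L, windows_per_class = 60L,
                                n_samples = 300L, seed = 7L) {
  pars <- list(
    baseline    = c(p = 0.951938, a = 0.912975, b = 2.723644),
    full        = c(p = 0.694752, a = 0.531299, b = 2.066778),
    micturition = c(p = 0.609638, a = 0.199801, b = 2.249689)
  )
  set.seed(seed)
  labels <- rep(names(pars), each = windows_per_class)
  per_channel <- lapply(seq_len(n_channels), function(ch) {
    feats <- matrix(0, length(labels), 9L)
    for (i in seq_along(labels)) {
      pp <- pars[[labels[i]]]
      mag <- ifelse(stats::runif(n_samples) < pp["p"], pp["a"], pp["b"])
      x <- sort(c(mag * sample(c(-1, 1), n_samples, replace = TRUE), -3, 3))
      feats[i, ] <- extract_features(x)
    }
    colnames(feats) <- c("MEAN", "VAR", "SKEW", "KUR", "MAV", "WL",
                         "MAX", "AMP", "POW")
    feats
  })
  assemble_table(per_channel, labels)
}
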