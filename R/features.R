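# Time windowing, nine-feature extraction, table assembly, standardization.

FEATURE_NAMES <- c("MEAN", "VAR", "SKEW", "KUR", "MAV", "WL", "MAX", "AMP", "POW")
STATE_LEVELS <- c("baseline", "full", "micturition")

#' Time-window specification
#'
#' Defaults follow the operating point used throughout the pipeline: 0.55 s
#' windows with 0.11 s (20%) overlap for training data; test data are
#' windowed with the same length and no overlap.
#'
#' @param length_s Window length in seconds.
#' @param overlap_s Overlap between contiguous training windows in seconds.
#' @param test_overlap_s Overlap for test windows (fixed 0 by convention).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length_s = 0.55, overlap_s = 0.11,
                        test_overlap_s = 0) {
  stopifnot(length_s > 0, overlap_s >= 0, overlap_s < length_s,
            test_overlap_s >= 0, test_overlap_s < length_s)
  structure(list(length_s = length_s, overlap_s = overlap_s,
                 test_overlap_s = test_overlap_s),
            class = "window_spec")
}

# Start indices (1-based) of sliding windows of `w` samples with overlap `o`
# over `n` samples; the trailing remainder is discarded.
window_starts <- function(n, w, o) {
  if (w > n) return(integer(0))
  step <- w - o
  seq.int(1L, n - w + 1L, by = step)
}

#' Slice a signal into equal-length overlapping windows
#'
#' Windows are `length_s * fs` (rounded) samples long, advance by
#' `length - overlap` samples, and the trailing remainder that cannot fill a
#' complete window is discarded. The number of windows equals
#' `floor((L - w) / (w - o)) + 1` in samples.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param length_s Window length in seconds.
#' @param overlap_s Overlap between contiguous windows in seconds.
#' @return List of numeric windows (possibly empty, with a warning, when the
#'   segment is shorter than one window).
#' @export
make_windows <- function(x, fs, length_s, overlap_s = 0) {
  stopifnot(fs > 0, length_s > 0, overlap_s >= 0, overlap_s < length_s)
  w <- round(length_s * fs)
  if (w < 2L) stop("window must span at least 2 samples", call. = FALSE)
  o <- round(overlap_s * fs)
  starts <- window_starts(length(x), w, o)
  if (length(starts) == 0L) {
    warning("segment shorter than one window; no windows produced",
            call. = FALSE)
    return(list())
  }
  lapply(starts, function(s) x[s:(s + w - 1L)])
}

#' Extract the nine per-window features
#'
#' Computes the handcrafted feature set used to summarize each time window
#' of each channel: `MEAN` (arithmetic mean), `VAR` (population variance),
#' `SKEW` (third standardized moment), `KUR` (excess kurtosis, fourth
#' standardized moment minus 3), `MAV` (mean absolute value), `WL` (waveform
#' length, the summed absolute sample-to-sample differences), `MAX`
#' (maximum), `AMP` (peak-to-peak amplitude, max minus min), and `POW`
#' (mean squared sample). Zero-variance windows (e.g. a flat dead channel)
#' take `SKEW = KUR = 0` so the table stays finite.
#'
#' @param x Numeric window of at least 2 samples.
#' @return Named numeric vector of length 9.
#' @export
extract_features <- function(x) {
  if (length(x) < 2L) stop("window must have at least 2 samples", call. = FALSE)
  m <- mean(x)
  xc <- x - m
  v <- mean(xc^2)
  if (v > 0) {
    skew <- mean(xc^3) / v^1.5
    kur <- mean(xc^4) / v^2 - 3
  } else {
    skew <- 0
    kur <- 0
  }
  c(MEAN = m, VAR = v, SKEW = skew, KUR = kur,
    MAV = mean(abs(x)), WL = sum(abs(diff(x))),
    MAX = max(x), AMP = max(x) - min(x), POW = mean(x^2))
}

# Vectorized feature extraction: all windows of one channel at once.
# `starts` are 1-based window starts, `w` the window width in samples.
# Returns an n_windows x 9 matrix.
extract_features_matrix <- function(x, starts, w) {
  nw <- length(starts)
  if (nw == 0L) {
    return(matrix(numeric(0), ncol = 9L,
                  dimnames = list(NULL, FEATURE_NAMES)))
  }
  idx <- rep(starts, each = w) + (0:(w - 1L))
  M <- matrix(x[idx], nrow = w)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = w)
  v <- colMeans(Mc^2)
  skew <- ifelse(v > 0, colMeans(Mc^3) / v^1.5, 0)
  kur <- ifelse(v > 0, colMeans(Mc^4) / v^2 - 3, 0)
  mav <- colMeans(abs(M))
  wl <- colSums(abs(M[-1L, , drop = FALSE] - M[-w, , drop = FALSE]))
  mx <- apply(M, 2L, max)
  mn <- apply(M, 2L, min)
  pow <- colMeans(M^2)
  out <- cbind(MEAN = mu, VAR = v, SKEW = skew, KUR = kur, MAV = mav,
               WL = wl, MAX = mx, AMP = mx - mn, POW = pow)
  out
}

#' Split a session into train and test segments on the raw timeline
#'
#' The split happens per class interval BEFORE any windowing: the final
#' `test_fraction` of each labeled interval becomes test material and the
#' initial remainder training material, so no raw sample can appear in both
#' sets and each class contributes the same fraction of its duration.
#'
#' @param session An `eng_session`.
#' @param test_fraction Test proportion of each interval (default 0.1, the
#'   1:10 test:train-plus-test ratio).
#' @return List of two data frames `train` and `test` with columns `start`,
#'   `end` (half-open sample indices) and `state`.
#' @export
split_train_test <- function(session, test_fraction = 0.1) {
  stopifnot(inherits(session, "eng_session"),
            test_fraction > 0, test_fraction < 1)
  iv <- session$intervals
  tr <- te <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    n <- iv$end[i] - iv$start[i]
    n_test <- round(n * test_fraction)
    if (n_test < 1L || n - n_test < 1L) {
      stop(sprintf("interval for class '%s' too short to split", iv$state[i]),
           call. = FALSE)
    }
    cut <- iv$start[i] + (n - n_test)
    tr <- rbind(tr, data.frame(start = iv$start[i], end = cut,
                               state = iv$state[i]))
    te <- rbind(te, data.frame(start = cut, end = iv$end[i],
                               state = iv$state[i]))
  }
  list(train = tr, test = te)
}

#' Assemble per-channel feature matrices into a feature table
#'
#' Concatenates the 9-feature blocks of all channels window-wise: row i is
#' the features of window i across channels, in channel-major /
#' feature-minor column order (`ch01_MEAN ... ch01_POW, ch02_MEAN, ...`).
#'
#' @param per_channel List of n_windows x 9 feature matrices, one per
#'   channel, all with the same window count.
#' @param labels Per-window state labels (factor or character).
#' @param split_tag `"train"` or `"test"`.
#' @param window_start,window_end Optional per-window raw-sample index
#'   bounds (half-open), used for leakage audits.
#' @param interval Optional per-window interval id.
#' @param channel_names Optional channel names (default `ch01`, `ch02`, ...).
#' @return An `eng_features` object: list with `x` (matrix), `labels`,
#'   `column_names`, `split_tag`, `scaler` (NULL until standardized), and
#'   window metadata.
#' @export
assemble_table <- function(per_channel, labels, split_tag = "train",
                           window_start = NULL, window_end = NULL,
                           interval = NULL, channel_names = NULL) {
  stopifnot(length(per_channel) >= 1L)
  counts <- vapply(per_channel, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("all channels must yield the same window count", call. = FALSE)
  }
  nw <- counts[1L]
  if (length(labels) != nw) {
    stop("`labels` length must equal the window count", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_along(per_channel))
  }
  cols <- as.vector(t(outer(channel_names, FEATURE_NAMES, paste, sep = "_")))
  x <- do.call(cbind, per_channel)
  colnames(x) <- cols
  labels <- factor(as.character(labels), levels = STATE_LEVELS)
  structure(
    list(x = x, labels = labels, column_names = cols, split_tag = split_tag,
         scaler = NULL,
         window_start = window_start, window_end = window_end,
         interval = interval, channel_names = channel_names),
    class = "eng_features"
  )
}

# Build an eng_features table from arbitrary labeled segments of a
# (preprocessed) session. Each segment is windowed independently so windows
# never straddle a state or split boundary; rows are ordered segment by
# segment, time-ordered within each.
make_table <- function(session, segments, length_s, overlap_s,
                       split_tag = "train") {
  fs <- session$fs
  w <- round(length_s * fs)
  if (w < 2L) stop("window must span at least 2 samples", call. = FALSE)
  o <- round(overlap_s * fs)
  nch <- nrow(session$signal)
  starts_all <- integer(0)
  labels <- character(0)
  interval <- integer(0)
  for (i in seq_len(nrow(segments))) {
    n <- segments$end[i] - segments$start[i]
    st <- window_starts(n, w, o)
    if (length(st)) {
      starts_all <- c(starts_all, segments$start[i] - 1L + st)
      labels <- c(labels, rep(as.character(segments$state[i]), length(st)))
      interval <- c(interval, rep(i, length(st)))
    }
  }
  per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    per_channel[[ch]] <- extract_features_matrix(session$signal[ch, ],
                                                 starts_all, w)
  }
  tab <- assemble_table(per_channel, labels, split_tag = split_tag,
                        window_start = starts_all,
                        window_end = starts_all + w,
                        interval = interval)
  tab$fs <- fs
  tab$window <- list(length_s = length_s, overlap_s = overlap_s)
  tab
}

#' Featurize a session into train and test feature tables
#'
#' End-to-end feature stage: split the timeline per class (see
#' [split_train_test()]), window the training side with the training
#' overlap, the test side with no overlap, extract the nine features per
#' window and channel, and assemble both tables. No standardization or
#' shuffling is applied here; do that with [standardize()] and
#' [shuffle_rows()], or let [nested_cv()] handle it fold-internally.
#'
#' @param session A preprocessed `eng_session`.
#' @param spec A [window_spec()].
#' @param test_fraction Test proportion per class interval.
#' @return List with `train` and `test` `eng_features` tables.
#' @export
featurize_session <- function(session, spec = window_spec(),
                              test_fraction = 0.1) {
  split <- split_train_test(session, test_fraction)
  list(
    train = make_table(session, split$train, spec$length_s, spec$overlap_s,
                       split_tag = "train"),
    test = make_table(session, split$test, spec$length_s, spec$test_overlap_s,
                      split_tag = "test")
  )
}

#' Standardize feature tables with training-set statistics
#'
#' Fits a per-column scaler (mean, standard deviation) on the training table
#' and applies `(x - mu_train) / max(sd_train, 1e-12)` to both tables; the
#' epsilon floor keeps zero-variance columns finite. The scaler is stored on
#' both outputs; re-standardizing an already-scaled table, or fitting on a
#' table tagged `"test"`, is a contract violation and errors.
#'
#' @param train Training `eng_features` (unscaled).
#' @param test Optional test `eng_features` to transform with the training
#'   scaler.
#' @return If `test` is given, list with `train` and `test`; otherwise the
#'   standardized training table.
#' @export
standardize <- function(train, test = NULL) {
  stopifnot(inherits(train, "eng_features"))
  if (!is.null(train$scaler)) {
    stop("training table is already standardized", call. = FALSE)
  }
  if (identical(train$split_tag, "test")) {
    stop("scaler must be fitted on a training table, not a test table",
         call. = FALSE)
  }
  mu <- colMeans(train$x)
  sd_ <- sqrt(colMeans(sweep(train$x, 2L, mu)^2))
  denom <- pmax(sd_, 1e-12)
  scaler <- list(mean = mu, sd = sd_, fitted_on = "train")
  train$x <- sweep(sweep(train$x, 2L, mu), 2L, denom, "/")
  train$scaler <- scaler
  if (is.null(test)) return(train)
  stopifnot(inherits(test, "eng_features"))
  test$x <- sweep(sweep(test$x, 2L, mu), 2L, denom, "/")
  test$scaler <- scaler
  list(train = train, test = test)
}

#' Shuffle the rows of a feature table
#'
#' Applies a seeded random permutation to the rows, keeping labels and
#' window metadata aligned. Used to break the temporal clustering of
#' consecutive windows before model fitting.
#'
#' @param table An `eng_features`.
#' @param seed Integer seed.
#' @return The permuted table (permutation stored as `shuffle_perm`).
#' @export
shuffle_rows <- function(table, seed = 1L) {
  stopifnot(inherits(table, "eng_features"))
  n <- nrow(table$x)
  perm <- with_seed(seed, sample.int(n))
  table$x <- table$x[perm, , drop = FALSE]
  table$labels <- table$labels[perm]
  for (f in c("window_start", "window_end", "interval")) {
    if (!is.null(table[[f]])) table[[f]] <- table[[f]][perm]
  }
  table$shuffle_perm <- perm
  table
}

#' @export
print.eng_features <- function(x, ...) {
  cat("<eng_features> ", nrow(x$x), " windows x ", ncol(x$x), " columns (",
      length(x$channel_names), " channels x 9 features), split = ",
      x$split_tag, "\n", sep = "")
  print(table(x$labels))
  if (!is.null(x$scaler)) cat("  standardized (train-fitted scaler)\n")
  invisible(x)
}

#' Export a feature table to CSV
#'
#' Writes the feature matrix with a `label` column and `chNN_FEAT` headers.
#'
#' @param table An `eng_features`.
#' @param path Output file path.
#' @export
write_features_csv <- function(table, path) {
  df <- data.frame(label = as.character(table$labels), table$x,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
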