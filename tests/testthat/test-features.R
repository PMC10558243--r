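# Windowing, feature extraction, table assembly, standardization, shuffling.

test_that("window counts match brute-force enumeration", {
  # stated examples
  expect_identical(oracle_window_count(1000, 100, 20), 12L)
  x <- seq_len(1000)
  expect_length(make_windows(x, 1, 100, 20), 12L)
  expect_length(make_windows(x, 1, 100, 0), 10L)

  # every window has exactly w samples
  ws <- make_windows(x, 1, 100, 20)
  expect_true(all(vapply(ws, length, integer(1)) == 100L))

  # dense randomized sweep of (L, w, o) triples with L <= 2000 vs oracle
  set.seed(1)
  for (i in 1:500) {
    L <- sample(2:2000, 1)
    w <- sample(2:L, 1)
    o <- sample(0:(w - 1), 1)
    count <- length(engdecode:::window_starts(L, w, o))
    expect_identical(count, oracle_window_count(L, w, o),
                     info = sprintf("L=%d w=%d o=%d", L, w, o))
    # closed form
    expect_identical(count, as.integer(floor((L - w) / (w - o)) + 1))
  }
  # window longer than segment: zero windows with a warning, not an error
  expect_warning(out <- make_windows(seq_len(10), 1, 100, 0), "window")
  expect_length(out, 0L)
})

test_that("the nine features follow their definitions", {
  # constant window: stated degenerate policy
  f <- extract_features(rep(3, 50))
  expect_equal(f, c(MEAN = 3, VAR = 0, SKEW = 0, KUR = 0, MAV = 3, WL = 0,
                    MAX = 3, AMP = 0, POW = 9))
  # hand-computed example
  f2 <- extract_features(c(1, -1, 1, -1))
  expect_equal(f2, c(MEAN = 0, VAR = 1, SKEW = 0, KUR = -2, MAV = 1, WL = 6,
                     MAX = 1, AMP = 2, POW = 1))
  expect_error(extract_features(1), "2 samples")
})

test_that("features match the brute-force oracle on random windows", {
  set.seed(2)
  for (i in 1:200) {
    x <- rnorm(sample(2:256, 1), sd = 10^runif(1, -2, 2))
    got <- extract_features(x)
    want <- oracle_features(x)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # vectorized multi-window path agrees with the scalar path
  x <- rnorm(5000)
  starts <- engdecode:::window_starts(5000, 100, 25)
  M <- engdecode:::extract_features_matrix(x, starts, 100L)
  for (k in c(1, 17, length(starts))) {
    expect_equal(M[k, ], extract_features(x[starts[k]:(starts[k] + 99)]),
                 tolerance = 1e-12)
  }
})

test_that("train/test split is per class, contiguous, and leak-free", {
  s <- small_session(seed = 12L, segment_s = 10, n_channels = 3L, n_dead = 0L)
  sp <- split_train_test(s, 0.1)
  # per-class durations at the stated ratio
  for (i in 1:3) {
    n <- s$intervals$end[i] - s$intervals$start[i]
    expect_identical(sp$test$end[i] - sp$test$start[i], round(n * 0.1))
    expect_identical(sp$train$end[i] - sp$train$start[i], n - round(n * 0.1))
  }
  # raw-sample index sets disjoint
  tr_idx <- unlist(mapply(seq, sp$train$start, sp$train$end - 1L,
                          SIMPLIFY = FALSE))
  te_idx <- unlist(mapply(seq, sp$test$start, sp$test$end - 1L,
                          SIMPLIFY = FALSE))
  expect_length(intersect(tr_idx, te_idx), 0L)

  # windowed tables inherit disjointness and class balance
  sf <- preprocess_session(s)
  tb <- featurize_session(sf, window_spec(0.4, 0.08))
  covered <- function(t) unlist(mapply(seq, t$window_start, t$window_end - 1L,
                                       SIMPLIFY = FALSE))
  expect_length(intersect(covered(tb$train), covered(tb$test)), 0L)
  per_class <- table(tb$test$labels)
  expect_lte(max(per_class) - min(per_class), 1)

  expect_error(split_train_test(s, 1e-9), "too short")
})

test_that("table assembly concatenates channel blocks in fixed order", {
  set.seed(3)
  mk <- function() {
    m <- matrix(rnorm(5 * 9), 5, 9)
    colnames(m) <- c("MEAN", "VAR", "SKEW", "KUR", "MAV", "WL", "MAX",
                     "AMP", "POW")
    m
  }
  chans <- replicate(32, mk(), simplify = FALSE)
  labels <- rep(c("baseline", "full", "micturition"), length.out = 5)
  tab <- assemble_table(chans, labels)
  expect_identical(ncol(tab$x), 288L)
  expect_identical(tab$column_names[1:10],
                   c(paste0("ch01_", colnames(chans[[1]])), "ch02_MEAN"))

  # single channel, single window: row equals its feature vector
  m1 <- mk()
  one <- assemble_table(list(m1[1, , drop = FALSE]), "full")
  expect_equal(as.numeric(one$x[1, ]), as.numeric(m1[1, ]))
  expect_identical(one$column_names, paste0("ch01_", colnames(m1)))
  # permuting channel input order permutes column blocks identically
  perm <- sample(32)
  tab_p <- assemble_table(chans[perm], labels)
  for (j in seq_along(perm)) {
    expect_equal(unname(tab_p$x[, (j - 1) * 9 + 1:9]),
                 unname(tab$x[, (perm[j] - 1) * 9 + 1:9]))
  }
  expect_error(assemble_table(list(mk(), mk()[1:3, ]), labels), "window count")
})

test_that("standardization is train-referenced with an epsilon floor", {
  set.seed(4)
  mkfeat <- function(n, shift = 0) {
    m <- matrix(rnorm(n * 9, mean = shift), n, 9)
    m[, 2] <- 5 # a zero-variance column
    colnames(m) <- c("MEAN", "VAR", "SKEW", "KUR", "MAV", "WL", "MAX",
                     "AMP", "POW")
    m
  }
  tr <- assemble_table(list(mkfeat(60)), rep(c("baseline", "full",
                                               "micturition"), 20))
  te <- assemble_table(list(mkfeat(30, shift = 2)),
                       rep(c("baseline", "full", "micturition"), 10),
                       split_tag = "test")
  std <- standardize(tr, te)
  mu <- colMeans(std$train$x)
  sds <- apply(std$train$x, 2, function(c) sqrt(mean((c - mean(c))^2)))
  nondeg <- std$train$scaler$sd > 1e-8
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sds[nondeg] - 1)), 1e-10)
  # zero-variance train column: zeros in train, finite in test
  expect_true(all(std$train$x[, 2] == 0))
  expect_true(all(is.finite(std$test$x[, 2])))
  # test is NOT independently standardized when distributions differ
  te_self <- scale(te$x[, -2])
  expect_gt(max(abs(std$test$x[, -2] - te_self)), 0.5)
  # contract violations
  expect_error(standardize(std$train), "already standardized")
  expect_error(standardize(te), "training table")
})

test_that("row shuffling is a seeded label-aligned permutation", {
  tab <- small_table(small_session(seed = 21L, segment_s = 4, n_channels = 2L,
                                   n_dead = 0L))
  sh <- shuffle_rows(tab, seed = 9L)
  # multiset of (row, label) pairs preserved
  key <- function(t) {
    ord <- order(t$x[, 1], t$x[, 2])
    list(x = t$x[ord, ], lab = as.character(t$labels)[ord])
  }
  expect_equal(key(sh), key(tab))
  expect_identical(table(sh$labels), table(tab$labels))
  # deterministic given seed, different under another seed
  expect_identical(shuffle_rows(tab, seed = 9L)$x, sh$x)
  expect_false(identical(shuffle_rows(tab, seed = 10L)$shuffle_perm,
                         sh$shuffle_perm))
})
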