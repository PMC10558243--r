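# Window-length analysis: RF classification across 20 window lengths with
# overlap fixed at 20% of the length, and a trade-off selection rule.

#' The twenty evaluated window lengths
#'
#' Linearly spaced, inclusive endpoints: 0.05, 0.10, ..., 1.00 s (step
#' 0.05 s). The operating point 0.55 s (overlap 0.11 s) is on this grid.
#'
#' @return Numeric vector of 20 lengths in seconds.
#' @export
sweep_lengths <- function() seq(0.05, 1, length.out = 20L)

#' Balanced-accuracy sweep over window lengths
#'
#' For each window length, feature tables are rebuilt from scratch - the
#' training side windowed with overlap equal to 20% of the length, the test
#' side without overlap - and a random forest is cross-validated with
#' contiguous, class-stratified time folds. Per fold, the timeline of each
#' class is cut into `n_folds` blocks; block k (windowed without overlap)
#' is the test fold and the remaining blocks (each windowed independently
#' with the 20% overlap) form the training set, so overlapping training
#' windows never straddle into test material. Standardization is fitted on
#' the training rows of each fold, and training rows are shuffled before
#' fitting.
#'
#' With more than one grid point, the hyperparameter combination minimizing
#' the forest's out-of-bag error on the fold's training data is selected.
#'
#' A length for which some fold has no window for some class is flagged
#' unusable (NA balanced accuracy) rather than failing the sweep.
#'
#' @param sessions A preprocessed `eng_session` or list of them.
#' @param grid An RF [model_grid()] (candidate values may be reduced to a
#'   single point for speed).
#' @param lengths_s Window lengths to evaluate (default [sweep_lengths()]).
#' @param n_folds Folds per length (default 10).
#' @param seed Integer master seed.
#' @return An `eng_sweep`: `lengths_s`, per-session `ba` matrix, cross-
#'   session `mean_ba` per length, `usable` flags, plus run parameters.
#' @export
window_sweep <- function(sessions, grid = model_grid("rf"),
                         lengths_s = sweep_lengths(), n_folds = 10L,
                         seed = 1L) {
  if (inherits(sessions, "eng_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "eng_session")),
            identical(grid$model_kind, "rf"),
            all(diff(lengths_s) > 0))
  ba <- matrix(NA_real_, nrow = length(sessions), ncol = length(lengths_s),
               dimnames = list(NULL, sprintf("%.2fs", lengths_s)))
  for (si in seq_along(sessions)) {
    for (li in seq_along(lengths_s)) {
      ba[si, li] <- sweep_one(sessions[[si]], grid, lengths_s[li], n_folds,
                              derive_seed(seed, si, li))
    }
  }
  mean_ba <- colMeans(ba)
  structure(
    list(lengths_s = lengths_s, ba = ba, mean_ba = mean_ba,
         usable = !is.na(mean_ba), overlap_fraction = 0.2,
         n_folds = n_folds, grid = grid, seed = seed),
    class = "eng_sweep"
  )
}

# One (session, window length) cell: blockwise time CV of the RF.
sweep_one <- function(session, grid, length_s, n_folds, seed) {
  overlap_s <- 0.2 * length_s
  iv <- session$intervals
  w <- round(length_s * session$fs)
  fold_ba <- numeric(n_folds)
  points <- grid_points(grid)
  for (k in seq_len(n_folds)) {
    te_seg <- tr_seg <- iv[0, ]
    for (i in seq_len(nrow(iv))) {
      n <- iv$end[i] - iv$start[i]
      cuts <- iv$start[i] + round(n * (0:n_folds) / n_folds)
      te_seg <- rbind(te_seg, data.frame(
        start = cuts[k], end = cuts[k + 1L], state = iv$state[i]))
      if (k > 1L) tr_seg <- rbind(tr_seg, data.frame(
        start = iv$start[i], end = cuts[k], state = iv$state[i]))
      if (k < n_folds) tr_seg <- rbind(tr_seg, data.frame(
        start = cuts[k + 1L], end = iv$end[i], state = iv$state[i]))
    }
    ttrain <- make_table(session, tr_seg, length_s, overlap_s, "train")
    ttest <- make_table(session, te_seg, length_s, 0, "test")
    lab_tr <- droplevels(ttrain$labels)
    lab_te <- ttest$labels
    if (nlevels(lab_tr) < nrow(iv) ||
        length(unique(lab_te)) < nrow(iv) || nrow(ttest$x) == 0L) {
      return(NA_real_)
    }
    std <- standardize(ttrain, ttest)
    str_ <- shuffle_rows(std$train, derive_seed(seed, k))
    params <- if (length(points) == 1L) points[[1L]] else {
      oob <- vapply(seq_along(points), function(p) {
        ranger::ranger(x = as.data.frame(str_$x), y = str_$labels,
                       num.trees = points[[p]]$num_trees,
                       max.depth = points[[p]]$max_depth,
                       mtry = max(1L, floor(sqrt(ncol(str_$x)))),
                       seed = derive_seed(seed, k, p),
                       num.threads = 1L)$prediction.error
      }, numeric(1))
      points[[which.min(oob)]]
    }
    model <- fit_model("rf", params, str_$x, str_$labels,
                       seed = derive_seed(seed, k, 1L))
    pred <- predict_model(model, std$test$x)
    fold_ba[k] <- balanced_accuracy(
      confusion_matrix(lab_te, pred, levels = levels(lab_te)))
  }
  mean(fold_ba)
}

#' Select the trade-off window length
#'
#' Formalizes the "highest balanced accuracy at the smallest window length"
#' criterion: among usable lengths, pick the smallest whose cross-session
#' mean BA is within `tolerance_pp` percentage points of the best mean BA.
#' With `tolerance_pp = 0` this is the (first-occurring, i.e. smallest)
#' argmax length.
#'
#' @param result An `eng_sweep`.
#' @param tolerance_pp Tolerance band in percentage points (default 2).
#' @return Selected length in seconds (also recorded on the sweep object
#'   when assigned back).
#' @export
select_tradeoff <- function(result, tolerance_pp = 2) {
  stopifnot(inherits(result, "eng_sweep"), tolerance_pp >= 0)
  ok <- result$usable
  if (!any(ok)) stop("no usable window lengths in sweep", call. = FALSE)
  m <- result$mean_ba[ok]
  lens <- result$lengths_s[ok]
  best <- max(m)
  lens[which(m >= best - tolerance_pp / 100)[1L]]
}

#' @export
print.eng_sweep <- function(x, ...) {
  cat("<eng_sweep> ", length(x$lengths_s), " window lengths in [",
      min(x$lengths_s), ", ", max(x$lengths_s), "] s, ",
      nrow(x$ba), " session(s), ", x$n_folds, " folds\n", sep = "")
  sel <- select_tradeoff(x)
  cat(sprintf("  best mean BA %.4f at %.2f s; trade-off (2 pp) selects %.2f s\n",
              max(x$mean_ba, na.rm = TRUE),
              x$lengths_s[which.max(x$mean_ba)], sel))
  invisible(x)
}

#' @export
plot.eng_sweep <- function(x, ...) {
  graphics::matplot(x$lengths_s, t(x$ba), type = "b", pch = 1, lty = 3,
                    xlab = "window length (s)", ylab = "mean test BA",
                    ylim = c(0, 1), col = "grey50", ...)
  graphics::lines(x$lengths_s, x$mean_ba, lwd = 2)
  invisible(x)
}

#' Export sweep results as a plot-ready data frame
#'
#' @param result An `eng_sweep`.
#' @return Data frame with `length_s`, `session`, `mean_ba`.
#' @export
sweep_as_data_frame <- function(result) {
  stopifnot(inherits(result, "eng_sweep"))
  data.frame(
    length_s = rep(result$lengths_s, each = nrow(result$ba)),
    session = rep(seq_len(nrow(result$ba)), length(result$lengths_s)),
    mean_ba = as.vector(result$ba)
  )
}
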