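# Model zoo, nested cross-validation with grid search, balanced accuracy,
# and Gini feature importance.

#' Hyperparameter grid for one model family
#'
#' Declares the search space for one of the four classifiers. Defaults are
#' the full grids used by the decoder: random forest with
#' trees in \{50, 100, 200, 300\} and depth in \{5, 10, 20, 30\} (mtry fixed
#' to the square-root rule); SVM with sigmoid or RBF kernel and
#' regularization in \{1e-3, 1e-2, 1e-1, 1\}; k-NN with k in
#' \{3, 5, 7, 9, 11\}; MLP with five four-hidden-layer layouts at learning
#' rate 1e-3. Unknown hyperparameter names are rejected. Candidate values
#' may be overridden (e.g. a single point) via `...`.
#'
#' @param model_kind One of `"rf"`, `"svm"`, `"knn"`, `"mlp"`.
#' @param ... Optional named candidate overrides (see Details).
#' @return A `model_grid` object.
#' @export
model_grid <- function(model_kind = c("rf", "svm", "knn", "mlp"), ...) {
  model_kind <- match.arg(model_kind)
  defaults <- switch(model_kind,
    rf = list(num_trees = c(50, 100, 200, 300),
              max_depth = c(5, 10, 20, 30)),
    svm = list(kernel = c("sigmoid", "rbf"),
               cost = c(1e-3, 1e-2, 1e-1, 1)),
    knn = list(k = c(3, 5, 7, 9, 11)),
    mlp = list(hidden = list(c(128, 128, 128, 128),
                             c(128, 256, 256, 128),
                             c(128, 256, 512, 128),
                             c(128, 512, 512, 128),
                             c(128, 256, 512, 512)),
               learning_rate = 1e-3)
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(defaults))
    if (length(bad) || is.null(names(override)) || any(names(override) == "")) {
      stop(sprintf("unknown hyperparameter(s) for %s grid: %s", model_kind,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    defaults[names(override)] <- override
  }
  structure(list(model_kind = model_kind, grid = defaults),
            class = "model_grid")
}

# All combinations of a grid's candidate values, as a list of named
# parameter lists (grid order: first hyperparameter varies fastest).
grid_points <- function(grid) {
  g <- grid$grid
  if (grid$model_kind == "mlp" && !is.list(g$hidden[[1]])) {
    # single layout given as a plain vector
    if (!is.list(g$hidden)) g$hidden <- list(g$hidden)
  }
  lens <- vapply(g, length, integer(1))
  idx <- expand.grid(lapply(lens, seq_len), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    p <- lapply(seq_along(g), function(j) g[[j]][[idx[i, j]]])
    names(p) <- names(g)
    p
  })
}

# Fit one model of the zoo on a standardized feature matrix.
fit_model <- function(kind, params, x, y, seed = 1L, importance = FALSE,
                      x_val = NULL, y_val = NULL) {
  switch(kind,
    rf = {
      fit <- ranger::ranger(
        x = as.data.frame(x), y = y,
        num.trees = params$num_trees, max.depth = params$max_depth,
        mtry = max(1L, floor(sqrt(ncol(x)))),
        importance = if (importance) "impurity" else "none",
        seed = seed, num.threads = 1L
      )
      list(kind = "rf", fit = fit)
    },
    svm = {
      fit <- e1071::svm(x = x, y = y,
                        kernel = if (params$kernel == "rbf") "radial" else params$kernel,
                        cost = params$cost, scale = FALSE)
      list(kind = "svm", fit = fit)
    },
    knn = list(kind = "knn", x = x, y = y, k = params$k),
    mlp = {
      fit <- mlp_fit(x, y, hidden = params$hidden,
                     learning_rate = params$learning_rate, seed = seed,
                     x_val = x_val, y_val = y_val)
      list(kind = "mlp", fit = fit)
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

predict_model <- function(model, newx) {
  switch(model$kind,
    rf = stats::predict(model$fit, data = as.data.frame(newx),
                        num.threads = 1L)$predictions,
    svm = stats::predict(model$fit, newx),
    # fixed seed so the rare k-NN vote tie is broken reproducibly
    knn = with_seed(1L, class::knn(model$x, newx, model$y, k = model$k)),
    mlp = stats::predict(model$fit, newx)
  )
}

#' Confusion matrix with fixed class order
#'
#' @param true,pred Vectors of true and predicted labels.
#' @param levels Class order (default baseline, full, micturition).
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true, pred, levels = STATE_LEVELS) {
  m <- table(factor(as.character(true), levels = levels),
             factor(as.character(pred), levels = levels))
  out <- matrix(as.integer(m), nrow = length(levels),
                dimnames = list(true = levels, predicted = levels))
  out
}

#' Balanced accuracy of a multiclass confusion matrix
#'
#' The unweighted mean of per-class recalls: for each class, recall is the
#' count of correct predictions divided by the number of true instances
#' (true positives plus false negatives), and balanced accuracy averages the
#' recalls over the classes, so it lies in \[0, 1\] and is robust to class
#' imbalance.
#'
#' @param cm Square confusion matrix, rows = true class.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    nm <- rownames(cm)[rs == 0]
    if (is.null(nm)) nm <- which(rs == 0)
    stop("no true instances for class: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  mean(diag(cm) / rs)
}

# Contiguous fold assignment: split each class's (time-ordered) row indices
# into n nearly-equal contiguous blocks; block k of every class forms fold k.
contiguous_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop(sprintf("class '%s' has %d windows; %d folds require at least %d",
                   cl, length(idx), n_folds, n_folds), call. = FALSE)
    }
    fold[idx] <- as.integer(cut(seq_along(idx), breaks = n_folds,
                                labels = FALSE))
  }
  fold
}

#' Nested cross-validation with grid search
#'
#' Outer folds are contiguous-in-time, class-stratified blocks of the
#' feature table's rows (the table must be in timeline order, unshuffled and
#' unstandardized). Within each outer training set, the inner loop slides a
#' contiguous validation block along the time dimension (`n_inner`
#' positions); every grid point is fitted on the inner-training block and
#' scored by balanced accuracy on the validation block. The grid point with
#' the best mean inner BA is refit on the full outer-training set and
#' evaluated once on the outer test fold. Standardization is fitted on
#' training data only, and row shuffling is applied to training data only,
#' inside every fold - outer-test windows never influence scaler
#' parameters, hyperparameter choice, or training order.
#'
#' @param table An `eng_features` in timeline order (no scaler, no shuffle).
#' @param grid A [model_grid()].
#' @param n_outer Number of outer folds (default 10).
#' @param n_inner Number of inner validation positions (default 3).
#' @param seed Integer master seed; per-fold seeds derive from it.
#' @param importance Compute Gini importance per fold (RF only; default
#'   `TRUE` for RF).
#' @return An `eng_cv` report: per-fold balanced accuracies and confusion
#'   matrices, selected hyperparameters per fold, fold assignment, summary
#'   statistics (mean/median/IQR of BA), pooled confusion matrix, and for RF
#'   an [eng_importance] averaged over folds.
#' @export
nested_cv <- function(table, grid, n_outer = 10L, n_inner = 3L, seed = 1L,
                      importance = identical(grid$model_kind, "rf")) {
  stopifnot(inherits(table, "eng_features"), inherits(grid, "model_grid"))
  if (!is.null(table$scaler)) {
    stop("`table` must be unstandardized; nested_cv standardizes per fold",
         call. = FALSE)
  }
  if (!is.null(table$shuffle_perm)) {
    stop("`table` must be in timeline order; nested_cv shuffles per fold",
         call. = FALSE)
  }
  labels <- droplevels(table$labels)
  fold <- contiguous_folds(labels, n_outer)
  points <- grid_points(grid)
  kind <- grid$model_kind

  fold_ba <- numeric(n_outer)
  fold_cm <- vector("list", n_outer)
  fold_params <- vector("list", n_outer)
  fold_imp <- vector("list", n_outer)

  for (k in seq_len(n_outer)) {
    te <- which(fold == k)
    tr <- which(fold != k)
    if (length(unique(labels[te])) < nlevels(labels) ||
        length(unique(labels[tr])) < nlevels(labels)) {
      stop(sprintf("fold %d is missing a class", k), call. = FALSE)
    }
    best <- select_grid_point(table, tr, labels, points, kind, n_inner,
                              derive_seed(seed, k))
    # refit on the full outer-training set, evaluate once on the test fold
    sc <- scale_xy(table$x[tr, , drop = FALSE], table$x[te, , drop = FALSE])
    ord <- with_seed(derive_seed(seed, k, 999L), sample.int(length(tr)))
    model <- fit_model(kind, best, sc$train[ord, , drop = FALSE],
                       labels[tr][ord], seed = derive_seed(seed, k, 1L),
                       importance = importance && kind == "rf")
    pred <- predict_model(model, sc$test)
    cm <- confusion_matrix(labels[te], pred, levels = levels(labels))
    fold_ba[k] <- balanced_accuracy(cm)
    fold_cm[[k]] <- cm
    fold_params[[k]] <- best
    if (importance && kind == "rf") {
      fold_imp[[k]] <- model$fit$variable.importance
    }
  }

  imp_report <- NULL
  if (importance && kind == "rf") {
    raw <- Reduce(`+`, lapply(fold_imp, function(v) v / max(sum(v), 1e-300)))
    imp_report <- importance_report(raw / n_outer, table$column_names)
  }

  structure(
    list(model_kind = kind, fold_ba = fold_ba, fold_cm = fold_cm,
         fold_params = fold_params, fold = fold,
         mean_ba = mean(fold_ba), median_ba = stats::median(fold_ba),
         iqr_ba = stats::IQR(fold_ba),
         pooled_cm = Reduce(`+`, fold_cm),
         importance = imp_report, grid = grid,
         n_outer = n_outer, n_inner = n_inner, seed = seed),
    class = "eng_cv"
  )
}

# Inner loop of nested CV: slide a contiguous validation block along the
# time dimension of the outer-training rows and pick the grid point with the
# highest mean validation BA (first on ties, in grid order).
select_grid_point <- function(table, tr, labels, points, kind, n_inner,
                              seed) {
  if (length(points) == 1L) return(points[[1L]])
  inner_fold <- contiguous_folds(droplevels(labels[tr]), n_inner)
  scores <- numeric(length(points))
  for (j in seq_len(n_inner)) {
    va <- tr[inner_fold == j]
    it <- tr[inner_fold != j]
    sc <- scale_xy(table$x[it, , drop = FALSE], table$x[va, , drop = FALSE])
    ord <- with_seed(derive_seed(seed, j, 7L), sample.int(length(it)))
    xin <- sc$train[ord, , drop = FALSE]
    yin <- labels[it][ord]
    for (p in seq_along(points)) {
      model <- fit_model(kind, points[[p]], xin, yin,
                         seed = derive_seed(seed, j, p),
                         x_val = sc$test, y_val = labels[va])
      pred <- predict_model(model, sc$test)
      cm <- confusion_matrix(labels[va], pred, levels = levels(labels))
      scores[p] <- scores[p] + balanced_accuracy(cm) / n_inner
    }
  }
  points[[which.max(scores)]]
}

# Fit/apply a train-only column scaler on raw matrices (epsilon-floored).
scale_xy <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd_ <- sqrt(colMeans(sweep(xtr, 2L, mu)^2))
  denom <- pmax(sd_, 1e-12)
  list(train = sweep(sweep(xtr, 2L, mu), 2L, denom, "/"),
       test = sweep(sweep(xte, 2L, mu), 2L, denom, "/"))
}

#' Compare the four classifier families on identical folds
#'
#' Runs [nested_cv()] for each supplied grid with the same seed and fold
#' boundaries (folds depend only on the table and `n_outer`), then ranks
#' models by mean balanced accuracy, breaking ties by smaller interquartile
#' range.
#'
#' @param table An `eng_features` in timeline order.
#' @param grids List of [model_grid()]s (default: all four full grids).
#' @param n_outer,n_inner,seed As in [nested_cv()].
#' @return An `eng_model_comparison`: named list of `eng_cv` reports plus a
#'   `ranking` data frame.
#' @export
compare_models <- function(table,
                           grids = list(model_grid("rf"), model_grid("svm"),
                                        model_grid("knn"), model_grid("mlp")),
                           n_outer = 10L, n_inner = 3L, seed = 1L) {
  reports <- lapply(grids, function(g) {
    nested_cv(table, g, n_outer = n_outer, n_inner = n_inner, seed = seed)
  })
  names(reports) <- vapply(grids, function(g) g$model_kind, character(1))
  rk <- data.frame(
    model = names(reports),
    mean_ba = vapply(reports, function(r) r$mean_ba, numeric(1)),
    median_ba = vapply(reports, function(r) r$median_ba, numeric(1)),
    iqr_ba = vapply(reports, function(r) r$iqr_ba, numeric(1))
  )
  rk <- rk[order(-rk$mean_ba, rk$iqr_ba), ]
  rk$rank <- seq_len(nrow(rk))
  structure(list(reports = reports, ranking = rk, seed = seed),
            class = "eng_model_comparison")
}

# Build an importance report from a per-column importance vector.
importance_report <- function(imp, column_names) {
  imp <- pmax(as.numeric(imp), 0)
  names(imp) <- column_names
  total <- sum(imp)
  if (total <= 0) stop("all importances are zero", call. = FALSE)
  imp <- imp / total
  parts <- strsplit(column_names, "_", fixed = TRUE)
  channel <- vapply(parts, `[[`, character(1), 1L)
  feature <- vapply(parts, `[[`, character(1), 2L)
  per_feature <- tapply(imp, feature, mean)[FEATURE_NAMES]
  per_channel <- tapply(imp, channel, sum)
  per_channel <- per_channel[order(names(per_channel))]
  structure(
    list(per_column = imp,
         per_feature = per_feature,
         per_channel = per_channel),
    class = "eng_importance"
  )
}

#' Gini feature importance of a fitted random forest
#'
#' Extracts the mean-decrease-in-impurity (Gini) importance of every feature
#' column, normalizes it to sum to one, and aggregates it two ways: per
#' feature (average over channels, giving the channel-independent ranking of
#' the nine features) and per active site (sum over a channel's nine
#' columns, giving each recording contact's weight).
#'
#' @param fit A `ranger` fit trained with `importance = "impurity"`, or a
#'   `fit_model()` wrapper around one, or an `eng_cv` RF report (whose
#'   fold-averaged importances are returned).
#' @param column_names Column names in `chNN_FEAT` form (not needed for
#'   `eng_cv` input).
#' @return An `eng_importance`: normalized `per_column` vector plus
#'   `per_feature` and `per_channel` aggregates.
#' @export
gini_importance <- function(fit, column_names = NULL) {
  if (inherits(fit, "eng_cv")) {
    if (!identical(fit$model_kind, "rf") || is.null(fit$importance)) {
      stop("Gini importance is only available for random-forest fits",
           call. = FALSE)
    }
    return(fit$importance)
  }
  if (is.list(fit) && !is.null(fit$kind)) {
    if (!identical(fit$kind, "rf")) {
      stop("Gini importance is only available for random-forest fits",
           call. = FALSE)
    }
    fit <- fit$fit
  }
  if (!inherits(fit, "ranger")) {
    stop("Gini importance is only available for random-forest fits",
         call. = FALSE)
  }
  imp <- fit$variable.importance
  if (is.null(imp) || !length(imp)) {
    stop("forest was fitted without impurity importance", call. = FALSE)
  }
  if (is.null(column_names)) column_names <- names(imp)
  importance_report(imp, column_names)
}

#' @export
print.eng_cv <- function(x, ...) {
  cat("<eng_cv> ", toupper(x$model_kind), " nested cross-validation, ",
      x$n_outer, " outer x ", x$n_inner, " inner folds\n", sep = "")
  cat(sprintf("  balanced accuracy: mean %.4f, median %.4f, IQR %.4f\n",
              x$mean_ba, x$median_ba, x$iqr_ba))
  invisible(x)
}

#' @export
summary.eng_cv <- function(object, ...) {
  print(object)
  cat("  per-fold BA:", paste(sprintf("%.3f", object$fold_ba),
                              collapse = " "), "\n")
  cat("  pooled confusion matrix (rows = true):\n")
  print(object$pooled_cm)
  sel <- vapply(object$fold_params, function(p) {
    paste(vapply(names(p), function(nm) {
      paste0(nm, "=", paste(p[[nm]], collapse = "-"))
    }, character(1)), collapse = ", ")
  }, character(1))
  cat("  selected hyperparameters per fold:\n")
  for (k in seq_along(sel)) cat(sprintf("    fold %2d: %s\n", k, sel[k]))
  invisible(object)
}

#' @export
plot.eng_cv <- function(x, ...) {
  graphics::boxplot(x$fold_ba, ylab = "balanced accuracy",
                    main = sprintf("%s nested CV", toupper(x$model_kind)),
                    ylim = c(0, 1), ...)
  graphics::points(rep(1, length(x$fold_ba)), x$fold_ba, pch = 19)
  invisible(x)
}

#' @export
print.eng_model_comparison <- function(x, ...) {
  cat("<eng_model_comparison>\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' @export
plot.eng_model_comparison <- function(x, ...) {
  ba <- lapply(x$reports, function(r) r$fold_ba)
  graphics::boxplot(ba, ylab = "balanced accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
print.eng_importance <- function(x, ...) {
  cat("<eng_importance> per-feature (channel-averaged) Gini importance:\n")
  pf <- sort(x$per_feature, decreasing = TRUE)
  for (nm in names(pf)) cat(sprintf("  %-5s %.4f\n", nm, pf[nm]))
  invisible(x)
}
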