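# Feed-forward multi-layer perceptron classifier trained with Adam.
#
# Small, dependency-free implementation sufficient for the decoder's model
# zoo: dense ReLU hidden layers, softmax output, full-batch Adam with
# cross-entropy loss, seeded He initialization, and early stopping either on
# validation balanced accuracy (when a validation set is supplied, as in the
# inner loops of nested CV) or on the training-loss plateau.

#' Fit a multi-layer perceptron classifier
#'
#' @param x Numeric feature matrix (rows = samples); expected standardized.
#' @param y Factor of class labels.
#' @param hidden Integer vector of hidden-layer widths, e.g.
#'   `c(128, 256, 256, 128)`.
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed for weight initialization.
#' @param x_val,y_val Optional validation set; when given, training stops
#'   after `patience` epochs without improvement in validation balanced
#'   accuracy and the best-scoring weights are restored. Otherwise the
#'   monitor is the training loss.
#' @return An object of class `eng_mlp`.
#' @export
mlp_fit <- function(x, y, hidden = c(128, 128, 128, 128),
                    learning_rate = 1e-3, max_epochs = 200L, patience = 20L,
                    seed = 1L, x_val = NULL, y_val = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  K <- length(classes)
  sizes <- c(ncol(x), hidden, K)
  L <- length(sizes) - 1L

  init <- with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       nrow = sizes[l])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b)
  })
  W <- init$W; b <- init$b
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x_) x_ * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  Y <- matrix(0, nrow(x), K)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  n <- nrow(x)

  forward <- function(W, b, X) {
    A <- vector("list", L + 1L)
    A[[1L]] <- X
    for (l in seq_len(L)) {
      Z <- A[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(X))
      A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
    }
    # softmax with the usual max-shift for stability
    Z <- A[[L + 1L]]
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    P <- E / rowSums(E)
    list(A = A, P = P)
  }

  monitor_val <- !is.null(x_val) && !is.null(y_val)
  best_metric <- -Inf
  best <- list(W = W, b = b)
  wait <- 0L
  t_step <- 0L

  for (epoch in seq_len(max_epochs)) {
    fw <- forward(W, b, x)
    P <- fw$P
    # backprop of mean cross-entropy
    delta <- (P - Y) / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(fw$A[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (fw$A[[l]] > 0)
      }
    }
    t_step <- t_step + 1L
    corr1 <- 1 - beta1^t_step
    corr2 <- 1 - beta2^t_step
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + eps)
    }
    metric <- if (monitor_val) {
      pv <- forward(W, b, x_val)$P
      pred <- factor(classes[max.col(pv, ties.method = "first")],
                     levels = classes)
      mean(diag(prop.table(table(factor(y_val, levels = classes), pred),
                           margin = 1L)), na.rm = TRUE)
    } else {
      loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
      -loss
    }
    if (!is.na(metric) && metric > best_metric + 1e-9) {
      best_metric <- metric
      best <- list(W = W, b = b)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  structure(
    list(W = best$W, b = best$b, classes = classes, hidden = hidden,
         learning_rate = learning_rate, epochs_run = epoch,
         monitored = if (monitor_val) "validation BA" else "training loss",
         forward = NULL),
    class = "eng_mlp"
  )
}

#' Predict classes from a fitted MLP
#'
#' @param object An `eng_mlp` fit.
#' @param newdata Numeric matrix on the same feature scale as training.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.eng_mlp <- function(object, newdata, ...) {
  A <- newdata
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- A %*% object$W[[l]] + rep(object$b[[l]], each = nrow(A))
    A <- if (l < L) pmax(Z, 0) else Z
  }
  factor(object$classes[max.col(A, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.eng_mlp <- function(x, ...) {
  cat("<eng_mlp> layers:", paste(x$hidden, collapse = "-"),
      "| classes:", paste(x$classes, collapse = ", "),
      "| epochs:", x$epochs_run, "(stopped on", x$monitored, ")\n")
  invisible(x)
}
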