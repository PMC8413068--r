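# Multilayer perceptron for binary classification: fully connected ReLU
# layers, sigmoid output, binary cross-entropy with L2 penalty, trained
# full-batch with Adam. Small and deterministic under a seed.

.relu <- function(z) pmax(z, 0)

#' Train a multilayer perceptron (binary)
#'
#' Architecture and optimisation defaults follow the stress-classifier
#' protocol: 3 hidden layers of 10 ReLU units, L2 regularisation
#' `alpha = 1e-4`, Adam with learning rate 0.001, 200 epochs (full-batch;
#' the training sets here are small). When a validation set is supplied
#' the weights with the lowest validation log-loss seen during training
#' are kept (early monitoring; training always runs the full epoch
#' budget).
#'
#' @param X numeric matrix, instances x features (already standardised).
#' @param y labels coercible to 0/1: logical, 0/1 numeric, or a factor /
#'   character with two levels (the second sorted level is the positive
#'   class).
#' @param hidden integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param alpha L2 penalty on the weights.
#' @param epochs training epochs.
#' @param seed integer seed for the weight initialisation (He-scaled
#'   normal draws).
#' @param Xval,yval optional validation set for best-weight tracking.
#' @return object of class `"stressMLP"`: list with the weight/bias
#'   lists, the positive-class label, and a `converged` flag (final
#'   training loss finite and below the initial loss).
#' @seealso [predict.stressMLP()]
#' @export
mlpTrain <- function(X, y, hidden = c(10L, 10L, 10L), lr = 1e-3,
                     alpha = 1e-4, epochs = 200L, seed = 1L,
                     Xval = NULL, yval = NULL) {
  X <- as.matrix(X)
  enc <- .encode01(y)
  yy <- enc$y
  yval01 <- if (!is.null(yval)) .encode01(yval, enc$positive)$y else NULL
  nIn <- ncol(X)
  sizes <- c(nIn, hidden, 1L)
  L <- length(sizes) - 1L

  W <- .with_seed(seed, lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))

  fwd <- function(W, b, X) {
    A <- vector("list", L + 1L)
    A[[1]] <- X
    for (l in seq_len(L)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
      A[[l + 1]] <- if (l < L) .relu(Z) else 1 / (1 + exp(-Z))
    }
    A
  }
  logloss <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  initLoss <- logloss(fwd(W, b, X)[[L + 1]], yy)
  bestVal <- Inf; bestW <- W; bestB <- b

  for (t in seq_len(epochs)) {
    A <- fwd(W, b, X)
    delta <- (A[[L + 1]] - yy) / n          # dLoss/dZ at the sigmoid output
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta) + alpha * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      cor1 <- 1 - b1^t; cor2 <- 1 - b2^t
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
    }
    if (!is.null(Xval) && length(yval01)) {
      vl <- logloss(fwd(W, b, Xval)[[L + 1]], yval01)
      if (vl < bestVal) { bestVal <- vl; bestW <- W; bestB <- b }
    }
  }
  if (!is.null(Xval) && length(yval01) && is.finite(bestVal)) {
    W <- bestW; b <- bestB
  }
  finalLoss <- logloss(fwd(W, b, X)[[L + 1]], yy)
  structure(list(W = W, b = b, hidden = hidden, positive = enc$positive,
                 converged = is.finite(finalLoss) && finalLoss <= initLoss,
                 train_loss = finalLoss),
            class = "stressMLP")
}

# Map labels to 0/1; positive class = second sorted level unless given.
.encode01 <- function(y, positive = NULL) {
  if (is.logical(y)) return(list(y = as.numeric(y), positive = TRUE))
  if (is.numeric(y) && all(y %in% c(0, 1)))
    return(list(y = as.numeric(y), positive = 1))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (is.null(positive)) {
    if (length(lev) > 2L) stop("binary labels expected, got: ",
                               paste(lev, collapse = ", "))
    positive <- lev[length(lev)]
  }
  list(y = as.numeric(y == positive), positive = positive)
}

#' Predict from a trained MLP
#'
#' @param object a `"stressMLP"` from [mlpTrain()].
#' @param newdata numeric matrix, instances x features, standardised the
#'   same way as the training data.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   0/1 at the 0.5 threshold.
#' @param ... unused.
#' @return numeric vector of probabilities or 0/1 predictions.
#' @export
predict.stressMLP <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  A <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2, object$b[[l]], `+`)
    A <- if (l < L) .relu(Z) else 1 / (1 + exp(-Z))
  }
  p <- as.numeric(A)
  if (type == "prob") p else as.numeric(p >= 0.5)
}
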