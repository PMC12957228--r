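#' Train a one-hidden-layer feed-forward regression network
#'
#' Minimal multilayer perceptron used by the neural-network SBW model:
#' one hidden layer of `hidden` rectified-linear units, a linear output,
#' squared-error loss, minibatch gradient descent with the adaptive-moment
#' (Adam) optimizer, He-scaled initialization, a fixed epoch budget and no
#' early stopping. The target is internally z-scored for optimization
#' stability and predictions are returned on the original scale.
#'
#' @param X numeric matrix (n x p), typically z-scored features.
#' @param y numeric response.
#' @param hidden hidden-layer width.
#' @param lr Adam learning rate.
#' @param epochs number of full passes over the data.
#' @param batch_size minibatch size.
#' @param seed integer seed (initialization and shuffling).
#' @return object of class `mlp_fit` for [mlp_predict()].
#' @export
mlp_fit <- function(X, y, hidden = 64, lr = 0.001, epochs = 500,
                    batch_size = 16, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  yt <- (y - y_center) / y_scale

  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(pars, function(z) z * 0)
  vel <- lapply(pars, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L

  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    for (bt in batches) {
      Xb <- X[bt, , drop = FALSE]; yb <- yt[bt]; m <- length(bt)
      Z1 <- sweep(Xb %*% pars$W1, 2, pars$b1, "+")
      A1 <- pmax(Z1, 0)
      pred <- drop(A1 %*% pars$W2) + pars$b2
      dpred <- 2 * (pred - yb) / m
      g <- list(
        W1 = NULL, b1 = NULL,
        W2 = crossprod(A1, dpred), b2 = sum(dpred)
      )
      dA1 <- tcrossprod(dpred, drop(pars$W2))
      dZ1 <- dA1 * (Z1 > 0)
      g$W1 <- crossprod(Xb, dZ1)
      g$b1 <- colSums(dZ1)
      t <- t + 1L
      for (nm in names(pars)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^t)
        vhat <- vel[[nm]] / (1 - beta2^t)
        pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(pars = pars, y_center = y_center, y_scale = y_scale,
                 hidden = hidden, lr = lr, epochs = epochs,
                 batch_size = batch_size, seed = seed),
            class = "mlp_fit")
}

#' Predict from a fitted [mlp_fit()] network
#' @param fit an `mlp_fit`.
#' @param X feature matrix on the training scale.
#' @return numeric predictions in original response units.
#' @export
mlp_predict <- function(fit, X) {
  X <- as.matrix(X)
  A1 <- pmax(sweep(X %*% fit$pars$W1, 2, fit$pars$b1, "+"), 0)
  drop(A1 %*% fit$pars$W2 + fit$pars$b2) * fit$y_scale + fit$y_center
}
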