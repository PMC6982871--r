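# Shallow feed-forward softmax classifier, implemented directly: one hidden
# ReLU layer, softmax output, full-batch Adam on the cross-entropy loss with
# L2 weight decay. Shallow networks are the appropriate induction algorithm
# for small binary-sensor datasets; no deep architecture is provided on
# purpose. Inputs are expected in [0, 1], so no further scaling is applied.

#' Hyperparameters for the shallow network
#'
#' @param hidden Hidden-layer width (units). Default 64.
#' @param epochs Maximum full-batch epochs. Default 500.
#' @param learn_rate Adam step size. Default 0.01.
#' @param l2 L2 weight-decay coefficient. Default 1e-4.
#' @param tol Stop early when the loss improves by less than `tol` over an
#'   epoch. Default 1e-7.
#' @return A `mlp_control` list.
#' @export
mlp_control <- function(hidden = 64, epochs = 500, learn_rate = 0.01,
                        l2 = 1e-4, tol = 1e-7) {
  stopifnot(hidden >= 1, epochs >= 1, learn_rate > 0, l2 >= 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learn_rate = learn_rate, l2 = l2, tol = tol),
            class = "mlp_control")
}

#' Fit the shallow network
#'
#' @param X Numeric matrix, instances x features.
#' @param y Factor (or character) labels; the level order fixes the output
#'   order and the argmax tie-break (lowest index wins).
#' @param control A [mlp_control()] record.
#' @param seed Integer seed for the weight initialisation; given the seed the
#'   fit is fully deterministic (training is full-batch, so there is no other
#'   randomness).
#' @return A `har_mlp` fit (weights, class levels, control, final loss).
#' @export
mlp_fit <- function(X, y, control = mlp_control(), seed = 0) {
  X <- as.matrix(X)
  y <- factor(y, levels = if (is.factor(y)) levels(y) else unique(y))
  classes <- levels(y)
  n <- nrow(X); d <- ncol(X); K <- length(classes); h <- control$hidden
  stopifnot(n == length(y), K >= 2)
  Tmat <- diag(K)[as.integer(y), , drop = FALSE]

  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h * K, sd = sqrt(2 / h)), h, K),
    b2 = rep(0, K)
  ))
  # Adam state, one slot per parameter
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  prev_loss <- Inf; loss <- NA_real_

  for (it in seq_len(control$epochs)) {
    Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
    H <- pmax(Z1, 0)
    S <- sweep(H %*% params$W2, 2, params$b2, "+")
    S <- S - apply(S, 1, max)
    E <- exp(S)
    P <- E / rowSums(E)
    loss <- -mean(log(pmax(P[Tmat == 1], 1e-12))) +
      control$l2 * (sum(params$W1^2) + sum(params$W2^2)) / 2
    if (abs(prev_loss - loss) < control$tol) break
    prev_loss <- loss

    dS <- (P - Tmat) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(H, dS) + control$l2 * params$W2,
      b2 = colSums(dS)
    )
    dH <- dS %*% t(params$W2)
    dZ1 <- dH * (Z1 > 0)
    grads$W1 <- crossprod(X, dZ1) + control$l2 * params$W1
    grads$b1 <- colSums(dZ1)

    for (nm in names(params)) {
      m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * grads[[nm]]
      v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1a^it)
      vhat <- v[[nm]] / (1 - b2a^it)
      params[[nm]] <- params[[nm]] - control$learn_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(params = params, classes = classes, control = control,
                 seed = seed, loss = loss, epochs_run = it, d = d),
            class = "har_mlp")
}

#' Class probabilities from a fitted network
#'
#' @param object A `har_mlp` fit.
#' @param X Matrix (or single vector) of inputs with the training
#'   dimensionality.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), columns in the
#'   fit's class-level order.
#' @export
predict.har_mlp <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != object$d) {
    stop("dimension mismatch: expected ", object$d, " features, got ", ncol(X))
  }
  p <- object$params
  H <- pmax(sweep(X %*% p$W1, 2, p$b1, "+"), 0)
  S <- sweep(H %*% p$W2, 2, p$b2, "+")
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  colnames(P) <- object$classes
  P
}
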