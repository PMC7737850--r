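.EPS <- 1e-12

#' Initialize network parameters
#'
#' First-layer weights start uniform on [0.01, 0.10] -- below the 1/e
#' watershed of the entropy penalty, so every weight is pushed towards 0 by
#' default and only weights receiving a persistent data gradient escape
#' upwards past 1/e towards 1. (Initializing symmetrically around 1/e lets
#' the penalty polarize most weights to 1 regardless of the data, which
#' destroys the importance ranking.) Deeper layers use scaled Gaussian (He)
#' draws and zero biases; \code{\link{trainSnapshots}} rescales them
#' against a sample of the training data before the first step.
#'
#' @param layerSizes integer vector, input width first, 1 last,
#'   e.g. \code{c(p, 50, 30, 1)}.
#' @param seed integer RNG seed.
#' @param hiddenActivation "relu" or "linear".
#' @return A \linkS4class{NetworkParams}.
#' @examples
#' initNetwork(c(4, 3, 1), seed = 1)
#' @export
initNetwork <- function(layerSizes, seed = 1L, hiddenActivation = "relu") {
  layerSizes <- as.integer(layerSizes)
  if (length(layerSizes) < 2) stop("need at least input and output layers")
  withr::local_seed(as.integer(seed))
  L <- length(layerSizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    nin <- layerSizes[l]; nout <- layerSizes[l + 1L]
    if (l == 1L) {
      weights[[l]] <- matrix(stats::runif(nin * nout, 0.01, 0.10), nin, nout)
    } else {
      weights[[l]] <- matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    }
    biases[[l]] <- rep(0, nout)
  }
  methods::new("NetworkParams", weights = weights, biases = biases,
               layerSizes = layerSizes, hiddenActivation = hiddenActivation)
}

.activate <- function(z, kind) {
  if (kind == "relu") pmax(z, 0) else z
}

# full forward pass keeping pre-activations and activations for backprop
.forwardFull <- function(params, X) {
  L <- length(params@weights)
  act <- params@hiddenActivation
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% params@weights[[l]] +
      matrix(params@biases[[l]], nrow(X), length(params@biases[[l]]), byrow = TRUE)
    A[[l + 1L]] <- if (l == L) stats::plogis(Z[[l]]) else .activate(Z[[l]], act)
  }
  list(A = A, Z = Z)
}

#' Forward pass of the classifier
#'
#' Per-layer affine transform followed by the hidden activation (rectifier
#' by default) and a logistic sigmoid on the single output unit.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param X numeric matrix of normalized inputs, one row per sample,
#'   columns matching the input layer width.
#' @return Numeric vector of probabilities in (0, 1), one per sample.
#' @examples
#' net <- initNetwork(c(3, 2, 1), seed = 1)
#' forwardPass(net, matrix(0, 1, 3))
#' @export
forwardPass <- function(params, X) {
  stopifnot(is(params, "NetworkParams"))
  X <- as.matrix(X)
  if (ncol(X) != params@layerSizes[1L])
    stop(sprintf("input has %d columns but the network expects %d",
                 ncol(X), params@layerSizes[1L]))
  if (any(!is.finite(X))) stop("input values must be finite")
  as.vector(.forwardFull(params, X)$A[[length(params@weights) + 1L]])
}

#' Entropy penalty of the bounded first-layer weights
#'
#' \eqn{-\sum_{jk} w_{jk} \log w_{jk}} with natural logarithm and the
#' convention \eqn{0 \log 0 = 0} (a floor of 1e-12 inside the log). The
#' penalty is zero exactly when every weight sits at 0 or 1 and is
#' maximized per weight at \eqn{w = 1/e}; minimizing it drives the first
#' layer towards a binary gate. The coefficient \eqn{\lambda} is applied by
#' \code{\link{totalLoss}}, not here.
#'
#' @param W1 numeric matrix of first-layer weights, entries in [0, 1].
#' @return Non-negative scalar.
#' @examples
#' entropyPenalty(matrix(c(0, 1, 1, 0), 2))   # 0
#' entropyPenalty(matrix(exp(-1)))            # 1/e, the per-weight maximum
#' @export
entropyPenalty <- function(W1) {
  W1 <- as.matrix(W1)
  if (any(W1 < -1e-9) || any(W1 > 1 + 1e-9))
    stop("first-layer weights outside [0, 1]: projection contract violated")
  -sum(W1 * log(pmax(W1, .EPS)))
}

# Layer-sequential rescaling of the deeper layers against real data.
# With non-negative inputs and a non-negative first layer, hidden
# pre-activations are offset-dominated; left uncalibrated they saturate the
# output sigmoid or kill rectifier units within the first epochs. Each
# layer beyond the first is rescaled so its pre-activations on a sample
# batch have zero mean and at most unit variance (biases absorb the
# offset). Amplification of low-variance units is capped (sd floored at
# 0.3, i.e. gain <= 3.3): unbounded amplification of a near-constant layer
# (tiny input widths at initialization) explodes the weights and
# destabilizes the first training steps, while the bounded first layer can
# still grow its activations by an order of magnitude during training.
# The first layer itself is never touched.
.calibrateDeepLayers <- function(params, X) {
  L <- length(params@weights)
  A <- as.matrix(X)
  for (l in seq_len(L)) {
    Z <- A %*% params@weights[[l]] +
      matrix(params@biases[[l]], nrow(A), length(params@biases[[l]]),
             byrow = TRUE)
    if (l > 1L) {
      m <- colMeans(Z)
      s <- apply(Z, 2L, stats::sd)
      s[!is.finite(s)] <- 1
      s <- pmax(s, 0.3)
      params@weights[[l]] <- sweep(params@weights[[l]], 2L, s, "/")
      params@biases[[l]] <- (params@biases[[l]] - m) / s
      Z <- sweep(sweep(Z, 2L, m, "-"), 2L, s, "/")
    }
    A <- if (l == L) stats::plogis(Z) else .activate(Z, params@hiddenActivation)
  }
  params
}

#' Elementwise gradient of the entropy penalty (internal)
#'
#' Consistent with the epsilon-floored penalty: for w > eps the derivative
#' of -w log w is -(log w + 1); below the floor the penalty is linear in w
#' with slope -log(eps).
#' @noRd
.entropyGrad <- function(W1) {
  g <- -(log(pmax(W1, .EPS)) + 1)
  g[W1 <= .EPS] <- -log(.EPS)
  g
}

#' Regularized cross-entropy training cost
#'
#' Mean binary cross-entropy of the predictions plus
#' \code{lambda} times the first-layer entropy penalty. Predictions are
#' clipped to [1e-12, 1 - 1e-12] inside the logs. Averaging (rather than
#' summing) the cross-entropy keeps the meaning of \code{lambda}
#' independent of batch size.
#'
#' @param yHat probability vector in (0, 1).
#' @param y binary label vector (0/1), same length.
#' @param W1 first-layer weight matrix, entries in [0, 1].
#' @param lambda non-negative penalty coefficient.
#' @return list (a loss breakdown) with \code{crossEntropy},
#'   \code{entropyPenalty}, \code{lambda}, \code{total}
#'   (= crossEntropy + lambda * entropyPenalty).
#' @examples
#' totalLoss(rep(0.5, 4), c(1, 0, 1, 0), matrix(1, 2, 2), 0)$crossEntropy # log 2
#' @export
totalLoss <- function(yHat, y, W1, lambda) {
  if (length(yHat) != length(y)) stop("yHat and y must have equal length")
  if (lambda < 0) stop("lambda must be >= 0")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  yc <- pmin(pmax(yHat, .EPS), 1 - .EPS)
  ce <- -mean(y * log(yc) + (1 - y) * log(1 - yc))
  pen <- entropyPenalty(W1)
  list(crossEntropy = ce, entropyPenalty = pen, lambda = lambda,
       total = ce + lambda * pen)
}

#' Clamp first-layer weights to [0, 1]
#'
#' The projection step of projected gradient descent: applied after every
#' optimizer update so the entropy penalty's domain assumption holds.
#' Idempotent.
#'
#' @param W1 numeric matrix with finite entries.
#' @return The elementwise clamp of \code{W1} to [0, 1].
#' @examples
#' projectFirstLayer(matrix(c(-0.5, 0.3, 1.7), 1))
#' @export
projectFirstLayer <- function(W1) {
  if (any(!is.finite(W1))) stop("first-layer weights must be finite")
  pmin(pmax(W1, 0), 1)
}

#' Analytic gradients of the training cost
#'
#' Back-propagation of \code{\link{totalLoss}} through the network,
#' including the entropy term on the first layer. Used by the SGD loop and
#' checkable against central finite differences.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param X input matrix (samples x features).
#' @param y binary labels.
#' @param lambda entropy-penalty coefficient.
#' @return list with \code{dW} and \code{db} (lists shaped like the
#'   parameters) and the scalar \code{loss} breakdown.
#' @export
lossGradients <- function(params, X, y, lambda) {
  X <- as.matrix(X)
  n <- nrow(X)
  L <- length(params@weights)
  fw <- .forwardFull(params, X)
  yHat <- as.vector(fw$A[[L + 1L]])
  loss <- totalLoss(yHat, y, params@weights[[1L]], lambda)

  dW <- vector("list", L)
  db <- vector("list", L)
  # mean cross-entropy with sigmoid output: dL/dz_L = (yHat - y)/n
  delta <- matrix((yHat - y) / n, n, 1L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params@weights[[l]])
      if (params@hiddenActivation == "relu")
        delta <- delta * (fw$Z[[l - 1L]] > 0)
    }
  }
  dW[[1L]] <- dW[[1L]] + lambda * .entropyGrad(params@weights[[1L]])
  list(dW = dW, db = db, loss = loss)
}
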