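#' Cyclic cosine learning-rate schedule
#'
#' \deqn{\alpha(t) = \frac{\alpha_0}{2}\left(\cos\!\left(\frac{\pi\,
#' \mathrm{mod}(t-1,\lceil T/M\rceil)}{\lceil T/M\rceil}\right)+1\right)}
#' Epochs are 1-based; each of the M cycles spans
#' \eqn{\lceil T/M \rceil} epochs, starting at the full rate
#' \eqn{\alpha_0}, decaying along a half cosine, and restarting with a
#' spike at the next cycle so the model is dislodged from its local
#' minimum before the next snapshot.
#'
#' @param t epoch index (1-based), may be a vector; must lie in [1, T].
#' @param alpha0 initial learning rate.
#' @param nEpochs total epochs T.
#' @param nSnapshots number of cycles M.
#' @return Learning rate(s) in (0, alpha0].
#' @examples
#' cosineLR(1, 0.1, 100, 5)    # cycle start: 0.1
#' cosineLR(11, 0.1, 100, 5)   # mid-cycle: 0.05
#' cosineLR(21, 0.1, 100, 5)   # restart spike: 0.1
#' @export
cosineLR <- function(t, alpha0, nEpochs, nSnapshots) {
  if (any(t < 1)) stop("epoch index must be >= 1")
  if (any(t > nEpochs)) stop("epoch index exceeds total epochs")
  cycleLength <- ceiling(nEpochs / nSnapshots)
  (alpha0 / 2) * (cos(pi * ((t - 1) %% cycleLength) / cycleLength) + 1)
}

#' Train one network under the cosine schedule, capturing snapshots
#'
#' Runs \code{nEpochs} of mini-batch projected SGD on the regularized
#' cross-entropy cost (\code{\link{totalLoss}}); the learning rate of every
#' epoch comes from \code{\link{cosineLR}} and first-layer weights are
#' clamped to [0, 1] after every step. A parameter copy is captured at the
#' final epoch of each of the M cosine cycles (and at the final epoch if T
#' is not a multiple of M, so the ensemble always holds M members). The run
#' is deterministic given \code{config@seed}.
#'
#' @param xTrain normalized training matrix (samples x features, values in
#'   [0, 1]).
#' @param yTrain binary training labels.
#' @param xVal,yVal optional validation data; when given, validation loss
#'   is logged per epoch.
#' @param config a \linkS4class{TrainConfig}.
#' @return A \linkS4class{SnapshotEnsemble}.
#' @examples
#' X <- matrix(runif(40), 20, 2); y <- rbinom(20, 1, 0.5)
#' trainSnapshots(X, y, config = TrainConfig(hiddenSizes = c(4, 3),
#'                nEpochs = 4, nSnapshots = 2, batchSize = 8))
#' @export
trainSnapshots <- function(xTrain, yTrain, xVal = NULL, yVal = NULL,
                           config = TrainConfig()) {
  stopifnot(is(config, "TrainConfig"))
  methods::validObject(config)
  xTrain <- as.matrix(xTrain)
  n <- nrow(xTrain)
  if (n == 0) stop("training data must be non-empty")
  if (length(yTrain) != n) stop("label length must match training rows")
  p <- ncol(xTrain)
  layerSizes <- c(p, config@hiddenSizes, 1L)
  withr::local_seed(config@seed)
  params <- initNetwork(layerSizes, seed = sample.int(.Machine$integer.max, 1),
                        hiddenActivation = config@hiddenActivation)
  params <- .calibrateDeepLayers(params,
                                 xTrain[seq_len(min(n, 512L)), , drop = FALSE])

  Tn <- config@nEpochs
  M <- config@nSnapshots
  cycleLength <- ceiling(Tn / M)
  batch <- min(config@batchSize, n)
  snaps <- vector("list", M)
  nextSnap <- 1L
  history <- data.frame(epoch = seq_len(Tn), lr = NA_real_,
                        trainLoss = NA_real_, trainCrossEntropy = NA_real_,
                        valLoss = NA_real_)

  for (t in seq_len(Tn)) {
    lr <- cosineLR(t, config@alpha0, Tn, M)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch)
    epochCE <- 0; epochTotal <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n)]
      g <- lossGradients(params, xTrain[idx, , drop = FALSE], yTrain[idx],
                         config@lambda)
      if (!is.finite(g$loss$total))
        stop(sprintf("non-finite training loss at epoch %d; try a smaller alpha0", t))
      for (l in seq_along(params@weights)) {
        params@weights[[l]] <- params@weights[[l]] - lr * g$dW[[l]]
        params@biases[[l]] <- params@biases[[l]] - lr * g$db[[l]]
      }
      params@weights[[1L]] <- projectFirstLayer(params@weights[[1L]])
      w <- length(idx) / n
      epochCE <- epochCE + w * g$loss$crossEntropy
      epochTotal <- epochTotal + w * g$loss$total
    }
    history$lr[t] <- lr
    history$trainCrossEntropy[t] <- epochCE
    history$trainLoss[t] <- epochTotal
    if (!is.null(xVal) && nrow(xVal) > 0) {
      vHat <- forwardPass(params, xVal)
      history$valLoss[t] <- totalLoss(vHat, yVal, params@weights[[1L]],
                                      config@lambda)$crossEntropy
    }
    atCycleEnd <- (t - 1L) %% cycleLength == cycleLength - 1L
    if ((atCycleEnd || t == Tn) && nextSnap <= M) {
      snaps[[nextSnap]] <- params
      nextSnap <- nextSnap + 1L
    }
  }
  # guard: if fewer cycle boundaries than M fell inside T, pad with final params
  while (nextSnap <= M) { snaps[[nextSnap]] <- params; nextSnap <- nextSnap + 1L }

  methods::new("SnapshotEnsemble",
    snapshots = snaps,
    schedule = list(alpha0 = config@alpha0, nEpochs = Tn, nSnapshots = M,
                    cycleLength = cycleLength),
    history = history, config = config)
}

#' Averaged prediction of a snapshot ensemble
#'
#' The unweighted mean of the member networks' probability outputs; class
#' labels are assigned at the 0.5 threshold.
#'
#' @param ensemble a \linkS4class{SnapshotEnsemble}.
#' @param X normalized input matrix.
#' @return list with \code{probability} (mean of member outputs) and
#'   \code{label} (integer 0/1 at the 0.5 threshold).
#' @export
ensemblePredict <- function(ensemble, X) {
  stopifnot(is(ensemble, "SnapshotEnsemble"))
  if (length(ensemble@snapshots) == 0) stop("ensemble has no snapshots")
  X <- as.matrix(X)
  probs <- vapply(ensemble@snapshots, function(s) forwardPass(s, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
  prob <- rowMeans(probs)
  list(probability = prob, label = as.integer(prob >= 0.5))
}

#' Member networks of a snapshot ensemble
#'
#' @param x a \linkS4class{SnapshotEnsemble}.
#' @param ... unused.
#' @return list of \linkS4class{NetworkParams}.
#' @rdname snapshots
#' @export
setMethod("snapshots", "SnapshotEnsemble", function(x, ...) x@snapshots)

#' Per-epoch training history
#'
#' @param x a \linkS4class{SnapshotEnsemble}.
#' @param ... unused.
#' @return data.frame with epoch, lr, trainLoss, trainCrossEntropy, valLoss.
#' @rdname trainHistory
#' @export
setMethod("trainHistory", "SnapshotEnsemble", function(x, ...) x@history)

setMethod("show", "SnapshotEnsemble", function(object) {
  sc <- object@schedule
  cat(sprintf("SnapshotEnsemble: %d snapshots over %d epochs (cycle length %d, alpha0 %.3g, lambda %.3g)\n",
              length(object@snapshots), sc$nEpochs, sc$cycleLength,
              sc$alpha0, object@config@lambda))
  final <- object@history[nrow(object@history), ]
  cat(sprintf("  final train loss %.4f (cross-entropy %.4f)\n",
              final$trainLoss, final$trainCrossEntropy))
  if (!is.na(final$valLoss))
    cat(sprintf("  final validation cross-entropy %.4f\n", final$valLoss))
  invisible(object)
})

#' Fraction of first-layer weights polarized to {0, 1}
#'
#' Diagnostic for the entropy regularizer: the share of first-layer
#' weights lying within \code{tol} of either 0 or 1. Under an effective
#' penalty the vast majority of weights converge to the extremes.
#'
#' @param x a \linkS4class{NetworkParams} or \linkS4class{SnapshotEnsemble}
#'   (averaged over members).
#' @param tol closeness tolerance (default 0.1).
#' @return Fraction in [0, 1].
#' @export
polarizationFraction <- function(x, tol = 0.1) {
  frac1 <- function(W) mean(W <= tol | W >= 1 - tol)
  if (is(x, "NetworkParams")) return(frac1(x@weights[[1L]]))
  if (is(x, "SnapshotEnsemble"))
    return(mean(vapply(x@snapshots, function(s) frac1(s@weights[[1L]]),
                       numeric(1))))
  stop("x must be NetworkParams or SnapshotEnsemble")
}
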