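#' Sample variance of a feature's absolute first-layer weights
#'
#' Variance with denominator J - 1 over the J weights fanning out of one
#' feature. A high value flags element-wise sparsity: the feature keeps
#' some first-layer connections while others have been driven to zero.
#'
#' @param weights numeric vector of absolute weights for one feature
#'   (length J >= 2).
#' @return Scalar sample variance.
#' @examples
#' weightVariance(c(1, 0))     # 0.5
#' weightVariance(c(1, 0, 1))  # 1/3
#' @export
weightVariance <- function(weights) {
  J <- length(weights)
  if (J < 2) stop("need at least two weights per feature (J >= 2)")
  sum((weights - mean(weights))^2) / (J - 1)
}

#' Feature Sparsity Importance
#'
#' For each input feature k with first-layer weight vector
#' \eqn{W^1_k} (the J weights connecting it to the first hidden layer):
#' \deqn{R_k = \frac{\overline{|W^1_k|} - \sigma^2(|W^1_k|)}
#'   {\max_k \overline{|W^1_k|}}}
#' Fully connected features (high mean, low variance) score near 1;
#' partially connected features are penalized by their element-wise
#' variance; disconnected features score near 0. R_k can drop below 0 when
#' the variance exceeds the mean; such values are kept for ranking and
#' floored at 0 only by the cumulative selection policy.
#'
#' @param W1 first-layer weight matrix with one row per feature
#'   (p x J, as stored in \linkS4class{NetworkParams}).
#' @return Named numeric vector of length p (names from rownames, when
#'   present).
#' @examples
#' featureImportance(rbind(A = c(1, 1, 1), B = c(0, 0, 0)))  # c(A = 1, B = 0)
#' @export
featureImportance <- function(W1) {
  W1 <- as.matrix(W1)
  if (length(W1) == 0) stop("empty weight matrix")
  if (ncol(W1) < 2) stop("need at least two hidden units per feature (J >= 2)")
  A <- abs(W1)
  m <- rowMeans(A)
  v <- rowSums((A - m)^2) / (ncol(A) - 1)
  mx <- max(m)
  r <- if (mx == 0) rep(0, length(m)) else (m - v) / mx
  names(r) <- rownames(W1)
  r
}

#' Average per-snapshot importance vectors
#'
#' @param perSnapshot numeric matrix with one row per snapshot (M x p), or
#'   a list of equal-length numeric vectors.
#' @return Elementwise arithmetic mean, length p.
#' @examples
#' aggregateImportance(rbind(c(1, 0), c(0, 1)))  # c(0.5, 0.5)
#' @export
aggregateImportance <- function(perSnapshot) {
  if (is.list(perSnapshot)) {
    lens <- lengths(perSnapshot)
    if (length(unique(lens)) != 1) stop("importance vectors differ in length")
    perSnapshot <- do.call(rbind, perSnapshot)
  }
  colMeans(perSnapshot)
}

#' Connectivity category of each feature
#'
#' Features are sorted into the three-way taxonomy induced by the
#' polarized first layer: \emph{disconnected} when every weight is at most
#' \code{low} (the feature is filtered out entirely), \emph{full} when
#' every weight is at least \code{high}, and \emph{partial} otherwise
#' (element-wise sparsity).
#'
#' @param W1 first-layer weight matrix, one row per feature.
#' @param low,high category thresholds, 0 <= low < high <= 1.
#' @return Character vector in \{"disconnected", "partial", "full"\}.
#' @examples
#' categorizeFeatures(rbind(c(0.01, 0.03), c(0.95, 0.99), c(0.95, 0.02)))
#' @export
categorizeFeatures <- function(W1, low = 0.1, high = 0.9) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1")
  W1 <- as.matrix(W1)
  out <- rep("partial", nrow(W1))
  out[apply(W1 <= low, 1L, all)] <- "disconnected"
  out[apply(W1 >= high, 1L, all)] <- "full"
  names(out) <- rownames(W1)
  out
}

#' Build the full importance report for a snapshot ensemble
#'
#' Computes \code{\link{featureImportance}} on each snapshot's first layer
#' (each snapshot self-normalizes by its own maximum mean absolute
#' weight), averages across snapshots, fits the moments (mu, sigma) of the
#' aggregated distribution for the outlier policy, and categorizes each
#' feature from the elementwise mean of the absolute first-layer weights
#' across snapshots.
#'
#' @param ensemble a \linkS4class{SnapshotEnsemble}.
#' @param featureNames optional character vector naming the p input
#'   features.
#' @param low,high category thresholds passed to
#'   \code{\link{categorizeFeatures}}.
#' @return An \linkS4class{ImportanceReport}.
#' @export
importanceReport <- function(ensemble, featureNames = NULL,
                             low = 0.1, high = 0.9) {
  stopifnot(is(ensemble, "SnapshotEnsemble"))
  W1s <- lapply(ensemble@snapshots, function(s) s@weights[[1L]])
  p <- nrow(W1s[[1L]])
  if (is.null(featureNames)) featureNames <- rownames(W1s[[1L]])
  if (is.null(featureNames)) featureNames <- sprintf("f%d", seq_len(p))
  perSnapshot <- do.call(rbind, lapply(W1s, function(w) unname(featureImportance(w))))
  colnames(perSnapshot) <- featureNames
  agg <- colMeans(perSnapshot)
  meanW1 <- Reduce(`+`, lapply(W1s, abs)) / length(W1s)
  methods::new("ImportanceReport",
    perSnapshot = perSnapshot, aggregated = agg,
    featureNames = featureNames,
    mu = mean(agg), sigma = stats::sd(agg),
    categories = unname(categorizeFeatures(meanW1, low, high)))
}

#' Aggregated importance values of a report
#'
#' @param x an \linkS4class{ImportanceReport}.
#' @param ... unused.
#' @return Named numeric vector of aggregated Feature Sparsity Importance.
#' @rdname importanceValues
#' @export
setMethod("importanceValues", "ImportanceReport", function(x, ...) x@aggregated)

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport: %d features x %d snapshots\n",
              length(object@featureNames), nrow(object@perSnapshot)))
  cat(sprintf("  aggregated R: mu = %.4f, sigma = %.4f\n",
              object@mu, object@sigma))
  tab <- table(factor(object@categories,
                      levels = c("disconnected", "partial", "full")))
  cat(sprintf("  categories: %d disconnected / %d partial / %d full\n",
              tab[["disconnected"]], tab[["partial"]], tab[["full"]]))
  top <- utils::head(sort(object@aggregated, decreasing = TRUE), 5)
  cat("  top features:", paste(sprintf("%s (%.3f)", names(top), top),
                               collapse = ", "), "\n")
  invisible(object)
})

#' Export an importance report as a data.frame
#'
#' One row per feature: per-snapshot R values, the aggregated value and
#' the connectivity category. Suitable for writing as TSV.
#'
#' @param report an \linkS4class{ImportanceReport}.
#' @return data.frame.
#' @export
importanceTable <- function(report) {
  stopifnot(is(report, "ImportanceReport"))
  ps <- t(report@perSnapshot)
  colnames(ps) <- sprintf("R_snapshot%d", seq_len(ncol(ps)))
  data.frame(feature = report@featureNames, ps,
             aggregated = unname(report@aggregated),
             category = report@categories,
             row.names = NULL, stringsAsFactors = FALSE)
}
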