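.asImportanceVector <- function(x) {
  if (is(x, "ImportanceReport")) x <- x@aggregated
  if (is.null(names(x))) names(x) <- sprintf("f%d", seq_along(x))
  x
}

# descending importance, ties broken by ascending feature name
.rankOrder <- function(v) order(-v, names(v), method = "radix")

.newSelection <- function(policy, parameters, values) {
  methods::new("SelectionResult", policy = policy, parameters = parameters,
               selected = values)
}

#' Top-k feature selection
#'
#' The naive cutoff policy: keep the k features of largest aggregated
#' importance, ties broken by ascending feature name.
#'
#' @param x an \linkS4class{ImportanceReport} or a named importance vector.
#' @param k number of features to keep (1 <= k <= p).
#' @return A \linkS4class{SelectionResult}.
#' @examples
#' selectTopK(c(a = 0.9, b = 0.1, c = 0.5), k = 2)
#' @export
selectTopK <- function(x, k = 10L) {
  v <- .asImportanceVector(x)
  k <- as.integer(k)
  if (k < 1 || k > length(v)) stop("k must lie in [1, p]")
  ord <- .rankOrder(v)[seq_len(k)]
  .newSelection("top_k", list(k = k), v[ord])
}

#' Sigma-outlier feature selection
#'
#' Fits the sample mean and SD of the aggregated importance values (the
#' bulk of features forms a low-importance normal distribution) and keeps
#' features lying strictly above mu + nSigma * sigma. With sigma = 0 the
#' selection is empty (strict inequality).
#'
#' @param x an \linkS4class{ImportanceReport} or a named importance vector.
#' @param nSigma number of standard deviations (default 3).
#' @return A \linkS4class{SelectionResult}; parameters include the fitted
#'   mu, sigma and the implied threshold.
#' @export
selectOutliers <- function(x, nSigma = 3) {
  v <- .asImportanceVector(x)
  if (length(v) < 2) stop("need at least two features to fit a distribution")
  mu <- mean(v)
  sigma <- stats::sd(v)
  thr <- mu + nSigma * sigma
  keep <- v > thr
  ord <- .rankOrder(v)
  ord <- ord[keep[ord]]
  .newSelection("sigma_outlier",
                list(nSigma = nSigma, mu = mu, sigma = sigma, threshold = thr),
                v[ord])
}

#' Cumulative-importance feature selection
#'
#' Keeps the smallest prefix of the descending-sorted features whose
#' summed importance reaches \code{quantile} of the total. Negative
#' importance values are floored at 0 for this policy (they carry no
#' importance mass); with zero total importance the selection is empty.
#'
#' @param x an \linkS4class{ImportanceReport} or a named importance vector.
#' @param quantile cumulative cut-off in (0, 1), default 0.95.
#' @return A \linkS4class{SelectionResult}.
#' @examples
#' selectCumulative(c(a = 0.5, b = 0.3, c = 0.2), quantile = 0.79)  # a, b
#' @export
selectCumulative <- function(x, quantile = 0.95) {
  if (!(quantile > 0 && quantile < 1)) stop("quantile must lie in (0, 1)")
  v <- .asImportanceVector(x)
  v0 <- pmax(v, 0)
  total <- sum(v0)
  if (total == 0)
    return(.newSelection("cumulative", list(quantile = quantile), numeric(0)))
  ord <- .rankOrder(v0)
  cum <- cumsum(v0[ord])
  nKeep <- which(cum >= quantile * total - 1e-12)[1L]
  ord <- ord[seq_len(nKeep)]
  ord <- ord[v0[ord] > 0]                 # never select zero-mass features
  .newSelection("cumulative", list(quantile = quantile), v0[ord])
}

#' Selected feature names of a SelectionResult
#'
#' @param x a \linkS4class{SelectionResult}.
#' @param ... unused.
#' @return Character vector, ordered by descending importance.
#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x, ...) names(x@selected))

setMethod("show", "SelectionResult", function(object) {
  pars <- paste(names(object@parameters),
                vapply(object@parameters, function(p) format(p, digits = 4),
                       character(1)),
                sep = " = ", collapse = ", ")
  cat(sprintf("SelectionResult (%s; %s): %d feature(s)\n",
              object@policy, pars, length(object@selected)))
  if (length(object@selected)) {
    top <- utils::head(object@selected, 10)
    cat(" ", paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  }
  invisible(object)
})
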