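#' Generate a sparse synthetic coded-event cohort with planted signal
#'
#' Emulates the structure of a primary-care coded-event dataset: a
#' patient-by-event-code frequency table in which a patient uses only a tiny
#' subset of a large code vocabulary. Each cell is drawn as
#' occupancy ~ Bernoulli(1 - sparsity) times a positive count
#' 1 + Geometric(1/countDispersion) (mean countDispersion), so the expected
#' zero fraction of a background column equals \code{sparsity}; planted
#' columns use \code{plantedSparsity} instead, emulating the higher
#' prevalence of chronic-condition risk-factor codes. The binary
#' hospitalization label
#' follows a logistic model on the standardized counts of
#' \code{nInformative} planted features: a share
#' \code{interactionFraction} of them act only through pairwise products
#' (non-linear, multivariate signal), the rest as main effects with
#' alternating signs. The linear predictor is centred so the cohort is
#' roughly balanced, and scaled by \code{signalStrength};
#' \code{signalStrength = 0} makes labels independent of all features.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return An \linkS4class{EventMatrix} with labels and the planted feature
#'   names recorded in \code{\link{plantedFeatures}}.
#' @examples
#' cohort <- generateCohort(SimConfig(nPatients = 50, nFeatures = 100, seed = 1))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  n <- config@nPatients
  p <- config@nFeatures
  withr::local_seed(config@seed)

  geomProb <- min(1, 1 / config@countDispersion)
  occ <- stats::rbinom(n * p, 1L, 1 - config@sparsity)
  cts <- occ * (1L + stats::rgeom(n * p, geomProb))
  X <- matrix(as.numeric(cts), nrow = n, ncol = p)
  featNames <- sprintf("EC%05d", seq_len(p))
  dimnames(X) <- list(sprintf("patient_%04d", seq_len(n)), featNames)

  informative <- sort(sample.int(p, config@nInformative))
  if (config@nInformative > 0) {
    k <- config@nInformative
    occP <- stats::rbinom(n * k, 1L, 1 - config@plantedSparsity)
    X[, informative] <- occP * (1L + stats::rgeom(n * k, geomProb))
  }
  eta <- rep(0, n)
  if (config@nInformative > 0 && config@signalStrength > 0) {
    Z <- scale(X[, informative, drop = FALSE])
    Z[!is.finite(Z)] <- 0
    nInter <- 2L * (round(config@interactionFraction * config@nInformative) %/% 2L)
    interIdx <- seq_len(nInter)           # first nInter planted cols act in pairs
    mainIdx <- setdiff(seq_len(config@nInformative), interIdx)
    if (length(mainIdx)) {
      beta <- rep_len(c(1, -1), length(mainIdx))
      eta <- eta + as.vector(Z[, mainIdx, drop = FALSE] %*% beta)
    }
    if (nInter >= 2L) {
      a <- interIdx[seq(1L, nInter, by = 2L)]
      b <- interIdx[seq(2L, nInter, by = 2L)]
      eta <- eta + rowSums(Z[, a, drop = FALSE] * Z[, b, drop = FALSE])
    }
    eta <- config@signalStrength * (eta - mean(eta))
  }
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  EventMatrix(X, labels = y, planted = featNames[informative])
}

#' Tabulate a long-format event log into an EventMatrix
#'
#' One-hot frequency encoding: one column per distinct event code (sorted
#' lexicographically), one row per distinct patient id (sorted), cell =
#' total occurrence count over the log; duplicate (patient, code) records
#' are summed, absent pairs are zero. Labels are absent (NA) in the result.
#'
#' @param log data.frame with columns \code{patient_id}, \code{event_code},
#'   \code{count} (non-negative integers). See \code{\link{readEventLog}}.
#' @return An \linkS4class{EventMatrix} without outcome labels.
#' @examples
#' log <- data.frame(patient_id = c("pA", "pB", "pA"),
#'                   event_code = c("E00..", "bd3..", "E00.."),
#'                   count = c(2, 1, 1))
#' patientMatrix(encodeEvents(log), dense = TRUE)
#' @export
encodeEvents <- function(log) {
  req <- c("patient_id", "event_code", "count")
  if (!is.data.frame(log) || !all(req %in% names(log)))
    stop("log must be a data.frame with columns patient_id, event_code, count")
  if (nrow(log) == 0) stop("log must be non-empty")
  if (any(!is.finite(log$count)) || any(log$count < 0))
    stop("counts must be finite and non-negative")
  pid <- factor(log$patient_id, levels = sort(unique(as.character(log$patient_id))))
  code <- factor(log$event_code, levels = sort(unique(as.character(log$event_code))))
  cts <- Matrix::sparseMatrix(
    i = as.integer(pid), j = as.integer(code), x = as.numeric(log$count),
    dims = c(nlevels(pid), nlevels(code)),
    dimnames = list(levels(pid), levels(code))
  )
  EventMatrix(cts)
}

#' Per-feature min-max normalization to [0, 1]
#'
#' Scales each feature (column) to the unit interval. When
#' \code{referenceStats} is supplied (statistics fitted on the training
#' role), those minima/maxima are applied and out-of-range results are
#' clipped to [0, 1] -- the leakage-safe way to normalize validation and
#' test folds. Constant features map to all-zero.
#'
#' @param x patient x feature matrix of non-negative values (dense or
#'   sparse).
#' @param referenceStats optional value of the \code{stats} element of a
#'   previous call; feature names must match exactly.
#' @return list with \code{values} (dense numeric matrix in [0, 1]) and
#'   \code{stats} (data.frame: feature, min, max).
#' @examples
#' normalizeFeatures(cbind(f1 = c(0, 2, 4)))$values
#' @export
normalizeFeatures <- function(x, referenceStats = NULL) {
  X <- as.matrix(x)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (is.null(referenceStats)) {
    stats <- data.frame(
      feature = colnames(X),
      min = apply(X, 2L, min),
      max = apply(X, 2L, max),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    stats <- as.data.frame(referenceStats)
    if (!identical(stats$feature, colnames(X)))
      stop("referenceStats features do not match the matrix columns")
  }
  rng <- stats$max - stats$min
  scale <- ifelse(rng > 0, 1 / rng, 0)       # constant features -> all zero
  V <- sweep(X, 2L, stats$min, "-")
  V <- sweep(V, 2L, scale, "*")
  V[V < 0] <- 0
  V[V > 1] <- 1
  list(values = V, stats = stats)
}

#' Build a k-fold plan with cyclic train/validation/test roles
#'
#' Per repeat, patients are partitioned at random into k folds whose sizes
#' differ by at most one. Each of the k cyclic rotations designates one
#' fold as the test set, the next fold as validation, and the remaining
#' k - 2 folds as training data, yielding k x repeats evaluations.
#'
#' @param n number of patients.
#' @param k number of folds (>= 3, so all three roles exist).
#' @param repeats number of independent repartitions.
#' @param seed integer RNG seed.
#' @return A \linkS4class{FoldPlan}.
#' @examples
#' plan <- makeCVFolds(10, k = 5, repeats = 2, seed = 1)
#' foldAssignments(plan)[[1]][[1]]$test
#' @export
makeCVFolds <- function(n, k = 5L, repeats = 2L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 3) stop("k must be >= 3: train/validation/test roles need three folds")
  if (n < k) stop("n must be at least k")
  withr::local_seed(as.integer(seed))
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))    # sizes differ by <= 1
    evs <- vector("list", k)
    for (i in seq_len(k)) {
      testF <- i
      valF <- i %% k + 1L
      evs[[i]] <- list(
        train = which(!fold %in% c(testF, valF)),
        validation = which(fold == valF),
        test = which(fold == testF)
      )
    }
    assignments[[r]] <- evs
  }
  methods::new("FoldPlan", assignments = assignments, k = k,
               repeats = repeats, n = n, seed = as.integer(seed))
}

#' Fold-role assignments of a FoldPlan
#'
#' @param x a \linkS4class{FoldPlan}.
#' @param ... unused.
#' @return Nested list: \code{[[repeat]][[fold]]} with integer vectors
#'   \code{train}, \code{validation}, \code{test}.
#' @rdname foldAssignments
#' @export
setMethod("foldAssignments", "FoldPlan", function(x, ...) x@assignments)

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d patients, %d folds x %d repeats (%d evaluations), seed %d\n",
              object@n, object@k, object@repeats,
              object@k * object@repeats, object@seed))
  invisible(object)
})
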