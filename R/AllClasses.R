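#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' EventMatrix: a patient-by-event-code count matrix with outcomes
#'
#' Container for sparse coded-event cohorts. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"counts"} assay holds event
#' codes in rows and patients in columns (Bioconductor orientation), the
#' binary outcome lives in \code{colData(x)$label}, and the names of any
#' planted (simulated signal) features are kept in
#' \code{metadata(x)$planted}. Modeling code works on the transposed
#' patient-by-feature view returned by \code{\link{patientMatrix}}.
#'
#' @slot .
#'   Inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{encodeEvents}},
#'   \code{\link{readEventMatrix}}
#' @exportClass EventMatrix
setClass("EventMatrix", contains = "SummarizedExperiment")

.validEventMatrix <- function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    neg <- if (is(cts, "sparseMatrix")) any(cts@x < 0) else any(cts < 0)
    if (isTRUE(neg)) msg <- c(msg, "counts must be non-negative")
  }
  fn <- rownames(object)
  if (is.null(fn) || anyDuplicated(fn))
    msg <- c(msg, "feature names (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'label' column")
  else {
    lab <- cd$label
    bad <- !is.na(lab) & !(lab %in% c(0, 1))
    if (any(bad)) msg <- c(msg, "labels must be 0, 1 or NA")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("EventMatrix", .validEventMatrix)

#' Simulation configuration for synthetic coded-event cohorts
#'
#' Parameters of the synthetic cohort generator (see
#' \code{\link{generateCohort}} for the generative model). Defaults describe
#' a desk-scale analogue of a primary-care cohort: a few thousand patients,
#' hundreds of one-hot event-code features, extreme sparsity, and a small
#' planted subset of features carrying the hospitalization signal.
#'
#' @slot nPatients integer, cohort size.
#' @slot nFeatures integer, vocabulary size (number of event codes).
#' @slot nInformative integer, number of planted signal features.
#' @slot sparsity expected fraction of zero cells, in [0, 1).
#' @slot plantedSparsity zero-cell fraction of the planted columns; planted
#'   risk factors emulate common chronic-condition codes, far more
#'   prevalent than the background vocabulary (default 0.7, i.e. 30%
#'   prevalence).
#' @slot signalStrength non-negative scale of the planted log-odds; 0 makes
#'   the label independent of every feature.
#' @slot interactionFraction fraction of planted features acting only
#'   through pairwise products.
#' @slot countDispersion mean of the positive (geometric) count component.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nPatients = "integer", nFeatures = "integer", nInformative = "integer",
    sparsity = "numeric", plantedSparsity = "numeric",
    signalStrength = "numeric",
    interactionFraction = "numeric", countDispersion = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@nInformative > object@nFeatures)
    msg <- c(msg, "nInformative must not exceed nFeatures")
  if (object@sparsity < 0 || object@sparsity >= 1)
    msg <- c(msg, "sparsity must lie in [0, 1)")
  if (object@plantedSparsity < 0 || object@plantedSparsity >= 1)
    msg <- c(msg, "plantedSparsity must lie in [0, 1)")
  if (object@signalStrength < 0)
    msg <- c(msg, "signalStrength must be >= 0")
  if (object@interactionFraction < 0 || object@interactionFraction > 1)
    msg <- c(msg, "interactionFraction must lie in [0, 1]")
  if (object@countDispersion <= 0)
    msg <- c(msg, "countDispersion must be > 0")
  if (object@nPatients < 1 || object@nFeatures < 1)
    msg <- c(msg, "nPatients and nFeatures must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for \linkS4class{SimConfig}
#'
#' @param nPatients,nFeatures,nInformative cohort dimensions.
#' @param sparsity expected zero-cell fraction in [0, 1).
#' @param plantedSparsity zero-cell fraction of the planted columns
#'   (default 0.7: common risk-factor codes).
#' @param signalStrength planted log-odds scale (0 = null cohort).
#' @param interactionFraction share of planted features acting only in
#'   pairwise interaction terms.
#' @param countDispersion mean of the positive count component.
#' @param seed integer RNG seed.
#' @return A \code{SimConfig} object.
#' @examples
#' SimConfig(nPatients = 50, nFeatures = 100, seed = 1)
#' @export
SimConfig <- function(nPatients = 2000L, nFeatures = 500L,
                      nInformative = 10L, sparsity = 0.95,
                      plantedSparsity = 0.7,
                      signalStrength = 2, interactionFraction = 0.2,
                      countDispersion = 1.5, seed = 1L) {
  new("SimConfig",
    nPatients = as.integer(nPatients), nFeatures = as.integer(nFeatures),
    nInformative = as.integer(nInformative), sparsity = as.numeric(sparsity),
    plantedSparsity = as.numeric(plantedSparsity),
    signalStrength = as.numeric(signalStrength),
    interactionFraction = as.numeric(interactionFraction),
    countDispersion = as.numeric(countDispersion), seed = as.integer(seed)
  )
}

#' Cross-validation fold plan with train/validation/test roles
#'
#' A partition of patients into k folds per repeat, with the k cyclic role
#' rotations: each fold serves as the test set exactly once per repeat, the
#' next fold in the cycle as validation, and the remaining k-2 folds as
#' training data.
#'
#' @slot assignments nested list: \code{assignments[[r]][[f]]} is a list with
#'   integer vectors \code{train}, \code{validation}, \code{test}.
#' @slot k integer number of folds (>= 3).
#' @slot repeats integer number of repeats.
#' @slot n integer number of patients partitioned.
#' @slot seed integer RNG seed used to build the partition.
#' @seealso \code{\link{makeCVFolds}}
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(assignments = "list", k = "integer", repeats = "integer",
                 n = "integer", seed = "integer")
)

setValidity("FoldPlan", function(object) {
  msg <- NULL
  if (object@k < 3) msg <- c(msg, "k must be >= 3")
  if (length(object@assignments) != object@repeats)
    msg <- c(msg, "one assignment set per repeat required")
  for (r in seq_along(object@assignments)) {
    evs <- object@assignments[[r]]
    if (length(evs) != object@k) {
      msg <- c(msg, "k evaluations per repeat required")
      next
    }
    tested <- sort(unlist(lapply(evs, `[[`, "test")))
    if (!identical(tested, seq_len(object@n)))
      msg <- c(msg, sprintf("repeat %d: each patient must be tested exactly once", r))
    for (ev in evs) {
      all_idx <- c(ev$train, ev$validation, ev$test)
      if (anyDuplicated(all_idx) || length(all_idx) != object@n)
        msg <- c(msg, "train/validation/test roles must partition all patients")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Feed-forward network parameters with bounded first layer
#'
#' Layered weights and biases of the classifier. \code{weights[[l]]} maps
#' layer l-1 activations to layer l pre-activations (so \code{weights[[1]]}
#' is the p x J1 input weight matrix whose row k holds the weights fanning
#' out of feature k). First-layer entries are kept inside [0, 1] by
#' projection after every optimizer step.
#'
#' @slot weights list of numeric matrices, one per layer.
#' @slot biases list of numeric vectors, one per layer.
#' @slot layerSizes integer vector, e.g. c(p, 50, 30, 1).
#' @slot hiddenActivation "relu" or "linear".
#' @seealso \code{\link{initNetwork}}, \code{\link{forwardPass}}
#' @exportClass NetworkParams
setClass("NetworkParams",
  representation(weights = "list", biases = "list", layerSizes = "integer",
                 hiddenActivation = "character")
)

setValidity("NetworkParams", function(object) {
  msg <- NULL
  L <- length(object@layerSizes) - 1L
  if (length(object@weights) != L || length(object@biases) != L)
    return("weights/biases must have one entry per non-input layer")
  for (l in seq_len(L)) {
    W <- object@weights[[l]]
    if (!all(dim(W) == object@layerSizes[c(l, l + 1L)]))
      msg <- c(msg, sprintf("layer %d weight shape mismatch", l))
    if (length(object@biases[[l]]) != object@layerSizes[l + 1L])
      msg <- c(msg, sprintf("layer %d bias length mismatch", l))
  }
  W1 <- object@weights[[1L]]
  if (any(W1 < -1e-8) || any(W1 > 1 + 1e-8))
    msg <- c(msg, "first-layer weights must lie in [0, 1]")
  if (!object@hiddenActivation %in% c("relu", "linear"))
    msg <- c(msg, "hiddenActivation must be 'relu' or 'linear'")
  if (is.null(msg)) TRUE else msg
})

#' Training configuration
#'
#' All tunable knobs of entropy-regularized snapshot training. The hidden
#' architecture default (50 and 30 units) follows the method's reference
#' configuration; the schedule defaults (T = 100 epochs, M = 5 snapshots,
#' alpha0 = 0.1, lambda = 0.01, batch 128) are package defaults, surfaced
#' here so every run records them.
#'
#' @slot hiddenSizes integer vector of hidden layer widths.
#' @slot lambda entropy-penalty coefficient (>= 0).
#' @slot alpha0 initial learning rate (> 0).
#' @slot nEpochs total training epochs T.
#' @slot nSnapshots number of cosine cycles / snapshots M (M <= T).
#' @slot batchSize mini-batch size.
#' @slot hiddenActivation "relu" (default) or "linear".
#' @slot seed integer RNG seed.
#' @slot cvK folds for cross-validation.
#' @slot cvRepeats CV repeats.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    hiddenSizes = "integer", lambda = "numeric", alpha0 = "numeric",
    nEpochs = "integer", nSnapshots = "integer", batchSize = "integer",
    hiddenActivation = "character", seed = "integer",
    cvK = "integer", cvRepeats = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- NULL
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@alpha0 <= 0) msg <- c(msg, "alpha0 must be > 0")
  if (object@nEpochs < 1 || object@nSnapshots < 1)
    msg <- c(msg, "nEpochs and nSnapshots must be >= 1")
  if (object@nSnapshots > object@nEpochs)
    msg <- c(msg, "nSnapshots must not exceed nEpochs")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (!object@hiddenActivation %in% c("relu", "linear"))
    msg <- c(msg, "hiddenActivation must be 'relu' or 'linear'")
  if (object@cvK < 3) msg <- c(msg, "cvK must be >= 3")
  if (object@cvRepeats < 1) msg <- c(msg, "cvRepeats must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Constructor for \linkS4class{TrainConfig}
#'
#' @param hiddenSizes hidden layer widths (default \code{c(50, 30)}).
#' @param lambda entropy-penalty coefficient.
#' @param alpha0 initial learning rate of the cosine schedule.
#' @param nEpochs total epochs T.
#' @param nSnapshots snapshots/cycles M.
#' @param batchSize mini-batch size.
#' @param hiddenActivation hidden-unit activation, "relu" or "linear".
#' @param seed integer RNG seed.
#' @param cvK,cvRepeats cross-validation geometry.
#' @return A \code{TrainConfig} object.
#' @examples
#' TrainConfig(nEpochs = 20, nSnapshots = 2, seed = 7)
#' @export
TrainConfig <- function(hiddenSizes = c(50L, 30L), lambda = 0.01,
                        alpha0 = 0.1, nEpochs = 100L, nSnapshots = 5L,
                        batchSize = 128L, hiddenActivation = "relu",
                        seed = 1L, cvK = 5L, cvRepeats = 2L) {
  new("TrainConfig",
    hiddenSizes = as.integer(hiddenSizes), lambda = as.numeric(lambda),
    alpha0 = as.numeric(alpha0), nEpochs = as.integer(nEpochs),
    nSnapshots = as.integer(nSnapshots), batchSize = as.integer(batchSize),
    hiddenActivation = hiddenActivation, seed = as.integer(seed),
    cvK = as.integer(cvK), cvRepeats = as.integer(cvRepeats)
  )
}

#' Snapshot ensemble produced by one cyclic-cosine training run
#'
#' @slot snapshots list of M \linkS4class{NetworkParams}, one per cosine
#'   cycle, captured at the final epoch of the cycle.
#' @slot schedule list with alpha0, nEpochs, nSnapshots, cycleLength.
#' @slot history data.frame with one row per epoch: epoch, lr, trainLoss,
#'   trainCrossEntropy, valLoss (NA when no validation data was supplied).
#' @slot config the \linkS4class{TrainConfig} that produced the run.
#' @seealso \code{\link{trainSnapshots}}, \code{\link{ensemblePredict}}
#' @exportClass SnapshotEnsemble
setClass("SnapshotEnsemble",
  representation(snapshots = "list", schedule = "list",
                 history = "data.frame", config = "TrainConfig")
)

setValidity("SnapshotEnsemble", function(object) {
  msg <- NULL
  if (length(object@snapshots) != object@schedule$nSnapshots)
    msg <- c(msg, "snapshot count must equal the scheduled M")
  if (!all(vapply(object@snapshots, is, logical(1), "NetworkParams")))
    msg <- c(msg, "snapshots must be NetworkParams objects")
  if (is.null(msg)) TRUE else msg
})

#' Feature Sparsity Importance report
#'
#' Per-snapshot and aggregated Feature Sparsity Importance values
#' (R_k = (mean|W1_k| - var|W1_k|) / max_k mean|W1_k|, self-normalized per
#' snapshot), the moment fit of the aggregated distribution, and the
#' disconnected/partial/full connectivity category of each feature.
#'
#' @slot perSnapshot M x p numeric matrix of per-snapshot R_k values.
#' @slot aggregated named length-p numeric vector, column mean of perSnapshot.
#' @slot featureNames length-p character.
#' @slot mu,sigma sample mean and SD of the aggregated values.
#' @slot categories length-p character in {"disconnected","partial","full"}.
#' @seealso \code{\link{importanceReport}}, \code{\link{featureImportance}}
#' @exportClass ImportanceReport
setClass("ImportanceReport",
  representation(perSnapshot = "matrix", aggregated = "numeric",
                 featureNames = "character", mu = "numeric",
                 sigma = "numeric", categories = "character")
)

setValidity("ImportanceReport", function(object) {
  p <- length(object@featureNames)
  msg <- NULL
  if (ncol(object@perSnapshot) != p)
    msg <- c(msg, "perSnapshot must have one column per feature")
  if (length(object@aggregated) != p || length(object@categories) != p)
    msg <- c(msg, "aggregated/categories length must match featureNames")
  if (max(abs(object@aggregated - colMeans(object@perSnapshot))) > 1e-8)
    msg <- c(msg, "aggregated must be the column mean of perSnapshot")
  if (is.null(msg)) TRUE else msg
})

#' Result of a feature-selection policy
#'
#' @slot policy one of "top_k", "sigma_outlier", "cumulative", or the name
#'   of a baseline ranking.
#' @slot parameters named list of the policy's parameters.
#' @slot selected named numeric vector of importance values, ordered by
#'   descending importance (ties broken by ascending feature name).
#' @seealso \code{\link{selectTopK}}, \code{\link{selectOutliers}},
#'   \code{\link{selectCumulative}}
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(policy = "character", parameters = "list",
                 selected = "numeric")
)

setValidity("SelectionResult", function(object) {
  s <- object@selected
  if (length(s) > 1 && any(diff(s) > 1e-12))
    return("selected values must be in descending order")
  TRUE
})
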