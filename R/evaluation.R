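#' Confusion-matrix metrics of a binary classifier
#'
#' Counts TP/FP/TN/FN and derives accuracy, sensitivity (TPR), specificity
#' (TNR), positive and negative predictive value, and F1. Ratios with a
#' zero denominator are reported as NaN, never silently as 0 -- an
#' always-positive "inactive" model therefore shows TPR 1, TNR 0 and an
#' NaN NPV rather than a fabricated score.
#'
#' @param yTrue,yPred equal-length 0/1 vectors.
#' @return list with \code{counts} (named TP, FP, TN, FN) and
#'   \code{metrics} (named accuracy, tpr, tnr, ppv, npv, f1).
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))$metrics
#' @export
confusionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    stop("labels must be 0/1")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  tn <- sum(yTrue == 0 & yPred == 0)
  fn <- sum(yTrue == 1 & yPred == 0)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = c(
      accuracy = ratio(tp + tn, tp + fp + tn + fn),
      tpr = ratio(tp, tp + fn),
      tnr = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      npv = ratio(tn, tn + fn),
      f1 = ratio(2 * tp, 2 * tp + fp + fn)
    )
  )
}

.metricNames <- c("accuracy", "tpr", "tnr", "ppv", "npv", "f1")

.evalSeed <- function(seed, r, f) {
  as.integer((as.numeric(seed) + 7919 * r + 104729 * f) %% 2147483646) + 1L
}

#' Cross-validated training and evaluation
#'
#' Runs the full k-fold x repeats evaluation: for every rotation,
#' normalization statistics are fitted on the training role only and
#' applied to the validation and test roles, a snapshot ensemble is
#' trained, and the averaged ensemble prediction is scored on the test
#' role. When \code{featureSubset} is given, all stages see only those
#' columns.
#'
#' @param x an \linkS4class{EventMatrix} with complete 0/1 labels.
#' @param config a \linkS4class{TrainConfig} (cvK and cvRepeats set the
#'   plan geometry; the plan and every per-evaluation training seed derive
#'   from \code{config@seed}).
#' @param featureSubset optional character vector of event codes to
#'   restrict the model to; unknown names are an error.
#' @param foldPlan optional pre-built \linkS4class{FoldPlan}; pass the same
#'   plan to two runs to compare them fold-by-fold (paired tests).
#' @return A \code{CVResults} list: \code{perEvaluation} (one row per
#'   evaluation with counts and metrics), \code{aggregate} (mean and SD
#'   per metric over evaluations, NaN rows excluded with the excluded
#'   count in \code{nDroppedNaN}), \code{foldPlan}, \code{config}.
#' @export
runCV <- function(x, config = TrainConfig(), featureSubset = NULL,
                  foldPlan = NULL) {
  stopifnot(is(x, "EventMatrix"))
  y <- outcomeLabels(x)
  if (any(is.na(y))) stop("all patients need a 0/1 outcome label for CV")
  raw <- patientMatrix(x, features = featureSubset, dense = TRUE)
  n <- nrow(raw)
  if (is.null(foldPlan))
    foldPlan <- makeCVFolds(n, config@cvK, config@cvRepeats, seed = config@seed)
  stopifnot(is(foldPlan, "FoldPlan"), foldPlan@n == n)

  rows <- list()
  for (r in seq_len(foldPlan@repeats)) {
    for (f in seq_len(foldPlan@k)) {
      roles <- foldPlan@assignments[[r]][[f]]
      norm <- normalizeFeatures(raw[roles$train, , drop = FALSE])
      xTr <- norm$values
      xVa <- normalizeFeatures(raw[roles$validation, , drop = FALSE],
                               referenceStats = norm$stats)$values
      xTe <- normalizeFeatures(raw[roles$test, , drop = FALSE],
                               referenceStats = norm$stats)$values
      cfg <- config
      cfg@seed <- .evalSeed(config@seed, r, f)
      ens <- trainSnapshots(xTr, y[roles$train], xVa, y[roles$validation], cfg)
      pred <- ensemblePredict(ens, xTe)
      cm <- confusionMetrics(y[roles$test], pred$label)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, t(cm$counts), t(cm$metrics))
    }
  }
  perEval <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(.metricNames, function(m) {
    v <- perEval[[m]]
    ok <- is.finite(v)
    data.frame(metric = m, mean = mean(v[ok]), sd = stats::sd(v[ok]),
               nDroppedNaN = sum(!ok))
  }))
  structure(list(perEvaluation = perEval, aggregate = agg,
                 foldPlan = foldPlan, config = config),
            class = "CVResults")
}

#' @export
print.CVResults <- function(x, ...) {
  cat(sprintf("CVResults: %d evaluations (%d folds x %d repeats)\n",
              nrow(x$perEvaluation), x$foldPlan@k, x$foldPlan@repeats))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-8s %.4f (SD %.4f)%s\n", agg$metric[i], agg$mean[i],
                agg$sd[i],
                if (agg$nDroppedNaN[i] > 0)
                  sprintf("  [%d NaN evaluation(s) excluded]", agg$nDroppedNaN[i])
                else ""))
  invisible(x)
}

#' Aggregate accuracy of a CVResults object
#' @param cv a \code{CVResults} list from \code{\link{runCV}}.
#' @return Mean test accuracy over evaluations.
#' @export
cvAccuracy <- function(cv) {
  cv$aggregate$mean[cv$aggregate$metric == "accuracy"]
}

#' Backward-stepwise refinement of a feature subset
#'
#' Greedy elimination on validation-role accuracy: at every step each
#' remaining feature's removal is scored by retraining without it, and the
#' feature whose removal least degrades (or most improves) accuracy is
#' dropped -- as long as the best candidate stays within \code{tol} of the
#' current accuracy. The data are split once into train/validation/test
#' roles (first rotation of a fold plan built from \code{config}); the
#' test role is never touched.
#'
#' @param x an \linkS4class{EventMatrix} with complete labels.
#' @param initialSubset character vector of event codes (length >= 2).
#' @param config a \linkS4class{TrainConfig}; every candidate retraining
#'   uses the same seed so comparisons are paired.
#' @param tol accuracy tolerance for continuing elimination
#'   (default 0.002).
#' @return list with \code{subset} (surviving event codes) and
#'   \code{trace} (data.frame: step, dropped, accuracy, nFeatures).
#' @export
backwardStepwise <- function(x, initialSubset, config = TrainConfig(),
                             tol = 0.002) {
  stopifnot(is(x, "EventMatrix"))
  if (length(initialSubset) < 2)
    stop("initialSubset must contain at least two features")
  unknown <- setdiff(initialSubset, eventCodes(x))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  y <- outcomeLabels(x)
  if (any(is.na(y))) stop("all patients need a 0/1 outcome label")
  raw <- patientMatrix(x, dense = TRUE)
  plan <- makeCVFolds(nrow(raw), config@cvK, 1L, seed = config@seed)
  roles <- plan@assignments[[1L]][[1L]]

  valAccuracy <- function(subset) {
    sub <- raw[, subset, drop = FALSE]
    norm <- normalizeFeatures(sub[roles$train, , drop = FALSE])
    xTr <- norm$values
    xVa <- normalizeFeatures(sub[roles$validation, , drop = FALSE],
                             referenceStats = norm$stats)$values
    ens <- trainSnapshots(xTr, y[roles$train], config = config)
    pred <- ensemblePredict(ens, xVa)
    mean(pred$label == y[roles$validation])
  }

  current <- initialSubset
  acc <- valAccuracy(current)
  trace <- data.frame(step = 0L, dropped = NA_character_, accuracy = acc,
                      nFeatures = length(current), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 1L) {
    candAcc <- vapply(current,
                      function(feat) valAccuracy(setdiff(current, feat)),
                      numeric(1))
    best <- which.max(candAcc)
    if (candAcc[best] < acc - tol) break   # every removal degrades too much
    step <- step + 1L
    dropped <- current[best]
    current <- setdiff(current, dropped)
    acc <- candAcc[best]
    trace <- rbind(trace, data.frame(step = step, dropped = dropped,
                                     accuracy = acc,
                                     nFeatures = length(current),
                                     stringsAsFactors = FALSE))
  }
  list(subset = current, trace = trace)
}

#' Uniform random feature subset
#'
#' Baseline selection: k features sampled without replacement from the
#' vocabulary.
#'
#' @param p vocabulary size.
#' @param k subset size (0 <= k <= p).
#' @param seed integer RNG seed.
#' @return Integer vector of k feature indices.
#' @export
randomSubset <- function(p, k, seed = 1L) {
  if (k > p) stop("k must not exceed p")
  if (k == 0) return(integer(0))
  withr::local_seed(as.integer(seed))
  sample.int(p, k)
}

#' Pearson correlation between a feature and the outcome
#'
#' Standard product-moment r with a two-sided p-value; for two binary
#' vectors this is the phi coefficient.
#'
#' @param feature numeric vector (length >= 3, non-constant).
#' @param labels numeric/binary vector, same length, non-constant.
#' @return list with \code{r} and \code{p.value}.
#' @export
pearsonFeatureCorrelation <- function(feature, labels) {
  if (length(feature) != length(labels)) stop("inputs differ in length")
  if (length(feature) < 3) stop("need at least three observations")
  if (stats::sd(feature) == 0 || stats::sd(labels) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(feature, labels, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Paired two-sided t-test over CV evaluations
#'
#' Compares two per-evaluation metric vectors paired by (repeat, fold).
#' Zero variance of the differences (including identical vectors) leaves
#' the statistic undefined and is an error by contract.
#'
#' @param metricsA,metricsB equal-length numeric vectors (length >= 2).
#' @return list with \code{t} and \code{p.value}.
#' @export
pairedTTest <- function(metricsA, metricsB) {
  if (length(metricsA) != length(metricsB)) stop("inputs differ in length")
  if (length(metricsA) < 2) stop("need at least two paired evaluations")
  d <- metricsA - metricsB
  if (stats::sd(d) == 0)
    stop("degenerate case: paired differences have zero variance")
  tt <- stats::t.test(metricsA, metricsB, paired = TRUE)
  list(t = unname(tt$statistic), p.value = tt$p.value)
}
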