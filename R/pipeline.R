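#' Run the full four-stage analysis pipeline
#'
#' End-to-end driver mirroring the method's intended use on a cohort:
#' \enumerate{
#'   \item cross-validated snapshot training on the full vocabulary;
#'   \item entropy-regularized training on the train+validation roles of
#'     the first rotation, yielding the Feature Sparsity Importance
#'     report (the test role never informs ranking);
#'   \item feature selection under the three policies (top-k, 3-sigma
#'     outlier, cumulative 95\%);
#'   \item re-evaluation of the selected subset -- and of an equal-sized
#'     random subset baseline -- by the same cross-validation plan, so
#'     comparisons are paired fold-by-fold.
#' }
#'
#' @param x an \linkS4class{EventMatrix} with complete 0/1 labels.
#' @param config a \linkS4class{TrainConfig}.
#' @param outDir optional directory; when given, writes
#'   \code{cv_results.json}, \code{importance_report.tsv},
#'   \code{selections.json}, \code{comparison_table.tsv} and
#'   \code{manifest.json}.
#' @param policy which selection defines the re-evaluated subset:
#'   "top_k" (default), "sigma_outlier" or "cumulative".
#' @param k subset size for the top-k policy (default 10).
#' @return list with \code{cvFull}, \code{cvReduced}, \code{cvRandom},
#'   \code{report} (\linkS4class{ImportanceReport}), \code{selections}
#'   (list of \linkS4class{SelectionResult}), \code{subset},
#'   \code{comparison} (data.frame of aggregate metrics per run).
#' @export
runPipeline <- function(x, config = TrainConfig(), outDir = NULL,
                        policy = c("top_k", "sigma_outlier", "cumulative"),
                        k = 10L) {
  policy <- match.arg(policy)
  stopifnot(is(x, "EventMatrix"))
  y <- outcomeLabels(x)
  if (any(is.na(y))) stop("all patients need a 0/1 outcome label")
  raw <- patientMatrix(x, dense = TRUE)
  plan <- makeCVFolds(nrow(raw), config@cvK, config@cvRepeats,
                      seed = config@seed)

  cvFull <- runCV(x, config, foldPlan = plan)

  roles <- plan@assignments[[1L]][[1L]]
  norm <- normalizeFeatures(raw[roles$train, , drop = FALSE])
  xVa <- normalizeFeatures(raw[roles$validation, , drop = FALSE],
                           referenceStats = norm$stats)$values
  ens <- trainSnapshots(norm$values, y[roles$train], xVa, y[roles$validation],
                        config)
  report <- importanceReport(ens, featureNames = colnames(raw))
  selections <- list(
    top_k = selectTopK(report, k = min(k, ncol(raw))),
    sigma_outlier = selectOutliers(report, nSigma = 3),
    cumulative = selectCumulative(report, quantile = 0.95)
  )
  subset <- selectedFeatures(selections[[policy]])
  cvReduced <- if (length(subset) >= 1)
    runCV(x, config, featureSubset = subset, foldPlan = plan) else NULL
  cvRandom <- if (length(subset) >= 1) {
    rnd <- colnames(raw)[randomSubset(ncol(raw), length(subset),
                                      seed = config@seed)]
    runCV(x, config, featureSubset = rnd, foldPlan = plan)
  } else NULL

  rows <- list(cbind(run = "full", cvFull$aggregate))
  if (!is.null(cvReduced))
    rows <- c(rows, list(cbind(run = "reduced", cvReduced$aggregate)))
  if (!is.null(cvRandom))
    rows <- c(rows, list(cbind(run = "random", cvRandom$aggregate)))
  comparison <- do.call(rbind, rows)

  out <- list(cvFull = cvFull, cvReduced = cvReduced, cvRandom = cvRandom,
              report = report, selections = selections, subset = subset,
              comparison = comparison)
  if (!is.null(outDir)) .writePipelineOutputs(out, x, config, outDir)
  out
}

.selectionAsList <- function(sel) {
  list(policy = sel@policy, parameters = sel@parameters,
       features = as.list(sel@selected))
}

.writePipelineOutputs <- function(out, x, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cvAsList <- function(cv) if (is.null(cv)) NULL else
    list(perEvaluation = cv$perEvaluation, aggregate = cv$aggregate)
  jsonlite::write_json(
    list(full = cvAsList(out$cvFull), reduced = cvAsList(out$cvReduced),
         random = cvAsList(out$cvRandom)),
    file.path(outDir, "cv_results.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(importanceTable(out$report),
                     file.path(outDir, "importance_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mu = out$report@mu, sigma = out$report@sigma,
         selections = lapply(out$selections, .selectionAsList),
         subset = out$subset),
    file.path(outDir, "selections.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(out$comparison,
                     file.path(outDir, "comparison_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(package = "ecnn",
         version = as.character(utils::packageVersion("ecnn")),
         nPatients = ncol(x), nFeatures = nrow(x),
         config = list(
           hiddenSizes = config@hiddenSizes, lambda = config@lambda,
           alpha0 = config@alpha0, nEpochs = config@nEpochs,
           nSnapshots = config@nSnapshots, batchSize = config@batchSize,
           hiddenActivation = config@hiddenActivation, seed = config@seed,
           cvK = config@cvK, cvRepeats = config@cvRepeats)),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
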