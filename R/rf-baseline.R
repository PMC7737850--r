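#' Random-forest permutation-importance baseline ranking
#'
#' The traditional comparator: a random-forest classifier with
#' permutation importance (accuracy drop under feature perturbation).
#' No forest implementation ships with this package's R dependency set,
#' so the fit is delegated to the scikit-learn installation found on the
#' PATH (\code{python}); the returned vector plugs into the same selection
#' policies as the network's own ranking
#' (\code{\link{selectTopK}}, \code{\link{selectOutliers}}).
#'
#' @param x an \linkS4class{EventMatrix} with complete 0/1 labels
#'   containing both classes.
#' @param nTrees number of trees (default 500).
#' @param seed integer seed passed to the forest and the permutation.
#' @param nPermutations permutation repeats per feature (default 5).
#' @return Named numeric vector of mean permutation importances, one per
#'   feature, in vocabulary order.
#' @export
rfBaselineRanking <- function(x, nTrees = 500L, seed = 1L, nPermutations = 5L) {
  stopifnot(is(x, "EventMatrix"))
  y <- outcomeLabels(x)
  if (any(is.na(y))) stop("all patients need a 0/1 outcome label")
  if (length(unique(y)) < 2)
    stop("labels are single-class: a classifier baseline is undefined")
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("no 'python' interpreter with scikit-learn found on the PATH")

  X <- patientMatrix(x, dense = TRUE)
  inFile <- tempfile(fileext = ".csv")
  outFile <- tempfile(fileext = ".csv")
  scriptFile <- tempfile(fileext = ".py")
  on.exit(unlink(c(inFile, outFile, scriptFile)), add = TRUE)
  df <- as.data.frame(X)
  df[[".label."]] <- y
  utils::write.csv(df, inFile, row.names = FALSE)
  writeLines(c(
    "import sys",
    "import pandas as pd",
    "from sklearn.ensemble import RandomForestClassifier",
    "from sklearn.inspection import permutation_importance",
    "inp, outp, seed, ntrees, nrep = sys.argv[1:6]",
    "data = pd.read_csv(inp)",
    "y = data.pop('.label.').values",
    "rf = RandomForestClassifier(n_estimators=int(ntrees),",
    "                            random_state=int(seed), n_jobs=1)",
    "rf.fit(data.values, y)",
    "pi = permutation_importance(rf, data.values, y, n_repeats=int(nrep),",
    "                            random_state=int(seed), n_jobs=1)",
    "pd.DataFrame({'feature': data.columns,",
    "              'importance': pi.importances_mean}).to_csv(outp, index=False)"
  ), scriptFile)
  status <- system2(py, c(scriptFile, inFile, outFile, as.integer(seed),
                          as.integer(nTrees), as.integer(nPermutations)),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(outFile))
    stop("scikit-learn random-forest baseline failed (exit status ", status, ")")
  res <- utils::read.csv(outFile, stringsAsFactors = FALSE)
  stats::setNames(res$importance, colnames(X))
}
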