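#' Read a long-format event log
#'
#' TSV with header columns \code{patient_id}, \code{event_code},
#' \code{count}; one row per (patient, code) observation. Feed the result
#' to \code{\link{encodeEvents}}.
#'
#' @param path file path.
#' @return data.frame with the three columns, counts validated
#'   non-negative.
#' @export
readEventLog <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  log <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "event_code", "count")
  missing <- setdiff(req, names(log))
  if (length(missing))
    stop(path, " is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(log$count)) || any(log$count < 0))
    stop(path, " contains negative or non-finite counts")
  log[req]
}

#' Write an EventMatrix to disk
#'
#' Two on-disk dialects share one reader/writer pair:
#' \itemize{
#'   \item a directory holding \code{counts.mtx} (MatrixMarket, patients in
#'     rows), \code{features.tsv} (column \code{feature}) and
#'     \code{patients.tsv} (columns \code{patient_id}, \code{label});
#'   \item a single dense TSV (\code{.tsv} path) with columns
#'     \code{patient_id}, \code{label}, then one column per event code --
#'     meant for tiny fixtures only.
#' }
#' Planted feature names, when present, are written as
#' \code{planted.tsv} next to the matrix (directory dialect only).
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param path output directory (MatrixMarket dialect) or a \code{.tsv}
#'   file path (dense dialect).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEventMatrix}}
#' @export
writeEventMatrix <- function(x, path) {
  stopifnot(is(x, "EventMatrix"))
  m <- patientMatrix(x)
  lab <- outcomeLabels(x)
  if (grepl("\\.tsv$", path)) {
    df <- data.frame(patient_id = rownames(m), label = lab,
                     as.matrix(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(path, "counts.mtx"))
  utils::write.table(data.frame(feature = colnames(m)),
                     file.path(path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(patient_id = rownames(m), label = lab),
                     file.path(path, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pl <- plantedFeatures(x)
  if (length(pl))
    utils::write.table(data.frame(feature = pl),
                       file.path(path, "planted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EventMatrix from disk
#'
#' Counterpart of \code{\link{writeEventMatrix}}; accepts either dialect.
#' Shape mismatches between the matrix and its sidecars are an error
#' naming the offending file.
#'
#' @param path directory (MatrixMarket dialect) or \code{.tsv} file path.
#' @return An \linkS4class{EventMatrix}.
#' @export
readEventMatrix <- function(path) {
  if (grepl("\\.tsv$", path) && !dir.exists(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "label") %in% names(df)))
      stop(path, " must contain patient_id and label columns")
    feats <- setdiff(names(df), c("patient_id", "label"))
    m <- as.matrix(df[feats])
    rownames(m) <- df$patient_id
    return(EventMatrix(m, labels = df$label))
  }
  if (!dir.exists(path)) stop("directory not found: ", path)
  need <- c("counts.mtx", "features.tsv", "patients.tsv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("missing sidecar or matrix file: ", file.path(path, f))
  m <- as(Matrix::readMM(file.path(path, "counts.mtx")), "CsparseMatrix")
  feats <- utils::read.delim(file.path(path, "features.tsv"),
                             stringsAsFactors = FALSE)$feature
  pats <- utils::read.delim(file.path(path, "patients.tsv"),
                            stringsAsFactors = FALSE)
  if (length(feats) != ncol(m))
    stop(file.path(path, "features.tsv"),
         " lists ", length(feats), " features but the matrix has ", ncol(m))
  if (nrow(pats) != nrow(m))
    stop(file.path(path, "patients.tsv"),
         " lists ", nrow(pats), " patients but the matrix has ", nrow(m))
  dimnames(m) <- list(pats$patient_id, feats)
  planted <- character(0)
  plFile <- file.path(path, "planted.tsv")
  if (file.exists(plFile))
    planted <- utils::read.delim(plFile, stringsAsFactors = FALSE)$feature
  EventMatrix(m, labels = pats$label, planted = planted)
}

#' Serialize a fold plan to JSON
#'
#' @param plan a \linkS4class{FoldPlan}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFoldPlan <- function(plan, path) {
  stopifnot(is(plan, "FoldPlan"))
  jsonlite::write_json(
    list(k = plan@k, repeats = plan@repeats, n = plan@n, seed = plan@seed,
         assignments = plan@assignments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fold plan from JSON
#'
#' @param path file written by \code{\link{writeFoldPlan}}.
#' @return A \linkS4class{FoldPlan}.
#' @export
readFoldPlan <- function(path) {
  if (!file.exists(path)) stop("fold plan not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  assignments <- lapply(seq_len(j$repeats), function(r) {
    lapply(seq_len(j$k), function(f) {
      ev <- j$assignments[[r]][[f]]
      list(train = as.integer(ev$train),
           validation = as.integer(ev$validation),
           test = as.integer(ev$test))
    })
  })
  methods::new("FoldPlan", assignments = assignments, k = as.integer(j$k),
               repeats = as.integer(j$repeats), n = as.integer(j$n),
               seed = as.integer(j$seed))
}

#' Serialize network parameters to JSON
#'
#' Layer shapes, weights, biases and the hidden activation in one
#' checkpoint file; exact round-trip of the numeric values.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkParams <- function(params, path) {
  stopifnot(is(params, "NetworkParams"))
  jsonlite::write_json(
    list(layerSizes = params@layerSizes,
         hiddenActivation = params@hiddenActivation,
         weights = lapply(params@weights, function(w) as.data.frame(unname(w))),
         biases = params@biases),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read network parameters from a JSON checkpoint
#'
#' @param path file written by \code{\link{writeNetworkParams}}.
#' @return A \linkS4class{NetworkParams}.
#' @export
readNetworkParams <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(j$layerSizes)
  weights <- lapply(seq_along(j$weights), function(l) {
    unname(as.matrix(j$weights[[l]]))
  })
  biases <- lapply(j$biases, as.numeric)
  methods::new("NetworkParams", weights = weights, biases = biases,
               layerSizes = sizes, hiddenActivation = j$hiddenActivation)
}
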