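#' Construct an EventMatrix
#'
#' Builds the package's central container from a patient-by-feature count
#' matrix (dense or sparse). Internally counts are stored transposed
#' (features in rows), following the SummarizedExperiment convention.
#'
#' @param counts patient x feature matrix of non-negative counts
#'   (base matrix or any \pkg{Matrix} class); must have unique column names
#'   (event codes). Row names (patient ids) are generated when absent.
#' @param labels optional binary outcome vector (0/1, NA allowed), length
#'   \code{nrow(counts)}.
#' @param planted optional character vector of planted signal feature names
#'   (recorded in metadata, used by simulation-recovery experiments).
#' @return An \linkS4class{EventMatrix}.
#' @examples
#' m <- matrix(c(2, 0, 0, 1), 2, dimnames = list(c("pA", "pB"), c("E00", "bd3")))
#' EventMatrix(m, labels = c(1, 0))
#' @export
EventMatrix <- function(counts, labels = NULL, planted = character(0)) {
  if (is.null(colnames(counts)))
    stop("counts must have column names (event codes)")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("patient_%d", seq_len(nrow(counts)))
  cts <- Matrix::t(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                           "generalMatrix"), "CsparseMatrix"))
  n <- ncol(cts)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (length(labels) != n)
    stop("labels length must equal the number of patients")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = colnames(cts))
  )
  S4Vectors::metadata(se)$planted <- as.character(planted)
  methods::new("EventMatrix", se)
}

#' Event-code by patient count assay
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param ... unused.
#' @return Sparse matrix of counts, features in rows, patients in columns.
#' @rdname eventCounts
#' @export
setMethod("eventCounts", "EventMatrix", function(x, ...) {
  SummarizedExperiment::assay(x, "counts")
})

#' Patient-by-feature count view
#'
#' The orientation used by the classifier: one row per patient, one column
#' per event code.
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param features optional character vector of event codes to keep
#'   (column subset); unknown names are an error.
#' @param dense return a base matrix instead of a sparse one.
#' @param ... unused.
#' @return Patient x feature matrix of counts.
#' @rdname patientMatrix
#' @export
setMethod("patientMatrix", "EventMatrix",
  function(x, features = NULL, dense = FALSE, ...) {
    m <- Matrix::t(eventCounts(x))
    if (!is.null(features)) {
      missing <- setdiff(features, colnames(m))
      if (length(missing))
        stop("unknown feature name(s): ", paste(missing, collapse = ", "))
      m <- m[, features, drop = FALSE]
    }
    if (dense) as.matrix(m) else m
  })

#' Binary outcome labels
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param ... unused.
#' @return Integer vector of 0/1 (NA where no outcome was supplied), one
#'   per patient.
#' @rdname outcomeLabels
#' @export
setMethod("outcomeLabels", "EventMatrix", function(x, ...) {
  SummarizedExperiment::colData(x)$label
})

#' Planted signal features of a simulated cohort
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param ... unused.
#' @return Character vector of planted feature names (empty for real data).
#' @rdname plantedFeatures
#' @export
setMethod("plantedFeatures", "EventMatrix", function(x, ...) {
  pl <- S4Vectors::metadata(x)$planted
  if (is.null(pl)) character(0) else pl
})

#' Event-code vocabulary
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param ... unused.
#' @return Character vector of feature names.
#' @rdname eventCodes
#' @export
setMethod("eventCodes", "EventMatrix", function(x, ...) rownames(x))

setMethod("show", "EventMatrix", function(object) {
  cts <- eventCounts(object)
  nz <- Matrix::nnzero(cts)
  lab <- outcomeLabels(object)
  cat("EventMatrix:", ncol(cts), "patients x", nrow(cts), "event codes\n")
  cat(sprintf("  nonzero cells: %d (%.2f%%)\n", nz,
              100 * nz / (as.numeric(nrow(cts)) * ncol(cts))))
  if (all(is.na(lab))) {
    cat("  labels: none\n")
  } else {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(lab == 1, na.rm = TRUE), sum(lab == 0, na.rm = TRUE)))
  }
  pl <- plantedFeatures(object)
  if (length(pl)) cat("  planted features:", length(pl), "\n")
  invisible(object)
})
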