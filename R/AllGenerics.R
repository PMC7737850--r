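#' @rdname eventCounts
#' @export
setGeneric("eventCounts", function(x, ...) standardGeneric("eventCounts"))

#' @rdname patientMatrix
#' @export
setGeneric("patientMatrix", function(x, ...) standardGeneric("patientMatrix"))

#' @rdname outcomeLabels
#' @export
setGeneric("outcomeLabels", function(x, ...) standardGeneric("outcomeLabels"))

#' @rdname plantedFeatures
#' @export
setGeneric("plantedFeatures", function(x, ...) standardGeneric("plantedFeatures"))

#' @rdname eventCodes
#' @export
setGeneric("eventCodes", function(x, ...) standardGeneric("eventCodes"))

#' @rdname snapshots
#' @export
setGeneric("snapshots", function(x, ...) standardGeneric("snapshots"))

#' @rdname trainHistory
#' @export
setGeneric("trainHistory", function(x, ...) standardGeneric("trainHistory"))

#' @rdname importanceValues
#' @export
setGeneric("importanceValues", function(x, ...) standardGeneric("importanceValues"))

#' @rdname selectedFeatures
#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))

#' @rdname foldAssignments
#' @export
setGeneric("foldAssignments", function(x, ...) standardGeneric("foldAssignments"))
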