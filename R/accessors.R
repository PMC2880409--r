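# Accessor generics and methods for the package's S4 containers.

#' @name accessors
#' @title Accessors for nabind objects
#' @description Slot accessors: \code{seqString} and \code{bindingLabels} for
#'   \linkS4class{LabeledSequence}; \code{pssmScores} for
#'   \linkS4class{PSSMProfile}; \code{profileStats} and \code{columnCounts}
#'   for \linkS4class{ConservationProfile}; \code{instanceMatrix} and
#'   \code{instanceLabels} for \linkS4class{InstanceSet}; \code{rocPointsTable}
#'   and \code{rocAUC} for \linkS4class{ROCCalibration};
#'   \code{kernelParams} for \linkS4class{BindingClassifier}.
#' @param x an object of the relevant class.
#' @return the slot contents (see class documentation for types and units).
NULL

#' @rdname accessors
#' @export
setGeneric("seqString", function(x) standardGeneric("seqString"))
#' @rdname accessors
#' @export
setMethod("seqString", "LabeledSequence", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("bindingLabels", function(x) standardGeneric("bindingLabels"))
#' @rdname accessors
#' @export
setMethod("bindingLabels", "LabeledSequence", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("profileStats", function(x) standardGeneric("profileStats"))
#' @rdname accessors
#' @export
setMethod("profileStats", "ConservationProfile", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("columnCounts", function(x) standardGeneric("columnCounts"))
#' @rdname accessors
#' @export
setMethod("columnCounts", "ConservationProfile", function(x) x@nobs)

#' @rdname accessors
#' @export
setGeneric("instanceMatrix", function(x) standardGeneric("instanceMatrix"))
#' @rdname accessors
#' @export
setMethod("instanceMatrix", "InstanceSet", function(x) x@x)

#' @rdname accessors
#' @export
setGeneric("instanceLabels", function(x) standardGeneric("instanceLabels"))
#' @rdname accessors
#' @export
setMethod("instanceLabels", "InstanceSet", function(x) x@y)

#' @rdname accessors
#' @export
setGeneric("rocPointsTable", function(x) standardGeneric("rocPointsTable"))
#' @rdname accessors
#' @export
setMethod("rocPointsTable", "ROCCalibration", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))
#' @rdname accessors
#' @export
setMethod("rocAUC", "ROCCalibration", function(x) x@auc)

#' @rdname accessors
#' @export
setGeneric("kernelParams", function(x) standardGeneric("kernelParams"))
#' @rdname accessors
#' @export
setMethod("kernelParams", "BindingClassifier", function(x) x@params)
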