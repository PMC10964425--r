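#' @name gutweb-accessors
#' @title Accessors for gutweb S4 objects
#'
#' @description Slot access goes through these accessors; the slots
#' themselves are internal representation.
#'
#' @param object a gutweb S4 object.
#' @param ... ignored.
NULL

#' @rdname gutweb-accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname gutweb-accessors
#' @export
setGeneric("sampleNames", function(object, ...) standardGeneric("sampleNames"))

#' @rdname gutweb-accessors
#' @export
setGeneric("featureNames", function(object, ...) standardGeneric("featureNames"))

#' @rdname gutweb-accessors
#' @export
setGeneric("featureMarker", function(object, ...) standardGeneric("featureMarker"))

#' @rdname gutweb-accessors
#' @export
setGeneric("featureDomain", function(object, ...) standardGeneric("featureDomain"))

#' @rdname gutweb-accessors
#' @export
setGeneric("edges", function(object, ...) standardGeneric("edges"))

#' @rdname gutweb-accessors
#' @export
setGeneric("networkNodes", function(object, ...) standardGeneric("networkNodes"))

#' @rdname gutweb-accessors
#' @export
setGeneric("selectedLambda", function(object, ...) standardGeneric("selectedLambda"))

#' @rdname gutweb-accessors
#' @export
setGeneric("lambdaPath", function(object, ...) standardGeneric("lambdaPath"))

#' @rdname gutweb-accessors
#' @export
setGeneric("instabilityPath", function(object, ...) standardGeneric("instabilityPath"))

#' @rdname gutweb-accessors
#' @export
setGeneric("contaminantScores", function(object, ...) standardGeneric("contaminantScores"))

#' @rdname gutweb-accessors
#' @export
setGeneric("flaggedIds", function(object, ...) standardGeneric("flaggedIds"))

#' @rdname gutweb-accessors
#' @export
setGeneric("selectedThreshold", function(object, ...) standardGeneric("selectedThreshold"))

#' @rdname gutweb-accessors
#' @export
setGeneric("thresholdGrid", function(object, ...) standardGeneric("thresholdGrid"))
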