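#' Accessor generics
#'
#' Small accessor generics for the S4 classes in this package. Each class
#' documents which of these apply to it.
#'
#' @param x An object of one of the package's S4 classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specSize", function(x) standardGeneric("specSize"))

#' @rdname accessors
#' @export
setGeneric("minCount", function(x) standardGeneric("minCount"))

#' @rdname accessors
#' @export
setGeneric("spectrumAlpha", function(x) standardGeneric("spectrumAlpha"))

#' @rdname accessors
#' @export
setGeneric("spectrumBeta", function(x) standardGeneric("spectrumBeta"))

#' @rdname accessors
#' @export
setGeneric("spectrumMean", function(x) standardGeneric("spectrumMean"))

#' @rdname accessors
#' @export
setGeneric("estValue", function(x) standardGeneric("estValue"))

#' @rdname accessors
#' @export
setGeneric("estStderr", function(x) standardGeneric("estStderr"))

#' @rdname accessors
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname accessors
#' @export
setGeneric("atBoundary", function(x) standardGeneric("atBoundary"))

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname accessors
#' @export
setGeneric("clonalFraction", function(x) standardGeneric("clonalFraction"))

#' @rdname accessors
#' @export
setGeneric("regionSizeMb", function(x) standardGeneric("regionSizeMb"))

#' @rdname accessors
#' @export
setGeneric("tmbValue", function(x) standardGeneric("tmbValue"))

#' @rdname accessors
#' @export
setGeneric("nPass", function(x) standardGeneric("nPass"))

#' @rdname accessors
#' @export
setGeneric("nDetected", function(x) standardGeneric("nDetected"))

#' @rdname accessors
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname accessors
#' @export
setGeneric("betaHat", function(x) standardGeneric("betaHat"))

#' @rdname accessors
#' @export
setGeneric("sHat", function(x) standardGeneric("sHat"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("fitLogLik", function(x) standardGeneric("fitLogLik"))

#' @rdname accessors
#' @export
setGeneric("reportResults", function(x) standardGeneric("reportResults"))

#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))

#' @rdname accessors
#' @export
setGeneric("reportParameters", function(x) standardGeneric("reportParameters"))
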