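#' @rdname accessors
#' @export
setMethod("specSize", "TruncationSpec", function(x) x@size)

#' @rdname accessors
#' @export
setMethod("minCount", "TruncationSpec", function(x) x@minCount)

#' @rdname accessors
#' @export
setMethod("spectrumAlpha", "BetaSpectrum", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("spectrumBeta", "BetaSpectrum", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("spectrumMean", "BetaSpectrum",
          function(x) x@alpha / (x@alpha + x@beta))

#' @rdname accessors
#' @export
setMethod("estValue", "FrequencyEstimate", function(x) x@value)

#' @rdname accessors
#' @export
setMethod("estStderr", "FrequencyEstimate", function(x) x@stderr)

#' @rdname accessors
#' @export
setMethod("nObs", "FrequencyEstimate", function(x) x@nObs)

#' @rdname accessors
#' @export
setMethod("atBoundary", "FrequencyEstimate", function(x) x@atBoundary)

#' @rdname accessors
#' @export
setMethod("sites", "TumourSample", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("purity", "TumourSample", function(x) x@purity)

#' @rdname accessors
#' @export
setMethod("clonalFraction", "TumourSample", function(x) x@clonalFraction)

#' @rdname accessors
#' @export
setMethod("regionSizeMb", "TumourSample", function(x) x@regionSizeMb)

#' @rdname accessors
#' @export
setMethod("tmbValue", "TmbResult", function(x) x@tmb)

#' @rdname accessors
#' @export
setMethod("nPass", "TmbResult", function(x) x@nPass)

#' @rdname accessors
#' @export
setMethod("nDetected", "TmbResult", function(x) x@nDetected)

#' @rdname accessors
#' @export
setMethod("alphaHat", "SpectrumFit", function(x) x@alphaHat)

#' @rdname accessors
#' @export
setMethod("betaHat", "SpectrumFit", function(x) x@betaHat)

#' @rdname accessors
#' @export
setMethod("sHat", "SpectrumFit", function(x) x@sHat)

#' @rdname accessors
#' @export
setMethod("isConverged", "SpectrumFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("fitLogLik", "SpectrumFit", function(x) x@logLik)

#' @rdname accessors
#' @export
setMethod("nObs", "SpectrumFit", function(x) x@nUsed)

#' @rdname accessors
#' @export
setMethod("reportResults", "ExperimentReport", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("reportSummary", "ExperimentReport", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("reportParameters", "ExperimentReport", function(x) x@parameters)
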