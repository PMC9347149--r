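setMethod("show", "TruncationSpec", function(object) {
  cat(sprintf("TruncationSpec: size = %d, minCount = %d (retain X >= %d)\n",
              object@size, object@minCount, object@minCount))
})

setMethod("show", "BetaSpectrum", function(object) {
  cat(sprintf("BetaSpectrum(alpha = %g, beta = %g), mean VAF = %.4g\n",
              object@alpha, object@beta,
              object@alpha / (object@alpha + object@beta)))
})

setMethod("show", "FrequencyEstimate", function(object) {
  cat(sprintf("FrequencyEstimate: f = %.6g (n = %d%s)%s\n",
              object@value, object@nObs,
              if (is.na(object@stderr)) ""
              else sprintf(", se = %.3g", object@stderr),
              if (object@atBoundary) " [at boundary]" else ""))
})

setMethod("show", "SpectrumBiasResult", function(object) {
  cat(sprintf(paste0("SpectrumBiasResult: S = %d, tau = %g\n",
                     "  true above threshold     T = %.4f\n",
                     "  expected observed above  E = %.4f\n",
                     "  relative error (E - T)/T   = %+.4f\n"),
              object@S, object@tau, object@trueCount, object@expectedCount,
              object@relativeError))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d clonal + %d subclonal sites\n",
                     "  spectrum Beta(%g, %g), clonal VAF %g, purity %g\n",
                     "  depth model %s, region %g Mb, seed %d\n"),
              object@nClonal, object@nSubclonal, object@spectrum@alpha,
              object@spectrum@beta, object@clonalVaf, object@purity,
              paste(names(object@depthModel), unlist(object@depthModel),
                    sep = "=", collapse = " "),
              object@regionSizeMb, object@seed))
})

setMethod("show", "TumourSample", function(object) {
  s <- object@sites
  cat(sprintf(paste0("TumourSample: %d sites (%.1f%% clonal), purity %g,",
                     " region %g Mb\n  mean depth %.1f, mean observed VAF",
                     " %.4g (seed %d)\n"),
              nrow(s), 100 * object@clonalFraction, object@purity,
              object@regionSizeMb, mean(s$depth),
              mean(s$obs_vaf, na.rm = TRUE), object@seed))
})

setMethod("show", "TmbResult", function(object) {
  cat(sprintf(paste0("TmbResult (%s): TMB = %.4g mutations/Mb\n",
                     "  detected %d sites; %s pass tau = %g; region %g Mb\n"),
              object@method, object@tmb, object@nDetected,
              if (is.na(object@nPass)) "model-derived count"
              else sprintf("%d", object@nPass),
              object@tau, object@regionSizeMb))
})

setMethod("show", "SpectrumFit", function(object) {
  if (object@nUsed == 0L) {
    cat("SpectrumFit: empty (no usable subclonal sites), sHat = 0\n")
    return(invisible(NULL))
  }
  cat(sprintf(paste0("SpectrumFit: alphaHat = %.4g, betaHat = %.4g",
                     " (mean VAF %.4g)\n  sHat = %.4g from %d sites;",
                     " logLik = %.3f; converged: %s\n"),
              object@alphaHat, object@betaHat,
              object@alphaHat / (object@alphaHat + object@betaHat),
              object@sHat, object@nUsed, object@logLik, object@converged))
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s': %d result rows, %.2fs\n",
              object@name, nrow(object@results), object@runtime))
  nm <- names(object@summary)
  nm <- nm[nm != "raw"]
  for (k in nm) {
    v <- object@summary[[k]]
    if (is.numeric(v) && length(v) == 1L)
      cat(sprintf("  %s = %.6g\n", k, v))
  }
})
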