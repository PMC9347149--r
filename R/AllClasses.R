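#' Truncated binomial sampling scheme
#'
#' Describes the retention rule applied to a binomial read count at a site
#' sequenced to depth `size`: an observation is retained only when the mutant
#' read count is at least `minCount`. `minCount = 0` is the untruncated
#' binomial, `minCount = 1` the zero-truncated case (a site is only seen when
#' at least one mutant read is present), and `minCount = ceiling(tau * size)`
#' the case where only sites with observed mutant proportion of at least
#' `tau` are counted.
#'
#' @slot size Number of reads covering the site (positive integer).
#' @slot minCount Minimum retained mutant read count (integer in
#'   `[0, size]`).
#'
#' @param size,minCount See slots.
#' @return `TruncationSpec()` returns a validated `TruncationSpec` object.
#' @seealso [truncatedPmf()], [truncatedMeanProportion()],
#'   [sampleTruncated()], [fitTruncatedML()]
#' @examples
#' TruncationSpec(100, 5)   # retain sites with observed VAF >= 0.05
#' @export TruncationSpec
#' @exportClass TruncationSpec
TruncationSpec <- setClass("TruncationSpec",
  representation(size = "integer", minCount = "integer"))

setValidity("TruncationSpec", function(object) {
  msg <- character()
  if (length(object@size) != 1L || is.na(object@size) || object@size < 1L)
    msg <- c(msg, "'size' must be a single positive integer")
  if (length(object@minCount) != 1L || is.na(object@minCount) ||
      object@minCount < 0L)
    msg <- c(msg, "'minCount' must be a single non-negative integer")
  if (length(msg) == 0L && object@minCount > object@size)
    msg <- c(msg, "'minCount' must not exceed 'size'")
  if (length(msg)) msg else TRUE
})

setMethod("initialize", "TruncationSpec", function(.Object, size = 1L,
                                                  minCount = 0L, ...) {
  .Object <- callNextMethod(.Object, size = .asCount(size, "size"),
                            minCount = .asCount(minCount, "minCount"), ...)
  .Object
})

#' Frequency estimate from truncated binomial data
#'
#' The result of [fitTruncatedML()] (or of the naive retained-proportion
#' estimator): an estimate of the mutant allele frequency together with the
#' number of retained observations it is based on.
#'
#' @slot value Estimated success probability / mutant allele frequency in
#'   `[0, 1]`.
#' @slot nObs Number of retained observations used.
#' @slot stderr Approximate standard error (observed-information based), or
#'   `NA` when unavailable (e.g. boundary estimates).
#' @slot atBoundary `TRUE` when the estimate was clamped to the boundary of
#'   the optimisation interval.
#' @export
setClass("FrequencyEstimate",
  representation(value = "numeric", nObs = "integer", stderr = "numeric",
                 atBoundary = "logical"))

setValidity("FrequencyEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1L || is.na(object@value) ||
      object@value < 0 || object@value > 1)
    msg <- c(msg, "'value' must be a single number in [0, 1]")
  if (length(object@nObs) != 1L || is.na(object@nObs) || object@nObs < 1L)
    msg <- c(msg, "'nObs' must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Beta mutant-allele frequency spectrum
#'
#' The `(alpha, beta)` parameters of the beta distribution used as the
#' subclonal mutant allele frequency spectrum. Small `alpha` with large
#' `beta` gives a steep spectrum concentrated near frequency zero; `alpha`
#' above 1 gives a spectrum peaked at an intermediate frequency, emulating a
#' discrete subclone.
#'
#' @slot alpha,beta Strictly positive shape parameters.
#' @param alpha,beta See slots.
#' @return `BetaSpectrum()` returns a validated `BetaSpectrum` object.
#' @examples
#' BetaSpectrum(0.1, 100)  # steep neutral-tail-like spectrum, mean ~0.001
#' BetaSpectrum(2, 20)     # subclone cluster around VAF 0.09
#' @export BetaSpectrum
#' @exportClass BetaSpectrum
setClass("BetaSpectrum", representation(alpha = "numeric", beta = "numeric"))

BetaSpectrum <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta))
    stop("'alpha' and 'beta' must be numeric", call. = FALSE)
  new("BetaSpectrum", alpha = as.numeric(alpha), beta = as.numeric(beta))
}

setValidity("BetaSpectrum", function(object) {
  if (length(object@alpha) != 1L || length(object@beta) != 1L ||
      is.na(object@alpha) || is.na(object@beta) ||
      object@alpha <= 0 || object@beta <= 0)
    "'alpha' and 'beta' must be single strictly positive numbers"
  else TRUE
})

#' Expected versus true above-threshold mutation counts
#'
#' Holds, for one depth configuration, the true number of somatic mutations
#' with frequency above the threshold (`trueCount`), the expected number
#' observed above the threshold under binomial read sampling
#' (`expectedCount`), and their relative error
#' `(expectedCount - trueCount) / trueCount`.
#'
#' @slot trueCount,expectedCount Non-negative reals.
#' @slot relativeError `(E - T) / T`.
#' @slot tau Frequency threshold in `(0, 1)`.
#' @slot S Total number of somatic mutations.
#' @slot depths Integer vector of per-site sequencing depths.
#' @seealso [trueCountAboveThreshold()], [expectedObservedCount()],
#'   [spectrumBiasResult()]
#' @export
setClass("SpectrumBiasResult",
  representation(trueCount = "numeric", expectedCount = "numeric",
                 relativeError = "numeric", tau = "numeric", S = "integer",
                 depths = "integer"))

setValidity("SpectrumBiasResult", function(object) {
  msg <- character()
  if (object@trueCount < 0 || object@expectedCount < 0)
    msg <- c(msg, "counts must be non-negative")
  if (object@trueCount > object@S + 1e-9 ||
      object@expectedCount > object@S + 1e-9)
    msg <- c(msg, "counts must not exceed S")
  if (length(msg)) msg else TRUE
})

#' Configuration of a simulated tumour sample
#'
#' Defines the generative model for one synthetic tumour sample: a clonal
#' component of `nClonal` mutations at cell-level frequency `clonalVaf`
#' (0.5 for heterozygous mutations in a diploid genome) and a subclonal
#' component of `nSubclonal` mutations with frequencies drawn from a beta
#' `spectrum`. All frequencies are scaled by `purity` before binomial read
#' sampling at depths drawn from `depthModel`.
#'
#' @slot nClonal,nSubclonal Non-negative integers, at least one positive.
#' @slot spectrum A [BetaSpectrum-class] for the subclonal component.
#' @slot clonalVaf Cell-level clonal frequency in `(0, 1]`, default 0.5.
#' @slot purity Tumour purity in `(0, 1]`, default 1.
#' @slot depthModel A depth model from [depthModelFixed()],
#'   [depthModelPoisson()] or [depthModelNegBin()].
#' @slot regionSizeMb Size of the sequenced target region in megabases.
#' @slot seed Integer seed making the sample reproducible.
#' @seealso [simulateSample()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(nClonal = "integer", nSubclonal = "integer",
                 spectrum = "BetaSpectrum", clonalVaf = "numeric",
                 purity = "numeric", depthModel = "list",
                 regionSizeMb = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nClonal < 0L) msg <- c(msg, "'nClonal' must be >= 0")
  if (object@nSubclonal < 0L) msg <- c(msg, "'nSubclonal' must be >= 0")
  if (object@nClonal + object@nSubclonal < 1L)
    msg <- c(msg, "'nClonal' + 'nSubclonal' must be >= 1")
  if (object@clonalVaf <= 0 || object@clonalVaf > 1)
    msg <- c(msg, "'clonalVaf' must be in (0, 1]")
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "'purity' must be in (0, 1]")
  if (object@regionSizeMb <= 0)
    msg <- c(msg, "'regionSizeMb' must be > 0")
  if (is.null(object@depthModel$type) ||
      !object@depthModel$type %in% c("fixed", "poisson", "nbinom"))
    msg <- c(msg, "'depthModel' must come from depthModelFixed/Poisson/NegBin")
  if (length(msg)) msg else TRUE
})

#' A simulated tumour sample
#'
#' One synthetic tumour sample: a per-site table plus sample-level metadata.
#' The `sites` data frame has columns `site_id` (character), `true_vaf`
#' (purity-scaled cell-level frequency actually used for read sampling),
#' `depth`, `alt_count`, `is_clonal` and `obs_vaf` (`alt_count / depth`,
#' possibly purity-adjusted by [purityAdjust()]; `NA` at depth 0).
#'
#' @slot sites Per-site data frame (see description).
#' @slot purity Tumour purity used in the simulation.
#' @slot clonalFraction Fraction of the sample's mutations that are clonal.
#' @slot regionSizeMb Target region size in megabases.
#' @slot seed Seed the sample was generated with.
#' @slot config Echo of the generating configuration (list form).
#' @seealso [simulateSample()], [downsampleSample()], [estimateTmbThreshold()]
#' @export
setClass("TumourSample",
  representation(sites = "data.frame", purity = "numeric",
                 clonalFraction = "numeric", regionSizeMb = "numeric",
                 seed = "integer", config = "list"))

setValidity("TumourSample", function(object) {
  msg <- character()
  s <- object@sites
  need <- c("site_id", "true_vaf", "depth", "alt_count", "is_clonal",
            "obs_vaf")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("'sites' must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(s) < 1L) {
      msg <- c(msg, "'sites' must be non-empty")
    } else {
      if (any(s$alt_count > s$depth))
        msg <- c(msg, "'alt_count' must not exceed 'depth'")
      if (any(s$alt_count < 0L) || any(s$depth < 0L))
        msg <- c(msg, "counts must be non-negative")
      if (abs(mean(s$is_clonal) - object@clonalFraction) > 1e-8)
        msg <- c(msg, "'clonalFraction' inconsistent with site flags")
    }
  }
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "'purity' must be in (0, 1]")
  if (object@regionSizeMb <= 0) msg <- c(msg, "'regionSizeMb' must be > 0")
  if (length(msg)) msg else TRUE
})

#' TMB estimate
#'
#' Result of [estimateTmbThreshold()] (`method = "threshold"`) or
#' [estimateTmbModel()] (`method = "model"`). For the threshold method,
#' `tmb` equals `nPass / regionSizeMb`; for the model method `nPass` is `NA`
#' and `tmb` is the model-derived count per megabase.
#'
#' @slot nDetected Number of detected sites considered.
#' @slot nPass Number of detected sites with observed VAF at or above `tau`
#'   (`NA` for the model method).
#' @slot tmb Mutations per megabase.
#' @slot tau Frequency threshold used.
#' @slot minAltReads Detection cut used.
#' @slot method `"threshold"` or `"model"`.
#' @slot regionSizeMb Region size used for the per-megabase scaling.
#' @export
setClass("TmbResult",
  representation(nDetected = "integer", nPass = "integer", tmb = "numeric",
                 tau = "numeric", minAltReads = "integer",
                 method = "character", regionSizeMb = "numeric"))

setValidity("TmbResult", function(object) {
  msg <- character()
  if (!object@method %in% c("threshold", "model"))
    msg <- c(msg, "'method' must be 'threshold' or 'model'")
  if (!is.na(object@nPass) && object@nPass > object@nDetected)
    msg <- c(msg, "'nPass' must not exceed 'nDetected'")
  if (object@method == "threshold" && !is.na(object@nPass) &&
      abs(object@tmb - object@nPass / object@regionSizeMb) > 1e-8)
    msg <- c(msg, "'tmb' must equal nPass / regionSizeMb for the threshold method")
  if (object@tmb < 0) msg <- c(msg, "'tmb' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fitted truncated beta-binomial frequency spectrum
#'
#' Result of [fitSpectrumML()]: maximum-likelihood estimates of the beta
#' spectrum parameters from detection-truncated read counts, together with
#' the inverse-probability-weighted estimate `sHat` of the total number of
#' subclonal mutations (detected or not). An "empty" fit (`nUsed = 0`,
#' `sHat = 0`, `NA` parameters) represents a sample with no usable subclonal
#' sites, e.g. a purely clonal sample.
#'
#' @slot alphaHat,betaHat Fitted spectrum parameters (`NA` for empty fits).
#' @slot sHat Estimated total subclonal mutation count; at least `nUsed`.
#' @slot logLik Maximised truncated log-likelihood.
#' @slot converged Convergence flag.
#' @slot nUsed Number of sites entering the fit.
#' @slot details List with per-start diagnostics, the cuts used and a
#'   degenerate-data flag.
#' @export
setClass("SpectrumFit",
  representation(alphaHat = "numeric", betaHat = "numeric", sHat = "numeric",
                 logLik = "numeric", converged = "logical", nUsed = "integer",
                 details = "list"))

setValidity("SpectrumFit", function(object) {
  msg <- character()
  if (object@nUsed > 0L && object@converged) {
    if (is.na(object@alphaHat) || is.na(object@betaHat) ||
        object@alphaHat <= 0 || object@betaHat <= 0)
      msg <- c(msg, "fitted parameters must be strictly positive")
    if (object@sHat < object@nUsed - 1e-6)
      msg <- c(msg, "'sHat' must be at least 'nUsed'")
  }
  if (length(msg)) msg else TRUE
})

#' Experiment report
#'
#' Output of the `run*` experiment drivers: a tidy per-unit results table,
#' the full parameter echo (including seeds) that reproduces it, and summary
#' statistics derived from the table.
#'
#' @slot name Experiment name.
#' @slot parameters Full configuration echo, including all seeds.
#' @slot results Tidy results table (one row per evaluation unit).
#' @slot summary Named list of summary statistics.
#' @slot runtime Elapsed seconds.
#' @seealso [runTruncationBias()], [runThresholdCrossing()],
#'   [runDownsampling()], [runDepthCorrelation()]
#' @export
setClass("ExperimentReport",
  representation(name = "character", parameters = "list",
                 results = "data.frame", summary = "list",
                 runtime = "numeric"))
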