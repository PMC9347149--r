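#' Detect mutations in a sample
#'
#' Stand-in for a somatic variant caller: a site is detected when it carries
#' at least `minAltReads` mutant reads (and has non-zero depth). Like real
#' callers this rule is monotone in depth, and unlike them it is
#' analytically tractable — the detection probability of a site at depth
#' `d` is the upper beta-binomial tail `P(X >= minAltReads)`.
#'
#' @param sample A [TumourSample-class].
#' @param minAltReads Minimum mutant read count (>= 1), default 3.
#' @return The detected subset of `sites(sample)`, order preserved.
#' @export
detectMutations <- function(sample, minAltReads = 3L) {
  stopifnot(is(sample, "TumourSample"))
  minAltReads <- .asCount(minAltReads, "minAltReads")
  if (minAltReads < 1L) stop("'minAltReads' must be >= 1", call. = FALSE)
  s <- sample@sites
  s[s$alt_count >= minAltReads & s$depth >= 1L, , drop = FALSE]
}

#' Threshold-counting TMB estimate
#'
#' The standard TMB estimator: among detected sites, count those whose
#' observed VAF is at or above the frequency threshold `tau` and divide by
#' the region size in megabases. For unadjusted samples the pass rule is
#' `alt_count >= ceiling(depth * tau)`, the same ceiling convention used by
#' [expectedObservedCount()]; for purity-adjusted samples the (adjusted)
#' `obs_vaf` column is compared against `tau` directly.
#'
#' @param sample A [TumourSample-class].
#' @param tau Frequency threshold in `(0, 1)`, default 0.05.
#' @param minAltReads Detection cut, default 3.
#' @return A [TmbResult-class] with `method = "threshold"`.
#' @examples
#' cfg <- SimulationConfig(nClonal = 20, nSubclonal = 180, seed = 11)
#' estimateTmbThreshold(simulateSample(cfg))
#' @export
estimateTmbThreshold <- function(sample, tau = 0.05, minAltReads = 3L) {
  stopifnot(is(sample, "TumourSample"))
  tau <- .asProb(tau, "tau", open_lo = TRUE, open_hi = TRUE)
  if (sample@regionSizeMb <= 0)
    stop("'regionSizeMb' must be > 0", call. = FALSE)
  det <- detectMutations(sample, minAltReads)
  pass <- !is.na(det$obs_vaf) & det$obs_vaf >= tau - 1e-9
  npass <- as.integer(sum(pass))
  new("TmbResult", nDetected = nrow(det), nPass = npass,
      tmb = npass / sample@regionSizeMb, tau = tau,
      minAltReads = .asCount(minAltReads, "minAltReads"),
      method = "threshold", regionSizeMb = sample@regionSizeMb)
}

#' Purity-adjust observed VAFs
#'
#' Divides the observed VAF of every site by the sample purity (capped at
#' 1), the standard correction for normal-cell contamination: in a sample of
#' purity `p`, a mutation present in a fraction `f` of cancer cells is
#' expected at read fraction `p * f`. `purity = 1` is the identity.
#'
#' @param sample A [TumourSample-class].
#' @param purity Purity in `(0, 1]` to correct by; defaults to the sample's
#'   own recorded purity.
#' @return The adjusted [TumourSample-class].
#' @export
purityAdjust <- function(sample, purity = sample@purity) {
  stopifnot(is(sample, "TumourSample"))
  purity <- .asProb(purity, "purity", open_lo = TRUE)
  if (purity == 1) return(sample)
  s <- sample@sites
  s$obs_vaf <- pmin(1, s$obs_vaf / purity)
  out <- sample
  out@sites <- s
  out
}
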