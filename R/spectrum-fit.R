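#' Fit the subclonal frequency spectrum from detection-truncated counts
#'
#' Maximum-likelihood fit of the beta spectrum `(alpha, beta)` from detected
#' mutant read counts, accounting for the detection truncation: each site
#' contributes `pmf_BB(x_i; d_i, a, b) / P(X >= c_i; d_i, a, b)` with
#' per-site cut `c_i = max(minAltReads, ceiling(d_i * tauDetect))`. By
#' default `tauDetect = 0`, so all detected sites — including those below
#' the TMB counting threshold — inform the spectrum. Sites whose observed
#' VAF is at or above `clonalExclusionVaf` are excluded as clonal before
#' fitting, since the beta component models subclonal mass only.
#'
#' The total subclonal mutation count is recovered by inverse-probability
#' weighting (capture–recapture style):
#' `sHat = sum_i 1 / P(X >= c_i; d_i, alphaHat, betaHat)`.
#'
#' Optimisation runs on `(log alpha, log beta)` from four fixed starting
#' points (Nelder-Mead, relative tolerance 1e-6), keeping the best
#' log-likelihood; ties are broken towards the smallest `alphaHat`. When the
#' detected counts leave the spectrum weakly identified (few sites, strong
#' truncation) the individual parameter estimates can drift to extreme
#' ridges while the above-threshold functional
#' `sHat * (1 - betaSpectrumCdf(tau, fit))` — the quantity
#' [estimateTmbModel()] consumes — remains stable; `details(fit)$atBound`
#' flags such fits.
#'
#' @param sample A [TumourSample-class] (or a detected-sites data frame with
#'   columns `depth`, `alt_count`, `obs_vaf`).
#' @param minAltReads Detection cut (>= 1), default 3.
#' @param tauDetect Additional proportional truncation for the fit, default
#'   0 (detection-only truncation).
#' @param clonalExclusionVaf Observed-VAF cut above which sites are treated
#'   as clonal and excluded, default 0.35.
#' @param minSites Minimum number of usable sites to attempt a fit.
#' @return A [SpectrumFit-class]. With no usable subclonal sites an "empty"
#'   converged fit (`nUsed = 0`, `sHat = 0`, `NA` parameters) is returned,
#'   so purely clonal samples flow through [estimateTmbModel()].
#' @export
fitSpectrumML <- function(sample, minAltReads = 3L, tauDetect = 0,
                          clonalExclusionVaf = 0.35, minSites = 10L) {
  minAltReads <- .asCount(minAltReads, "minAltReads")
  if (minAltReads < 1L) stop("'minAltReads' must be >= 1", call. = FALSE)
  tauDetect <- .asProb(tauDetect, "tauDetect", open_hi = TRUE)
  clonalExclusionVaf <- .asProb(clonalExclusionVaf, "clonalExclusionVaf")
  det <- if (is(sample, "TumourSample")) detectMutations(sample, minAltReads)
         else sample
  keep <- !is.na(det$obs_vaf) & det$obs_vaf < clonalExclusionVaf
  det <- det[keep, , drop = FALSE]
  n <- nrow(det)
  if (n == 0L)
    return(new("SpectrumFit", alphaHat = NA_real_, betaHat = NA_real_,
               sHat = 0, logLik = 0, converged = TRUE, nUsed = 0L,
               details = list(empty = TRUE)))
  if (n < .asCount(minSites, "minSites"))
    stop("need at least ", minSites, " usable sub-clonal sites, got ", n,
         call. = FALSE)
  d <- as.integer(det$depth)
  x <- as.integer(det$alt_count)
  cuts <- .passCut(d, tauDetect, minAltReads)
  degenerate <- all(x == cuts)
  # group identical (depth, cut) pairs: one tail evaluation per group
  key <- paste(d, cuts)
  grp <- match(key, unique(key))
  gd <- d[!duplicated(key)]
  gc <- cuts[!duplicated(key)]
  gn <- tabulate(grp)
  nll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 15)) return(1e10)
    a <- exp(theta[1L]); b <- exp(theta[2L])
    ltail <- vapply(seq_along(gd), function(i) {
      Fc <- .betabinomCdf(gc[i] - 1L, gd[i], a, b)
      if (!is.finite(Fc) || Fc >= 1) return(NA_real_)
      log1p(-Fc)
    }, 0)
    if (anyNA(ltail)) return(1e10)
    v <- -(sum(.ldbetabinom(x, d, a, b)) - sum(gn * ltail))
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(log(c(0.05, 5)), log(c(0.1, 100)), log(c(0.5, 50)),
                 log(c(1, 1)))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, nll, method = "Nelder-Mead",
                          control = list(reltol = 1e-6, maxit = 2000)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    return(new("SpectrumFit", alphaHat = NA_real_, betaHat = NA_real_,
               sHat = NA_real_, logLik = NA_real_, converged = FALSE,
               nUsed = n,
               details = list(error = "all optimisation starts failed")))
  vals <- vapply(fits[ok], function(f) f$value, 0)
  alphas <- vapply(fits[ok], function(f) exp(f$par[1L]), 0)
  # best log-likelihood; near-ties (within 1e-6) resolved to smallest alpha
  bestVal <- min(vals)
  cand <- which(vals <= bestVal + 1e-6)
  best <- fits[ok][[cand[which.min(alphas[cand])]]]
  a <- exp(best$par[1L]); b <- exp(best$par[2L])
  tails <- vapply(seq_along(gd), function(i)
    1 - .betabinomCdf(gc[i] - 1L, gd[i], a, b), 0)
  sHat <- sum(gn / tails)
  atBound <- any(abs(best$par) > 14)
  new("SpectrumFit", alphaHat = a, betaHat = b, sHat = sHat,
      logLik = -best$value,
      converged = best$convergence == 0L && all(is.finite(tails)) &&
        all(tails > 0),
      nUsed = n,
      details = list(cuts = cuts, degenerate = degenerate,
                     atBound = atBound,
                     startValues = vals))
}

#' Model-based TMB estimate from a fitted spectrum
#'
#' The full-spectrum alternative to threshold counting: the expected number
#' of subclonal mutations with true frequency at or above `tau` is computed
#' from the fitted spectrum and abundance,
#' `sHat * (1 - betaSpectrumCdf(tau, fitted spectrum))`, the observed clonal
#' mutations are added, and the total is divided by the region size. Because
#' the estimate integrates the whole detected frequency spectrum instead of
#' counting noisy threshold exceedances, it does not inherit the
#' threshold-crossing bias and is far less sensitive to sequencing depth.
#'
#' @param fit A converged [SpectrumFit-class].
#' @param tau Frequency threshold in `(0, 1)`.
#' @param regionSizeMb Region size in megabases.
#' @param nClonalObserved Number of observed clonal mutations (sites
#'   excluded from the fit by the clonal VAF cut).
#' @return A [TmbResult-class] with `method = "model"`.
#' @export
estimateTmbModel <- function(fit, tau = 0.05, regionSizeMb,
                             nClonalObserved) {
  stopifnot(is(fit, "SpectrumFit"))
  if (!fit@converged)
    stop("spectrum fit did not converge; refusing to compute model TMB",
         call. = FALSE)
  tau <- .asProb(tau, "tau", open_hi = TRUE)
  if (regionSizeMb <= 0) stop("'regionSizeMb' must be > 0", call. = FALSE)
  nClonalObserved <- .asCount(nClonalObserved, "nClonalObserved")
  subAbove <- if (fit@nUsed == 0L) 0
  else fit@sHat * (1 - stats::pbeta(tau, fit@alphaHat, fit@betaHat))
  new("TmbResult", nDetected = fit@nUsed + nClonalObserved,
      nPass = NA_integer_,
      tmb = (nClonalObserved + subAbove) / regionSizeMb,
      tau = tau, minAltReads = NA_integer_, method = "model",
      regionSizeMb = as.numeric(regionSizeMb))
}

#' Count observed clonal mutations
#'
#' Companion to [fitSpectrumML()]: the number of detected sites excluded
#' from the spectrum fit by the clonal observed-VAF cut, which
#' [estimateTmbModel()] adds back as directly observed clonal mutations.
#'
#' @inheritParams fitSpectrumML
#' @return Integer count.
#' @export
countObservedClonal <- function(sample, minAltReads = 3L,
                                clonalExclusionVaf = 0.35) {
  det <- detectMutations(sample, minAltReads)
  sum(!is.na(det$obs_vaf) & det$obs_vaf >= clonalExclusionVaf)
}
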