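#' Beta spectrum CDF
#'
#' Regularised incomplete beta function at `x` for the spectrum's
#' `(alpha, beta)`: the fraction of somatic mutations with true frequency at
#' or below `x`.
#'
#' @param x Value(s) in `[0, 1]`.
#' @param spectrum A [BetaSpectrum-class].
#' @return Probabilities, non-decreasing in `x`.
#' @examples
#' betaSpectrumCdf(0.05, BetaSpectrum(1, 1))    # 0.05
#' betaSpectrumCdf(0.05, BetaSpectrum(0.1, 100))
#' @export
betaSpectrumCdf <- function(x, spectrum) {
  stopifnot(is(spectrum, "BetaSpectrum"))
  if (any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  stats::pbeta(x, spectrum@alpha, spectrum@beta)
}

#' Beta-binomial pmf
#'
#' Probability of observing `x` mutant reads at depth `size` when the
#' underlying mutation frequency is drawn from the beta `spectrum`. Computed
#' through log-gamma differences so that large depths do not overflow.
#'
#' @param x Integer count(s) in `[0, size]`.
#' @param size Sequencing depth.
#' @param spectrum A [BetaSpectrum-class].
#' @param log Return the log pmf?
#' @return Probabilities (or their logs).
#' @export
betaBinomialPmf <- function(x, size, spectrum, log = FALSE) {
  stopifnot(is(spectrum, "BetaSpectrum"))
  size <- .asCount(size, "size")
  if (any(x < 0) || any(x > size))
    stop("'x' must lie in [0, size]", call. = FALSE)
  lp <- .ldbetabinom(x, size, spectrum@alpha, spectrum@beta)
  if (log) lp else exp(lp)
}

#' Beta-binomial CDF
#'
#' `P(X <= k)` for `X` beta-binomial with size `size` and the spectrum's
#' `(alpha, beta)`; pmf terms are accumulated from their log-space values.
#'
#' @param k Integer in `[0, size]`.
#' @param size Sequencing depth.
#' @param spectrum A [BetaSpectrum-class].
#' @return A probability.
#' @examples
#' betaBinomialCdf(0, 1, BetaSpectrum(1, 1))      # 0.5
#' betaBinomialCdf(0, 1, BetaSpectrum(0.1, 100))  # 100 / 100.1
#' @export
betaBinomialCdf <- function(k, size, spectrum) {
  stopifnot(is(spectrum, "BetaSpectrum"))
  size <- .asCount(size, "size")
  k <- .asCount(k, "k")
  if (k < 0 || k > size)
    stop("'k' must lie in [0, size]", call. = FALSE)
  .betabinomCdf(k, size, spectrum@alpha, spectrum@beta)
}

#' True number of somatic mutations above the frequency threshold
#'
#' The spectrum-level truth the threshold count is compared against:
#' `T = (1 - F_B(tau; alpha, beta)) * S`, the expected number of the `S`
#' somatic mutations whose true frequency is at or above `tau`.
#'
#' @param S Total number of somatic mutations.
#' @param tau Frequency threshold in `[0, 1)`.
#' @param spectrum A [BetaSpectrum-class].
#' @return A non-negative real, `S` at `tau = 0`.
#' @examples
#' trueCountAboveThreshold(100, 0.05, BetaSpectrum(1, 1))  # 95
#' @export
trueCountAboveThreshold <- function(S, tau, spectrum) {
  S <- .asCount(S, "S")
  if (S < 0) stop("'S' must be >= 0", call. = FALSE)
  tau <- .asProb(tau, "tau", open_hi = TRUE)
  (1 - betaSpectrumCdf(tau, spectrum)) * S
}

#' Expected number of mutations observed above the threshold
#'
#' Under binomial read sampling at per-site depths `depths`, the number of
#' mutant reads at a site is beta-binomial, and the expected number of sites
#' whose observed proportion reaches `tau` is
#' `E = sum_i (1 - F_BB(c_i - 1; d_i, alpha, beta))` with pass cut
#' `c_i = ceiling(d_i * tau)` (a site passes when `X / d_i >= tau`). The gap
#' between `E` and the spectrum-level truth is the threshold-crossing bias
#' of TMB.
#'
#' @param depths Integer vector of per-site depths (each >= 1).
#' @param tau Frequency threshold in `(0, 1)`.
#' @param spectrum A [BetaSpectrum-class].
#' @return Expected count, between 0 and `length(depths)`.
#' @examples
#' expectedObservedCount(rep(1, 100), 0.05, BetaSpectrum(1, 1))  # 50
#' @export
expectedObservedCount <- function(depths, tau, spectrum) {
  stopifnot(is(spectrum, "BetaSpectrum"))
  tau <- .asProb(tau, "tau", open_lo = TRUE, open_hi = TRUE)
  if (length(depths) == 0L) {
    warning("empty depth list; expected count is 0")
    return(0)
  }
  depths <- vapply(depths, .asCount, 0L, name = "depths")
  if (any(depths < 1L)) stop("all depths must be >= 1", call. = FALSE)
  cuts <- .passCut(depths, tau)
  key <- paste(depths, cuts)
  tab <- table(key)
  uk <- names(tab)
  parts <- strsplit(uk, " ", fixed = TRUE)
  vals <- vapply(parts, function(p) {
    d <- as.integer(p[1]); cc <- as.integer(p[2])
    1 - .betabinomCdf(cc - 1L, d, spectrum@alpha, spectrum@beta)
  }, 0)
  sum(vals * as.integer(tab))
}

#' Relative error of the expected above-threshold count
#'
#' `(E - T) / T`: the bias, relative to the spectrum-level truth, of
#' counting mutations whose observed proportion clears the threshold.
#' Positive values mean over-estimation.
#'
#' @param expected Expected observed count `E`.
#' @param trueCount True above-threshold count `T` (> 0).
#' @return `(E - T) / T`.
#' @export
relativeTmbError <- function(expected, trueCount) {
  if (!is.numeric(expected) || !is.numeric(trueCount))
    stop("'expected' and 'trueCount' must be numeric", call. = FALSE)
  if (any(trueCount <= 0))
    stop("relative error undefined: 'trueCount' must be > 0", call. = FALSE)
  (expected - trueCount) / trueCount
}

#' Bundle the (T, E, relative error) triple for one depth configuration
#'
#' @param S Total number of somatic mutations.
#' @param tau Frequency threshold in `(0, 1)`.
#' @param spectrum A [BetaSpectrum-class].
#' @param depths Per-site depths; a single value is recycled to length `S`.
#' @return A [SpectrumBiasResult-class].
#' @export
spectrumBiasResult <- function(S, tau, spectrum, depths) {
  S <- .asCount(S, "S")
  if (length(depths) == 1L) depths <- rep(depths, S)
  if (length(depths) != S)
    stop("'depths' must have length 1 or S", call. = FALSE)
  depths <- vapply(depths, .asCount, 0L, name = "depths")
  tc <- trueCountAboveThreshold(S, tau, spectrum)
  ec <- expectedObservedCount(depths, tau, spectrum)
  new("SpectrumBiasResult", trueCount = tc, expectedCount = ec,
      relativeError = relativeTmbError(ec, tc), tau = as.numeric(tau),
      S = S, depths = depths)
}

#' Relative-error curve over sequencing depth
#'
#' Evaluates the (T, E, relative error) triple at uniform depth for each
#' value of an ascending depth grid: the theoretical curve showing how the
#' threshold-crossing bias of TMB decays (or not) with sequencing depth.
#'
#' @param spectrum A [BetaSpectrum-class].
#' @param tau Frequency threshold in `(0, 1)`.
#' @param depthGrid Ascending vector of uniform depths.
#' @param S Total number of somatic mutations.
#' @return A data frame with columns `depth`, `trueCount`, `expectedCount`
#'   and `relativeError`; `trueCount` is constant across rows.
#' @examples
#' relativeErrorCurve(BetaSpectrum(0.1, 100), 0.05, c(50, 100, 1000), 200)
#' @export
relativeErrorCurve <- function(spectrum, tau, depthGrid, S) {
  if (length(depthGrid) == 0L)
    stop("'depthGrid' must be non-empty", call. = FALSE)
  if (is.unsorted(depthGrid, strictly = FALSE))
    stop("'depthGrid' must be ascending", call. = FALSE)
  rows <- lapply(depthGrid, function(d) {
    r <- spectrumBiasResult(S, tau, spectrum, d)
    data.frame(depth = as.integer(d), trueCount = r@trueCount,
               expectedCount = r@expectedCount,
               relativeError = r@relativeError)
  })
  do.call(rbind, rows)
}

# log beta-binomial pmf via log-gamma differences (vectorised over x)
.ldbetabinom <- function(x, size, alpha, beta) {
  lchoose(size, x) + lbeta(x + alpha, size - x + beta) - lbeta(alpha, beta)
}

.betabinomCdf <- function(k, size, alpha, beta) {
  if (k < 0L) return(0)
  if (k >= size) return(1)
  min(1, sum(exp(.ldbetabinom(0:k, size, alpha, beta))))
}
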