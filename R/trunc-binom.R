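#' Probability mass function of a truncated binomial read count
#'
#' Density of the mutant read count at a site covered by `specSize(spec)`
#' reads, conditional on the count reaching the retention cut
#' `minCount(spec)`: the binomial pmf renormalised by the upper-tail mass
#' `P(X >= minCount)`. With `minCount = 1` this is the zero-truncated
#' binomial that governs observed mutant read proportions; with
#' `minCount = ceiling(tau * size)` it is the distribution of read counts at
#' sites whose observed proportion clears the TMB frequency threshold.
#'
#' @param x Integer count(s) within `[minCount, size]`.
#' @param spec A [TruncationSpec-class].
#' @param f True mutant allele frequency. Must lie strictly inside `(0, 1)`
#'   when `minCount > 0` (otherwise the conditioning event can have zero
#'   probability).
#' @return Probabilities summing to 1 over the truncated support.
#' @examples
#' truncatedPmf(2, TruncationSpec(2, 1), 0.5)  # 1/3
#' sum(truncatedPmf(5:100, TruncationSpec(100, 5), 0.05))  # 1
#' @export
truncatedPmf <- function(x, spec, f) {
  stopifnot(is(spec, "TruncationSpec"))
  f <- .checkFreq(f, spec)
  x <- vapply(x, .asCount, 0L, name = "x")
  if (any(x < spec@minCount) || any(x > spec@size))
    stop("'x' must lie in [minCount, size] = [", spec@minCount, ", ",
         spec@size, "]", call. = FALSE)
  exp(stats::dbinom(x, spec@size, f, log = TRUE) - .logTailMass(spec, f))
}

#' Expected observed mutant proportion under truncation
#'
#' `E[X / N | X >= minCount]` for a binomial read count of size
#' `N = specSize(spec)` and success probability `f`. For the zero-truncated
#' case this has the closed form `f / (1 - (1 - f)^N)`; the general case is
#' evaluated by summation over the truncated support. The value always
#' exceeds `f` when `minCount > 0` — the observed proportion of mutant reads
#' is an upwardly biased estimator of the mutation frequency.
#'
#' @inheritParams truncatedPmf
#' @return The truncated mean proportion, a number in `[f, 1]`.
#' @examples
#' truncatedMeanProportion(TruncationSpec(2, 1), 0.5)  # 2/3
#' truncatedMeanProportion(TruncationSpec(100, 1), 0.1)
#' 0.1 / (1 - 0.9^100)  # the same, closed form
#' @export
truncatedMeanProportion <- function(spec, f) {
  stopifnot(is(spec, "TruncationSpec"))
  f <- .checkFreq(f, spec)
  if (spec@minCount == 0L) return(f)
  supp <- spec@minCount:spec@size
  p <- exp(stats::dbinom(supp, spec@size, f, log = TRUE) -
             .logTailMass(spec, f))
  sum(supp / spec@size * p)
}

#' Sample truncated binomial read counts
#'
#' Draws `n` i.i.d. counts from the truncated binomial defined by `spec` and
#' `f`. Uses rejection sampling from the untruncated binomial; when the
#' acceptance probability `P(X >= minCount)` falls below 0.01 it switches to
#' exact inverse-CDF sampling (a uniform draw on the conditioned CDF range
#' mapped through `qbinom`), so rare conditioning events cost O(n) rather
#' than O(n / P).
#'
#' @inheritParams truncatedPmf
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Integer vector of length `n`, all within `[minCount, size]`.
#' @examples
#' range(sampleTruncated(TruncationSpec(100, 5), 0.05, 1000, seed = 1))
#' @export
sampleTruncated <- function(spec, f, n, seed) {
  stopifnot(is(spec, "TruncationSpec"))
  f <- .checkFreq(f, spec)
  n <- .asCount(n, "n")
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  accept <- exp(.logTailMass(spec, f))
  if (accept <= 0 || !is.finite(accept))
    stop("conditioning event {X >= ", spec@minCount,
         "} has numerically zero probability at f = ", f, call. = FALSE)
  .withSeed(seed, {
    if (spec@minCount == 0L) {
      stats::rbinom(n, spec@size, f)
    } else if (accept >= 0.01) {
      out <- integer(0)
      while (length(out) < n) {
        m <- ceiling((n - length(out)) / accept * 1.1) + 10L
        draw <- stats::rbinom(m, spec@size, f)
        out <- c(out, draw[draw >= spec@minCount])
      }
      out[seq_len(n)]
    } else {
      # inverse-CDF fallback: uniform on (F(minCount - 1), 1]
      lo <- stats::pbinom(spec@minCount - 1L, spec@size, f)
      u <- lo + stats::runif(n) * (1 - lo)
      pmin(stats::qbinom(u, spec@size, f), spec@size)
    }
  })
}

#' Fisher's maximum-likelihood estimate of a truncated binomial frequency
#'
#' Maximises the truncated binomial log-likelihood
#' `sum(log dbinom(x_i; N, f)) - n * log P(X >= minCount; N, f)` over `f` by
#' bounded one-dimensional search on `[1e-8, 1 - 1e-8]` (tolerance 1e-8).
#' The likelihood is unimodal (truncation of a one-parameter exponential
#' family), so golden-section/parabolic search suffices. This removes the
#' upward bias of the naive retained-proportion estimator.
#'
#' @param counts Integer vector of retained counts, all within
#'   `[minCount, size]`.
#' @param spec A [TruncationSpec-class].
#' @return A [FrequencyEstimate-class]. When all counts equal `size` the
#'   estimate is pinned at the upper bound and flagged (with a warning);
#'   similarly at the lower bound for untruncated all-zero data.
#' @examples
#' x <- sampleTruncated(TruncationSpec(100, 5), 0.04, 2000, seed = 1)
#' fitTruncatedML(x, TruncationSpec(100, 5))
#' mean(x) / 100  # naive estimate, biased upwards
#' @export
fitTruncatedML <- function(counts, spec) {
  stopifnot(is(spec, "TruncationSpec"))
  if (length(counts) < 1L) stop("'counts' must be non-empty", call. = FALSE)
  counts <- vapply(counts, .asCount, 0L, name = "counts")
  if (any(counts < spec@minCount) || any(counts > spec@size))
    stop("all counts must lie in [minCount, size]", call. = FALSE)
  eps <- 1e-8
  n <- length(counts)
  if (all(counts == spec@size)) {
    warning("all counts equal 'size'; estimate pinned at the upper bound")
    return(new("FrequencyEstimate", value = 1 - eps, nObs = n,
               stderr = NA_real_, atBoundary = TRUE))
  }
  if (all(counts == 0L) && spec@minCount == 0L) {
    warning("all counts are zero; estimate pinned at the lower bound")
    return(new("FrequencyEstimate", value = eps, nObs = n,
               stderr = NA_real_, atBoundary = TRUE))
  }
  sx <- sum(counts)
  # log-likelihood up to an f-free constant: sufficient statistic is sum(x)
  ll <- function(f)
    sx * log(f) + (n * spec@size - sx) * log1p(-f) -
      n * .logTailMass(spec, f)
  opt <- stats::optimize(ll, c(eps, 1 - eps), maximum = TRUE, tol = 1e-8)
  fhat <- opt$maximum
  boundary <- fhat <= eps * 2 || fhat >= 1 - eps * 2
  se <- NA_real_
  if (!boundary) {
    h <- max(1e-6, fhat * 1e-4)
    hess <- (ll(fhat + h) - 2 * ll(fhat) + ll(fhat - h)) / h^2
    if (is.finite(hess) && hess < 0) se <- sqrt(-1 / hess)
  }
  new("FrequencyEstimate", value = fhat, nObs = n, stderr = se,
      atBoundary = boundary)
}

#' Naive retained-proportion frequency estimate
#'
#' The uncorrected estimator the truncated ML fit is compared against: the
#' observed proportion of mutant reads among retained draws. `pooled =
#' FALSE` (default) averages the per-draw proportions `x_i / N`, the
#' per-sample estimate; `pooled = TRUE` divides the pooled count by the
#' pooled read total. The two coincide for equal-size draws but are exposed
#' separately because both conventions occur in practice.
#'
#' @param counts Retained counts.
#' @param size Reads per draw.
#' @param pooled Pool counts before dividing?
#' @return The naive frequency estimate.
#' @export
retainedProportion <- function(counts, size, pooled = FALSE) {
  size <- .asCount(size, "size")
  if (length(counts) < 1L) stop("'counts' must be non-empty", call. = FALSE)
  if (pooled) sum(counts) / (length(counts) * size)
  else mean(counts / size)
}

# log P(X >= minCount; size, f)
.logTailMass <- function(spec, f) {
  if (spec@minCount == 0L) return(0)
  stats::pbinom(spec@minCount - 1L, spec@size, f, lower.tail = FALSE,
                log.p = TRUE)
}

.checkFreq <- function(f, spec) {
  if (spec@minCount > 0L) .asProb(f, "f", open_lo = TRUE, open_hi = TRUE)
  else .asProb(f, "f")
}
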