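test_that("beta spectrum CDF matches quadrature", {
  expect_equal(betaSpectrumCdf(0.5, BetaSpectrum(1, 1)), 0.5)
  expect_equal(betaSpectrumCdf(0.05, BetaSpectrum(1, 1)), 0.05)
  expect_equal(betaSpectrumCdf(0, BetaSpectrum(2, 20)), 0)
  expect_equal(betaSpectrumCdf(1, BetaSpectrum(2, 20)), 1)
  q <- integrate(function(p) dbeta(p, 0.1, 100), 0, 0.05,
                 rel.tol = 1e-10)$value
  expect_equal(betaSpectrumCdf(0.05, BetaSpectrum(0.1, 100)), q,
               tolerance = 1e-8)
  expect_error(betaSpectrumCdf(1.2, BetaSpectrum(1, 1)), "\\[0, 1\\]")
  expect_error(BetaSpectrum(-1, 2), "positive")
})

test_that("beta-binomial pmf/cdf agree with mixture quadrature", {
  expect_equal(betaBinomialCdf(7, 7, BetaSpectrum(2, 20)), 1.0)
  expect_equal(betaBinomialCdf(0, 1, BetaSpectrum(1, 1)), 0.5)
  expect_equal(betaBinomialCdf(0, 1, BetaSpectrum(0.1, 100)), 100 / 100.1)
  # pmf normalises at large depth (log-space accumulation)
  expect_equal(sum(betaBinomialPmf(0:200, 200, BetaSpectrum(0.1, 100))), 1,
               tolerance = 1e-10)
  # independent oracle: integrate the binomial CDF against the beta density
  for (case in list(list(k = 4L, d = 100L, sp = c(0.1, 100)),
                    list(k = 10L, d = 50L, sp = c(2, 20)))) {
    oracle <- integrate(function(p)
      pbinom(case$k, case$d, p) * dbeta(p, case$sp[1], case$sp[2]),
      0, 1, rel.tol = 1e-9)$value
    expect_equal(
      betaBinomialCdf(case$k, case$d, BetaSpectrum(case$sp[1], case$sp[2])),
      oracle, tolerance = 1e-6)
  }
  expect_error(betaBinomialCdf(8, 7, BetaSpectrum(1, 1)), "\\[0, size\\]")
})

test_that("true above-threshold count follows the spectrum tail", {
  expect_equal(trueCountAboveThreshold(100, 0, BetaSpectrum(0.1, 100)), 100)
  expect_equal(trueCountAboveThreshold(100, 0.05, BetaSpectrum(1, 1)), 95)
  sp <- BetaSpectrum(0.1, 100)
  q <- integrate(function(p) dbeta(p, 0.1, 100), 0.05, 1,
                 rel.tol = 1e-10)$value
  expect_equal(trueCountAboveThreshold(200, 0.05, sp), 200 * q,
               tolerance = 1e-6)
  taus <- c(0, 0.01, 0.05, 0.2, 0.5)
  tc <- vapply(taus, trueCountAboveThreshold, 0, S = 100, spectrum = sp)
  expect_true(all(diff(tc) <= 0))
})

test_that("expected observed count matches closed cases and Monte Carlo", {
  expect_equal(expectedObservedCount(rep(1, 100), 0.05, BetaSpectrum(1, 1)),
               50)
  expect_equal(
    expectedObservedCount(rep(1, 100), 0.05, BetaSpectrum(0.1, 100)),
    100 * 0.1 / 100.1)
  expect_warning(e0 <- expectedObservedCount(integer(0), 0.05,
                                             BetaSpectrum(1, 1)), "empty")
  expect_equal(e0, 0)

  # Monte Carlo oracle at the simulation scale used throughout
  sp <- BetaSpectrum(0.1, 100)
  e <- expectedObservedCount(rep(100, 200), 0.05, sp)
  counts <- withr::with_seed(42, vapply(1:500, function(r) {
    f <- rbeta(200, 0.1, 100)
    sum(rbinom(200, 100, f) >= 5)
  }, 0))
  expect_lt(abs(e - mean(counts)), 3 * seMean(counts))

  # monotone in tau at fixed depth; bounded by the number of sites
  es <- vapply(c(0.02, 0.05, 0.1, 0.3),
               function(tt) expectedObservedCount(rep(100, 50), tt, sp), 0)
  expect_true(all(diff(es) <= 0))
  expect_true(all(es >= 0 & es <= 50))
})

test_that("relative error quantifies threshold-crossing bias and its decay", {
  expect_equal(relativeTmbError(95, 95), 0)
  expect_equal(relativeTmbError(1.5 * 80, 80), 0.5)
  expect_error(relativeTmbError(10, 0), "undefined")

  crv <- relativeErrorCurve(BetaSpectrum(0.1, 100), 0.05,
                            c(50, 100, 10000), 200)
  expect_identical(nrow(crv), 3L)
  expect_true(all(crv$trueCount == crv$trueCount[1]))
  expect_gt(crv$relativeError[2], 0)      # over-estimation at depth 100
  expect_lt(abs(crv$relativeError[3]), abs(crv$relativeError[1]))

  flat <- relativeErrorCurve(BetaSpectrum(1, 1), 0.05, 1000, 100)
  expect_identical(nrow(flat), 1L)
  expect_lt(abs(flat$relativeError), 0.05)

  expect_error(relativeErrorCurve(BetaSpectrum(1, 1), 0.05, c(100, 50), 10),
               "ascending")
})

test_that("expected count converges to the spectrum tail at high depth", {
  for (sp in list(BetaSpectrum(0.1, 100), BetaSpectrum(0.3, 30),
                  BetaSpectrum(1, 1))) {
    eOverS <- expectedObservedCount(rep(10000, 1), 0.05, sp)
    limit <- 1 - betaSpectrumCdf(0.05, sp)
    expect_lt(abs(eOverS - limit), 0.01)
  }
})

test_that("spectrumBiasResult bundles a consistent triple", {
  r <- spectrumBiasResult(200, 0.05, BetaSpectrum(0.1, 100), 100)
  expect_equal(r@relativeError,
               (r@expectedCount - r@trueCount) / r@trueCount)
  expect_true(r@trueCount <= 200 && r@expectedCount <= 200)
  expect_identical(length(r@depths), 200L)
})
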