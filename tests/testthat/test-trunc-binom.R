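test_that("truncated pmf matches enumeration and normalises on its support", {
  # conditioning on X >= 1 with a single read forces X = 1
  expect_equal(truncatedPmf(1, TruncationSpec(1, 1), 0.3), 1.0)
  # enumeration: P(2) / (P(1) + P(2)) at N = 2, f = 0.5
  expect_equal(truncatedPmf(2, TruncationSpec(2, 1), 0.5),
               dbinom(2, 2, 0.5) / (dbinom(1, 2, 0.5) + dbinom(2, 2, 0.5)))
  for (N in c(2L, 5L, 100L)) {
    for (cc in c(0L, 1L, min(5L, N))) {
      for (f in c(0.05, 0.3, 0.7)) {
        p <- truncatedPmf(cc:N, TruncationSpec(N, cc), f)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_true(all(p >= 0))
      }
    }
  }
})

test_that("truncated pmf rejects out-of-domain arguments", {
  spec <- TruncationSpec(100, 5)
  expect_error(truncatedPmf(4, spec, 0.1), "minCount")
  expect_error(truncatedPmf(101, spec, 0.1), "minCount")
  expect_error(truncatedPmf(10, spec, 0), "'f'")
  expect_error(truncatedPmf(10, spec, 1), "'f'")
  expect_error(TruncationSpec(10, 11), "exceed")
})

test_that("truncated mean proportion matches closed form and brute force", {
  expect_equal(truncatedMeanProportion(TruncationSpec(1, 1), 0.7), 1.0)
  expect_equal(truncatedMeanProportion(TruncationSpec(2, 1), 0.5), 2 / 3)
  expect_equal(truncatedMeanProportion(TruncationSpec(100, 0), 0.3), 0.3)
  # zero-truncated closed form f / (1 - (1 - f)^N)
  for (N in c(10L, 100L, 500L)) {
    for (f in c(0.01, 0.1, 0.5)) {
      expect_equal(truncatedMeanProportion(TruncationSpec(N, 1), f),
                   f / (1 - (1 - f)^N), tolerance = 1e-10)
    }
  }
  # independent oracle: enumerate all 2^N read outcomes at N = 10
  N <- 10L
  outcomes <- as.matrix(expand.grid(rep(list(0:1), N)))
  k <- rowSums(outcomes)
  for (f in c(0.1, 0.5)) {
    prob <- f^k * (1 - f)^(N - k)
    for (cc in 1:3) {
      keep <- k >= cc
      oracle <- sum((k[keep] / N) * prob[keep]) / sum(prob[keep])
      expect_equal(truncatedMeanProportion(TruncationSpec(N, cc), f), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("truncation biases the mean proportion upwards, vanishing with depth", {
  for (f in c(0.02, 0.1, 0.4)) {
    means <- vapply(0:6, function(cc)
      truncatedMeanProportion(TruncationSpec(20L, cc), f), 0)
    expect_true(all(diff(means) > 0))       # strictly increasing in the cut
    expect_equal(means[1], f)               # untruncated is unbiased
    expect_true(all(means[-1] > f))
  }
  # the gap decays geometrically; beyond N ~ 400 it sits below double
  # precision at f = 0.1, so compare with a float-noise allowance
  gaps <- vapply(c(10L, 50L, 100L, 500L, 1000L), function(N)
    truncatedMeanProportion(TruncationSpec(N, 1), 0.1) - 0.1, 0)
  expect_true(all(diff(gaps) <= 1e-12))
  expect_gt(gaps[1], gaps[3])
  expect_lt(abs(gaps[5]), 1e-4)
})

test_that("truncated sampling is exact, seeded and supports both samplers", {
  spec <- TruncationSpec(100, 5)
  x <- sampleTruncated(spec, 0.05, 1000, seed = 1)
  expect_true(all(x >= 5 & x <= 100))
  expect_identical(x, sampleTruncated(spec, 0.05, 1000, seed = 1))
  expect_false(identical(x, sampleTruncated(spec, 0.05, 1000, seed = 2)))

  # untruncated: plain binomial mean
  x0 <- sampleTruncated(TruncationSpec(100, 0), 0.3, 20000, seed = 3)
  expect_lt(abs(mean(x0 / 100) - 0.3), 3 * seMean(x0 / 100))

  # rejection regime: acceptance prob ~0.56
  x1 <- sampleTruncated(spec, 0.05, 100000, seed = 4)
  expect_lt(abs(mean(x1 / 100) - truncatedMeanProportion(spec, 0.05)),
            3 * seMean(x1 / 100))

  # inverse-CDF fallback regime: P(X >= 5 | f = 0.01) ~ 3e-3 < 0.01
  x2 <- sampleTruncated(spec, 0.01, 20000, seed = 5)
  expect_true(all(x2 >= 5))
  expect_lt(abs(mean(x2 / 100) - truncatedMeanProportion(spec, 0.01)),
            3 * seMean(x2 / 100))
})

test_that("Fisher ML removes the truncation bias of the naive proportion", {
  # recovery at f = 0.3 under zero truncation
  spec1 <- TruncationSpec(100, 1)
  fit1 <- fitTruncatedML(sampleTruncated(spec1, 0.3, 10000, seed = 1), spec1)
  expect_lt(abs(estValue(fit1) - 0.3), 0.005)
  expect_identical(nObs(fit1), 10000L)
  expect_false(atBoundary(fit1))

  # strong truncation at f = 0.04, cut 5: ML sits below the naive mean
  spec5 <- TruncationSpec(100, 5)
  x <- sampleTruncated(spec5, 0.04, 10000, seed = 1)
  fit5 <- fitTruncatedML(x, spec5)
  expect_lt(estValue(fit5), retainedProportion(x, 100))
  expect_lt(abs(estValue(fit5) - 0.04), 0.01)

  # pooled and per-draw naive estimators agree for equal-size draws
  expect_equal(retainedProportion(x, 100),
               retainedProportion(x, 100, pooled = TRUE))
})

test_that("Fisher ML handles degenerate inputs", {
  expect_warning(fit <- fitTruncatedML(rep(10L, 5), TruncationSpec(10, 1)),
                 "upper bound")
  expect_true(atBoundary(fit))
  expect_equal(estValue(fit), 1 - 1e-8)
  expect_error(fitTruncatedML(integer(0), TruncationSpec(10, 1)),
               "non-empty")
  expect_error(fitTruncatedML(c(3L, 11L), TruncationSpec(10, 1)),
               "minCount")
})

test_that("Fisher ML is consistent over replicates", {
  spec <- TruncationSpec(100, 5)
  ests <- vapply(1:200, function(r)
    estValue(fitTruncatedML(sampleTruncated(spec, 0.1, 2000, seed = r),
                            spec)), 0)
  expect_lt(abs(mean(ests) - 0.1), 3 * seMean(ests))
})
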