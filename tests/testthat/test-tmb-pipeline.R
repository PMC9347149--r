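test_that("detection filters by minimum alt reads, preserving order", {
  s <- makeSiteSample(alt = c(0L, 2L, 3L, 10L), depth = rep(100L, 4))
  det <- detectMutations(s, minAltReads = 3)
  expect_identical(nrow(det), 2L)
  expect_identical(det$site_id, c("s003", "s004"))
  expect_identical(nrow(detectMutations(s, 1)), 3L)
  expect_error(detectMutations(s, 0), "minAltReads")
})

test_that("detection probability matches the beta-binomial tail", {
  sp <- BetaSpectrum(0.1, 100)
  pDetect <- 1 - betaBinomialCdf(2, 100, sp)
  fr <- vapply(1:50, function(r) {
    s <- simulateSample(SimulationConfig(0, 2000, spectrum = sp,
                                         depthModel = depthModelFixed(100),
                                         seed = 100 + r))
    nrow(detectMutations(s, 3)) / 2000
  }, 0)
  expect_lt(abs(mean(fr) - pDetect), 3 * seMean(fr))
})

test_that("threshold TMB counts pass sites per megabase", {
  s <- makeSiteSample(alt = c(10L, 49L, 50L, 400L), depth = rep(1000L, 4))
  r <- estimateTmbThreshold(s, tau = 0.05, minAltReads = 1)
  expect_identical(nPass(r), 2L)           # 0.05 and 0.40 pass; 0.049 not
  expect_identical(nDetected(r), 4L)
  expect_equal(tmbValue(r), 2.0)           # region is 1 Mb
  # threshold above every observed VAF
  expect_equal(tmbValue(estimateTmbThreshold(s, tau = 0.41,
                                             minAltReads = 1)), 0)
})

test_that("threshold TMB is monotone in tau and the detection cut", {
  s <- simulateSample(SimulationConfig(50, 450, seed = 17))
  tmbs <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4),
                 function(tt) tmbValue(estimateTmbThreshold(s, tt, 1)), 0)
  expect_true(all(diff(tmbs) <= 0))
  byCut <- vapply(c(1L, 3L, 5L, 10L),
                  function(m) tmbValue(estimateTmbThreshold(s, 0.05, m)), 0)
  expect_true(all(diff(byCut) <= 0))
})

test_that("mean threshold count agrees with the beta-binomial expectation", {
  sp <- BetaSpectrum(2, 20)
  eTheory <- expectedObservedCount(rep(100, 2000), 0.05, sp)
  counts <- vapply(1:30, function(r) {
    s <- simulateSample(SimulationConfig(0, 2000, spectrum = sp,
                                         depthModel = depthModelFixed(100),
                                         regionSizeMb = 1, seed = 200 + r))
    nPass(estimateTmbThreshold(s, 0.05, 3))
  }, 0L)
  expect_lt(abs(mean(counts) - eTheory), 3 * seMean(counts))
})

test_that("threshold counting over-estimates under a steep spectrum", {
  sp <- BetaSpectrum(0.1, 100)
  truth <- trueCountAboveThreshold(5000, 0.05, sp)
  counts <- vapply(1:100, function(r) {
    s <- simulateSample(SimulationConfig(0, 5000, spectrum = sp,
                                         depthModel = depthModelFixed(100),
                                         regionSizeMb = 1, seed = 300 + r))
    nPass(estimateTmbThreshold(s, 0.05, 3))
  }, 0L)
  expect_gt(mean(counts), truth)
  expect_gt(mean(counts) - 3 * seMean(counts), truth)
})

test_that("purity adjustment rescales observed VAF and improves TMB", {
  s <- makeSiteSample(alt = c(20L, 10L), depth = c(100L, 100L),
                      purity = 0.5)
  adj <- purityAdjust(s)
  expect_equal(sites(adj)$obs_vaf, c(0.4, 0.2))
  expect_identical(purityAdjust(s, 1), s)
  expect_error(purityAdjust(s, 0), "purity")

  closer <- vapply(1:50, function(r) {
    s1 <- simulateSample(SimulationConfig(60, 540, purity = 1, seed = r))
    s6 <- simulateSample(SimulationConfig(60, 540, purity = 0.6, seed = r))
    t1 <- tmbValue(estimateTmbThreshold(s1))
    tu <- tmbValue(estimateTmbThreshold(s6))
    ta <- tmbValue(estimateTmbThreshold(purityAdjust(s6)))
    abs(ta - t1) <= abs(tu - t1)
  }, TRUE)
  expect_gte(sum(closer), 45L)
})
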