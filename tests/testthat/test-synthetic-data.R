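test_that("simulateSample realises the configured generative model", {
  # 200 loci at constant depth 100, purely subclonal
  cfg <- SimulationConfig(nClonal = 0, nSubclonal = 200,
                          spectrum = BetaSpectrum(0.1, 100),
                          depthModel = depthModelFixed(100), seed = 7)
  s <- simulateSample(cfg)
  expect_identical(nrow(sites(s)), 200L)
  expect_true(all(sites(s)$depth == 100L))
  expect_true(all(!sites(s)$is_clonal))
  expect_equal(clonalFraction(s), 0)

  # purity scales every clonal site's sampling frequency multiplicatively
  cfgP <- SimulationConfig(nClonal = 50, nSubclonal = 0, purity = 0.5,
                           clonalVaf = 0.5, seed = 2)
  sP <- simulateSample(cfgP)
  expect_true(all(sites(sP)$true_vaf == 0.25))

  # subclonal frequencies follow the configured beta spectrum
  cfgB <- SimulationConfig(nClonal = 0, nSubclonal = 10000,
                           spectrum = BetaSpectrum(0.1, 100),
                           depthModel = depthModelFixed(50), seed = 3)
  tv <- sites(simulateSample(cfgB))$true_vaf
  expect_lt(abs(mean(tv) - 0.1 / 100.1), 3 * seMean(tv))

  # identical config => bit-identical sample
  expect_identical(sites(simulateSample(cfg)), sites(s))
})

test_that("simulation config validation lists offending fields", {
  expect_error(SimulationConfig(0, 0), "nClonal")
  expect_error(SimulationConfig(1, 1, purity = 1.5), "purity")
  expect_error(SimulationConfig(1, 1, regionSizeMb = 0), "regionSizeMb")
  expect_error(
    validObject(new("SimulationConfig", nClonal = 1L, nSubclonal = 1L,
                    spectrum = BetaSpectrum(1, 1), clonalVaf = 0.5,
                    purity = 1, depthModel = list(type = "weird"),
                    regionSizeMb = 1, seed = 1L)),
    "depthModel")
})

test_that("subclonal spectrum fidelity: empirical CDF tracks the beta CDF", {
  cfg <- SimulationConfig(nClonal = 0, nSubclonal = 10000,
                          spectrum = BetaSpectrum(2, 20),
                          depthModel = depthModelFixed(100), seed = 11)
  tv <- sort(sites(simulateSample(cfg))$true_vaf)
  ecdfv <- seq_along(tv) / length(tv)
  ks <- max(abs(ecdfv - pbeta(tv, 2, 20)))
  expect_lt(ks, 0.02)
})

test_that("read-level down-sampling obeys the thinning laws", {
  cfg <- SimulationConfig(nClonal = 100, nSubclonal = 900, seed = 5)
  s <- simulateSample(cfg)
  expect_identical(downsampleSample(s, 1, seed = 1), s)

  d5 <- downsampleSample(s, 0.5, seed = 9)
  expect_true(all(sites(d5)$alt_count <= sites(s)$alt_count))
  expect_true(all(sites(d5)$depth <= sites(s)$depth))
  halfGap <- sites(d5)$depth - 0.5 * sites(s)$depth
  expect_lt(abs(mean(halfGap)), 3 * seMean(halfGap))

  # thinning law at one site: alt' ~ Binomial(4, 0.5) across 10,000 sites
  one <- makeSiteSample(rep(4L, 10000), rep(100L, 10000))
  alt <- sites(downsampleSample(one, 0.5, seed = 13))$alt_count
  obs <- tabulate(alt + 1L, nbins = 5L)
  gof <- chisq.test(obs, p = dbinom(0:4, 4, 0.5))
  expect_gt(gof$p.value, 0.01)

  expect_error(downsampleSample(s, 0, seed = 1), "fraction")
  expect_error(downsampleSample(s, 1.2, seed = 1), "fraction")
})

test_that("sequential thinning composes multiplicatively", {
  s <- simulateSample(SimulationConfig(0, 5000, seed = 21))
  twoStep <- downsampleSample(downsampleSample(s, 0.6, seed = 1), 0.5,
                              seed = 2)
  oneStep <- downsampleSample(s, 0.3, seed = 3)
  d2 <- sites(twoStep)$depth
  d1 <- sites(oneStep)$depth
  expect_lt(abs(mean(d2) - mean(d1)),
            3 * sqrt(seMean(d1)^2 + seMean(d2)^2))
  expect_lt(abs(sd(d2) / sd(d1) - 1), 0.05)
})

test_that("cohort generation spans the requested ranges reproducibly", {
  base <- SimulationConfig(nClonal = 10, nSubclonal = 90, seed = 1)
  co <- simulateCohort(base, 10, c(100, 100), c(1, 1), seed = 4)
  expect_identical(length(co), 10L)
  expect_true(all(vapply(co, clonalFraction, 0) == 1))
  co0 <- simulateCohort(base, 5, c(80, 120), c(0, 0), seed = 4)
  expect_true(all(vapply(co0, clonalFraction, 0) == 0))

  coU <- simulateCohort(base, 100, c(50, 400), c(0, 1), seed = 8)
  pHigh <- mean(vapply(coU, clonalFraction, 0) > 0.5)
  expect_lt(abs(pHigh - 0.5), 3 * sqrt(0.25 / 100))

  expect_identical(
    lapply(simulateCohort(base, 5, c(80, 120), c(0, 1), seed = 6), sites),
    lapply(simulateCohort(base, 5, c(80, 120), c(0, 1), seed = 6), sites))
  expect_error(simulateCohort(base, 1, c(80, 120), c(0, 1), seed = 1),
               "nSamples")
  expect_error(simulateCohort(base, 5, c(120, 80), c(0, 1), seed = 1),
               "depthRange")
})

test_that("purity scaling concentrates observed VAF near purity * f", {
  cfg <- SimulationConfig(nClonal = 2000, nSubclonal = 0, purity = 0.7,
                          clonalVaf = 0.5,
                          depthModel = depthModelFixed(10000), seed = 9)
  ov <- sites(simulateSample(cfg))$obs_vaf
  expect_lt(abs(mean(ov) - 0.35), 3 * seMean(ov))
})
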