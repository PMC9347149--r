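#' Per-site depth models
#'
#' Constructors for the depth model used by [simulateSample()]: constant
#' depth, Poisson-distributed depth (the default in cohort simulations,
#' emulating coverage variation across a capture region), or
#' negative-binomial depth for over-dispersed coverage. Simulated depths are
#' floored at 1 read.
#'
#' @param depth Constant per-site depth.
#' @param mean Mean per-site depth.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   over-dispersed).
#' @return A depth-model list consumed by [SimulationConfig()].
#' @examples
#' depthModelFixed(100)
#' depthModelPoisson(80)
#' @name depthModels
NULL

#' @rdname depthModels
#' @export
depthModelFixed <- function(depth) {
  list(type = "fixed", depth = .asCount(depth, "depth"))
}

#' @rdname depthModels
#' @export
depthModelPoisson <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  list(type = "poisson", mean = as.numeric(mean))
}

#' @rdname depthModels
#' @export
depthModelNegBin <- function(mean, dispersion) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0)
    stop("'dispersion' must be a single positive number", call. = FALSE)
  list(type = "nbinom", mean = as.numeric(mean),
       dispersion = as.numeric(dispersion))
}

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of each field. The default
#' subclonal spectrum, `BetaSpectrum(2, 20)`, emulates a detectable subclone
#' cluster (mean VAF 0.09, density mode at 0.05); pass
#' `BetaSpectrum(0.1, 100)` for a steep neutral-tail-like spectrum dominated
#' by very-low-frequency mutations.
#'
#' @param nClonal,nSubclonal Numbers of clonal / subclonal mutations.
#' @param spectrum Subclonal [BetaSpectrum-class].
#' @param clonalVaf Cell-level clonal frequency, default 0.5 (heterozygous
#'   diploid).
#' @param purity Tumour purity in `(0, 1]`.
#' @param depthModel See [depthModels].
#' @param regionSizeMb Target region size in megabases (default 30,
#'   exome-like).
#' @param seed Integer seed.
#' @return A validated [SimulationConfig-class] object.
#' @export
SimulationConfig <- function(nClonal, nSubclonal,
                             spectrum = BetaSpectrum(2, 20),
                             clonalVaf = 0.5, purity = 1,
                             depthModel = depthModelPoisson(100),
                             regionSizeMb = 30, seed = 1L) {
  new("SimulationConfig", nClonal = .asCount(nClonal, "nClonal"),
      nSubclonal = .asCount(nSubclonal, "nSubclonal"), spectrum = spectrum,
      clonalVaf = as.numeric(clonalVaf), purity = as.numeric(purity),
      depthModel = depthModel, regionSizeMb = as.numeric(regionSizeMb),
      seed = .asCount(seed, "seed"))
}

.configAsList <- function(config) {
  list(nClonal = config@nClonal, nSubclonal = config@nSubclonal,
       alpha = config@spectrum@alpha, beta = config@spectrum@beta,
       clonalVaf = config@clonalVaf, purity = config@purity,
       depthModel = config@depthModel, regionSizeMb = config@regionSizeMb,
       seed = config@seed)
}

.drawDepths <- function(model, n) {
  d <- switch(model$type,
    fixed = rep(model$depth, n),
    poisson = stats::rpois(n, model$mean),
    nbinom = stats::rnbinom(n, size = model$dispersion, mu = model$mean),
    stop("unknown depth model type: ", model$type, call. = FALSE))
  pmax(1L, as.integer(d))
}

#' Simulate a tumour sample
#'
#' Generates one synthetic tumour sample under the configured generative
#' model: clonal sites carry cell-level frequency `clonalVaf`, subclonal
#' sites draw their frequency from the beta spectrum; frequencies are scaled
#' by `purity` (normal-cell contamination dilutes the mutant reads), depths
#' come from the depth model, and alt read counts are
#' `Binomial(depth, purity * f)`. Fully deterministic for a fixed config
#' (including its seed).
#'
#' @param config A [SimulationConfig-class].
#' @return A [TumourSample-class].
#' @examples
#' cfg <- SimulationConfig(nClonal = 0, nSubclonal = 200,
#'                         spectrum = BetaSpectrum(0.1, 100),
#'                         depthModel = depthModelFixed(100), seed = 7)
#' simulateSample(cfg)
#' @export
simulateSample <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  S <- config@nClonal + config@nSubclonal
  .withSeed(config@seed, {
    fSub <- stats::rbeta(config@nSubclonal, config@spectrum@alpha,
                         config@spectrum@beta)
    fCell <- c(rep(config@clonalVaf, config@nClonal), fSub)
    isClonal <- rep(c(TRUE, FALSE), c(config@nClonal, config@nSubclonal))
    trueVaf <- config@purity * fCell
    depth <- .drawDepths(config@depthModel, S)
    alt <- stats::rbinom(S, depth, trueVaf)
    sites <- data.frame(
      site_id = sprintf("site%06d", seq_len(S)),
      true_vaf = trueVaf, depth = depth, alt_count = alt,
      is_clonal = isClonal, obs_vaf = ifelse(depth > 0, alt / depth, NA_real_),
      stringsAsFactors = FALSE)
    new("TumourSample", sites = sites, purity = config@purity,
        clonalFraction = config@nClonal / S,
        regionSizeMb = config@regionSizeMb, seed = config@seed,
        config = .configAsList(config))
  })
}

#' Down-sample a tumour sample at read level
#'
#' Emulates random read sub-sampling of an alignment to a given fraction:
#' independently thins the mutant reads (`Binomial(alt_count, fraction)`)
#' and the reference reads (`Binomial(depth - alt_count, fraction)`) at each
#' site; the new depth is their sum. `fraction = 1` returns an identical
#' copy. Sites may end with depth 0; they are retained with `obs_vaf = NA`
#' and are undetectable downstream.
#'
#' @param sample A [TumourSample-class].
#' @param fraction Retention fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A [TumourSample-class] with thinned reads.
#' @export
downsampleSample <- function(sample, fraction, seed) {
  stopifnot(is(sample, "TumourSample"))
  fraction <- .asProb(fraction, "fraction", open_lo = TRUE)
  if (fraction == 1) return(sample)
  s <- sample@sites
  .withSeed(seed, {
    alt <- stats::rbinom(nrow(s), s$alt_count, fraction)
    ref <- stats::rbinom(nrow(s), s$depth - s$alt_count, fraction)
    s$alt_count <- alt
    s$depth <- alt + ref
    s$obs_vaf <- ifelse(s$depth > 0, s$alt_count / s$depth, NA_real_)
    out <- sample
    out@sites <- s
    out
  })
}

#' Simulate a cohort of tumour samples
#'
#' Generates `nSamples` samples sharing the base configuration, with each
#' sample's mean depth drawn uniformly from `depthRange` and its clonal
#' fraction uniformly from `clonalFractionRange` (the total number of sites
#' is held at `nClonal + nSubclonal` of the base config). Per-sample seeds
#' are derived from the master `seed`, so the cohort is reproducible
#' end-to-end.
#'
#' @param base A [SimulationConfig-class] providing the shared settings.
#' @param nSamples Number of samples (>= 2).
#' @param depthRange Length-2 vector `(low, high)` of mean depths.
#' @param clonalFractionRange Length-2 vector `(low, high)` in `[0, 1]`.
#' @param seed Master seed.
#' @return List of [TumourSample-class] objects.
#' @export
simulateCohort <- function(base, nSamples, depthRange, clonalFractionRange,
                           seed) {
  stopifnot(is(base, "SimulationConfig"))
  nSamples <- .asCount(nSamples, "nSamples")
  if (nSamples < 2L) stop("'nSamples' must be >= 2", call. = FALSE)
  if (length(depthRange) != 2L || any(depthRange <= 0) ||
      depthRange[1] > depthRange[2])
    stop("'depthRange' must be a valid (low, high) pair", call. = FALSE)
  if (length(clonalFractionRange) != 2L ||
      any(clonalFractionRange < 0) || any(clonalFractionRange > 1) ||
      clonalFractionRange[1] > clonalFractionRange[2])
    stop("'clonalFractionRange' must be a valid (low, high) pair in [0, 1]",
         call. = FALSE)
  S <- base@nClonal + base@nSubclonal
  subSeeds <- .deriveSeeds(seed, 3L * nSamples)
  meanDepths <- .withSeed(subSeeds[1L],
    stats::runif(nSamples, depthRange[1], depthRange[2]))
  cfs <- .withSeed(subSeeds[2L],
    stats::runif(nSamples, clonalFractionRange[1], clonalFractionRange[2]))
  lapply(seq_len(nSamples), function(i) {
    ncl <- as.integer(round(cfs[i] * S))
    dm <- if (base@depthModel$type == "fixed")
      depthModelFixed(round(meanDepths[i]))
    else if (base@depthModel$type == "nbinom")
      depthModelNegBin(meanDepths[i], base@depthModel$dispersion)
    else depthModelPoisson(meanDepths[i])
    cfg <- SimulationConfig(nClonal = ncl, nSubclonal = S - ncl,
                            spectrum = base@spectrum,
                            clonalVaf = base@clonalVaf, purity = base@purity,
                            depthModel = dm,
                            regionSizeMb = base@regionSizeMb,
                            seed = subSeeds[2L * nSamples + i])
    simulateSample(cfg)
  })
}
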