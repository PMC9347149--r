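# Scripted drivers reproducing the four bias analyses at desk scale on
# synthetic data. Each returns an ExperimentReport whose parameter echo
# (including every seed) reproduces the results table bit-exactly.

.report <- function(name, parameters, results, summary, t0) {
  new("ExperimentReport", name = name, parameters = parameters,
      results = results, summary = summary,
      runtime = as.numeric(proc.time()[["elapsed"]] - t0))
}

#' Truncation bias of the observed mutant read proportion
#'
#' For each true frequency `f`, draws `nReps` binomial read counts at depth
#' `size` and compares two frequency estimates: the mean observed proportion
#' over all draws, and the mean over only the retained draws (observed
#' proportion at or above `tau`). The retained mean is bounded below by
#' `tau` and exceeds the truth whenever `f` is below or near the threshold.
#'
#' @param fGrid True frequencies in `(0, 1)`.
#' @param size Reads per locus, default 100.
#' @param tau Retention threshold, default 0.05 (cut
#'   `ceiling(size * tau)`).
#' @param nReps Draws per frequency, default 1000.
#' @param seed Master seed.
#' @return An [ExperimentReport-class]; results columns `f`,
#'   `mean_untruncated`, `mean_truncated` (`NA` when no draw was retained),
#'   `n_retained`.
#' @examples
#' rep <- runTruncationBias(c(0.02, 0.3), nReps = 200, seed = 1)
#' reportResults(rep)
#' @export
runTruncationBias <- function(fGrid = c(0.01, 0.02, 0.03, 0.04, 0.05,
                                        0.1, 0.2, 0.3, 0.4, 0.5),
                              size = 100L, tau = 0.05, nReps = 1000L,
                              seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  size <- .asCount(size, "size")
  tau <- .asProb(tau, "tau", open_lo = TRUE, open_hi = TRUE)
  nReps <- .asCount(nReps, "nReps")
  if (any(fGrid <= 0) || any(fGrid >= 1))
    stop("'fGrid' values must lie in (0, 1)", call. = FALSE)
  cut <- .passCut(size, tau)
  seeds <- .deriveSeeds(seed, length(fGrid))
  rows <- lapply(seq_along(fGrid), function(i) {
    f <- fGrid[i]
    xs <- sampleTruncated(TruncationSpec(size, 0L), f, nReps, seeds[i])
    kept <- xs[xs >= cut]
    data.frame(f = f, mean_untruncated = mean(xs / size),
               mean_truncated = if (length(kept)) mean(kept / size)
                                else NA_real_,
               n_retained = length(kept))
  })
  res <- do.call(rbind, rows)
  .report("truncation_bias",
          list(fGrid = fGrid, size = size, tau = tau, cut = cut,
               nReps = nReps, seed = seed, subSeeds = seeds),
          res,
          list(max_abs_bias_truncated =
                 max(abs(res$mean_truncated - res$f), na.rm = TRUE),
               max_abs_bias_untruncated = max(abs(res$mean_untruncated -
                                                    res$f))),
          t0)
}

#' Threshold crossing counts under frequency-estimate noise
#'
#' Simulates `nReps` cohorts of `S` subclonal sites with frequencies from
#' the spectrum and counts, per replicate, the sites whose observed
#' proportion crosses the threshold upwards (true `f` below `tau`, observed
#' at or above) and downwards (true `f` at or above `tau`, observed below).
#' When the spectrum has a steep negative slope at `tau`, up-crossers far
#' outnumber down-crossers and the threshold count over-estimates the truth.
#'
#' @param spectrum Subclonal [BetaSpectrum-class]; default the steep
#'   `(0.1, 100)` spectrum.
#' @param S Sites per replicate, default 200.
#' @param depth Uniform sequencing depth, default 100.
#' @param tau Frequency threshold, default 0.05.
#' @param nReps Replicates, default 100.
#' @param seed Master seed.
#' @param keepRaw Keep the per-replicate site tables in the summary (for
#'   independent recounts)?
#' @return An [ExperimentReport-class]; results columns `rep`,
#'   `up_crossers`, `down_crossers`, `n_above_observed`, `n_above_true`.
#' @export
runThresholdCrossing <- function(spectrum = BetaSpectrum(0.1, 100),
                                 S = 200L, depth = 100L, tau = 0.05,
                                 nReps = 100L, seed = 1L, keepRaw = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  S <- .asCount(S, "S"); depth <- .asCount(depth, "depth")
  tau <- .asProb(tau, "tau", open_lo = TRUE, open_hi = TRUE)
  nReps <- .asCount(nReps, "nReps")
  cut <- .passCut(depth, tau)
  seeds <- .deriveSeeds(seed, nReps)
  raw <- if (keepRaw) vector("list", nReps) else NULL
  rows <- lapply(seq_len(nReps), function(r) {
    .withSeed(seeds[r], {
      f <- stats::rbeta(S, spectrum@alpha, spectrum@beta)
      xx <- stats::rbinom(S, depth, f)
      obsPass <- xx >= cut
      truePass <- f >= tau
      if (keepRaw)
        raw[[r]] <<- data.frame(true_vaf = f, alt_count = xx, depth = depth)
      data.frame(rep = r, up_crossers = sum(obsPass & !truePass),
                 down_crossers = sum(!obsPass & truePass),
                 n_above_observed = sum(obsPass),
                 n_above_true = sum(truePass))
    })
  })
  res <- do.call(rbind, rows)
  smry <- list(mean_up = mean(res$up_crossers),
               mean_down = mean(res$down_crossers),
               up_down_ratio = mean(res$up_crossers) /
                 max(mean(res$down_crossers), .Machine$double.eps),
               expected_above_theory =
                 expectedObservedCount(rep(depth, S), tau, spectrum),
               true_above_theory =
                 trueCountAboveThreshold(S, tau, spectrum))
  if (keepRaw) smry$raw <- raw
  .report("threshold_crossing",
          list(alpha = spectrum@alpha, beta = spectrum@beta, S = S,
               depth = depth, tau = tau, cut = cut, nReps = nReps,
               seed = seed, subSeeds = seeds),
          res, smry, t0)
}

#' Down-sampling consistency of threshold TMB
#'
#' Thins every cohort sample's reads to `fraction` and compares the
#' threshold TMB before and after, pairing by sample, with a sign test on
#' the paired differences. With abundant subclonal mutations near the
#' detection/frequency threshold, halving the depth systematically lowers
#' the estimate; clonal-dominated deep samples barely move.
#'
#' @param cohort List of [TumourSample-class] (e.g. from
#'   [simulateCohort()]).
#' @param fraction Read retention fraction, default 0.5.
#' @param tau Frequency threshold, default 0.05.
#' @param minAltReads Detection cut, default 3.
#' @param seed Master seed for the thinning.
#' @return An [ExperimentReport-class]; results columns `sample`,
#'   `clonal_fraction`, `mean_depth`, `tmb_full`, `tmb_downsampled`.
#' @export
runDownsampling <- function(cohort, fraction = 0.5, tau = 0.05,
                            minAltReads = 3L, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.list(cohort) || length(cohort) < 2L ||
      !all(vapply(cohort, is, TRUE, class2 = "TumourSample")))
    stop("'cohort' must be a list of >= 2 TumourSample objects",
         call. = FALSE)
  seeds <- .deriveSeeds(seed, length(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    smp <- cohort[[i]]
    down <- downsampleSample(smp, fraction, seeds[i])
    data.frame(sample = i, clonal_fraction = smp@clonalFraction,
               mean_depth = mean(smp@sites$depth),
               tmb_full = tmbValue(estimateTmbThreshold(smp, tau,
                                                        minAltReads)),
               tmb_downsampled = tmbValue(estimateTmbThreshold(down, tau,
                                                               minAltReads)))
  })
  res <- do.call(rbind, rows)
  diffs <- res$tmb_downsampled - res$tmb_full
  nLower <- sum(diffs < 0)
  nChanged <- sum(diffs != 0)
  signP <- if (nChanged > 0)
    stats::binom.test(sum(diffs[diffs != 0] < 0), nChanged)$p.value
  else NA_real_
  .report("downsampling",
          list(fraction = fraction, tau = tau, minAltReads = minAltReads,
               seed = seed, subSeeds = seeds, nSamples = length(cohort)),
          res,
          list(n_lower = nLower, n_pairs = length(diffs),
               median_rel_change = stats::median(
                 abs(diffs) / pmax(res$tmb_full, .Machine$double.eps)),
               sign_test_p = signP),
          t0)
}

#' Depth-TMB correlation, stratified by clonal fraction
#'
#' Splits the cohort at clonal fraction 0.5 and, within each stratum,
#' computes the Spearman correlation between per-sample mean site depth and
#' threshold TMB, with a seeded permutation p-value. Subclonal-heavy
#' (heterogeneous) strata show a positive depth-TMB correlation; strata
#' dominated by clonal mutations — which sit far above the threshold at any
#' realistic depth — do not.
#'
#' @param cohort List of [TumourSample-class].
#' @param tau Frequency threshold, default 0.05.
#' @param minAltReads Detection cut, default 3.
#' @param nPermutations Permutations for the p-value, default 10000.
#' @param seed Seed for the permutations.
#' @return An [ExperimentReport-class]; results has one row per sample
#'   (`sample`, `stratum`, `clonal_fraction`, `mean_depth`, `tmb`); the
#'   summary holds per-stratum `rho` and permutation `p` (`NA` when TMB is
#'   constant within a stratum).
#' @export
runDepthCorrelation <- function(cohort, tau = 0.05, minAltReads = 3L,
                                nPermutations = 10000L, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.list(cohort) ||
      !all(vapply(cohort, is, TRUE, class2 = "TumourSample")))
    stop("'cohort' must be a list of TumourSample objects", call. = FALSE)
  nPermutations <- .asCount(nPermutations, "nPermutations")
  rows <- lapply(seq_along(cohort), function(i) {
    smp <- cohort[[i]]
    data.frame(sample = i, clonal_fraction = smp@clonalFraction,
               stratum = if (smp@clonalFraction > 0.5) "clonal_high"
                         else "clonal_low",
               mean_depth = mean(smp@sites$depth),
               tmb = tmbValue(estimateTmbThreshold(smp, tau, minAltReads)))
  })
  res <- do.call(rbind, rows)
  strata <- c("clonal_low", "clonal_high")
  seeds <- .deriveSeeds(seed, length(strata))
  smry <- list()
  for (k in seq_along(strata)) {
    st <- strata[k]
    sub <- res[res$stratum == st, , drop = FALSE]
    if (nrow(sub) < 30L) {
      smry[[paste0("rho_", st)]] <- NA_real_
      smry[[paste0("p_", st)]] <- NA_real_
      smry[[paste0("n_", st)]] <- nrow(sub)
      next
    }
    pt <- spearmanPermTest(sub$mean_depth, sub$tmb, nPermutations, seeds[k])
    smry[[paste0("rho_", st)]] <- pt$rho
    smry[[paste0("p_", st)]] <- pt$p
    smry[[paste0("n_", st)]] <- nrow(sub)
  }
  .report("depth_correlation",
          list(tau = tau, minAltReads = minAltReads,
               nPermutations = nPermutations, seed = seed,
               subSeeds = seeds, nSamples = length(cohort)),
          res, smry, t0)
}

#' Spearman correlation with a seeded permutation p-value
#'
#' Two-sided permutation test for Spearman's rank correlation: the depth
#' labels are permuted `nPermutations` times and the p-value is the
#' add-one-smoothed fraction of permuted `|rho|` values at or above the
#' observed one. Returns `rho = NA` when either variable is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @param nPermutations Number of permutations.
#' @param seed Integer seed.
#' @return List with elements `rho` and `p`.
#' @export
spearmanPermTest <- function(x, y, nPermutations = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  nPermutations <- .asCount(nPermutations, "nPermutations")
  perm <- .withSeed(seed, {
    vapply(seq_len(nPermutations),
           function(i) stats::cor(sample(rx), ry), 0)
  })
  list(rho = rho, p = (1 + sum(abs(perm) >= abs(rho))) / (nPermutations + 1))
}
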