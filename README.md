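# tmbias

Bias and depth inconsistency in tumour mutation burden estimation.

## What this package is for

Tumour mutation burden (TMB) — somatic mutations per megabase of sequenced
region — is used clinically to select patients for immune checkpoint
inhibitors. The standard estimator counts mutations whose observed variant
allele frequency (VAF) reaches a threshold τ (typically 0.05) and divides
by the target size. `tmbias` gives statisticians and bioinformaticians a
tested, reproducible implementation of why that estimator misbehaves, and
of a model-based alternative:

1. **Truncation bias.** A site is only analysed when mutant reads are seen,
   so the mutant read count is a truncated binomial. The observed
   proportion from a zero-truncated binomial has expectation
   `f / (1 − (1 − f)^N) > f`, and τN-truncation (only counting sites with
   observed proportion ≥ τ) inflates it far more. The package provides the
   truncated distributions, exact samplers, and Fisher's maximum-likelihood
   estimator of `f` that removes the bias.

2. **Threshold-crossing bias.** For `S` subclonal mutations with a
   Beta(α, β) VAF spectrum, the true above-threshold count is
   `T = (1 − F_B(τ; α, β)) · S`, while the expected *observed* count at
   depths `d_i` is `E = Σ_i (1 − F_BB(⌈d_i τ⌉ − 1; d_i, α, β))` (F_BB the
   beta-binomial CDF). The relative error `(E − T)/T` is large and
   depth-dependent when the spectrum is steep at τ — so threshold TMB is
   both biased and inconsistent across sequencing depths.

3. **A synthetic tumour simulator** (clonal + beta-subclonal VAFs, purity
   scaling, per-site depth models, exact read-level down-sampling by
   binomial thinning) and **two TMB estimators**: threshold counting and a
   full-spectrum estimator that fits a truncated beta-binomial likelihood
   to all detected sites, recovers the total mutation abundance by
   inverse-probability weighting, and evaluates the spectrum tail above τ.

4. **Experiment drivers** (`runTruncationBias`, `runThresholdCrossing`,
   `runDownsampling`, `runDepthCorrelation`) reproducing the bias,
   down-sampling and depth-correlation analyses on synthetic cohorts, each
   returning a seeded, bit-reproducible report.

## Worked example

A subclonal-heavy tumour: 50 clonal + 5,000 subclonal mutations with a
steep Beta(0.1, 100) spectrum, sequenced at depth 100 over 1 Mb.

```r
library(tmbias)
sp <- BetaSpectrum(0.1, 100)
relativeErrorCurve(sp, tau = 0.05, depthGrid = c(50, 100, 1000, 10000), S = 200)
#>   depth  trueCount expectedCount relativeError
#> 1    50 0.02546112    0.35883636   13.09350509
#> 2   100 0.02546112    0.24010174    8.43013446
#> 3  1000 0.02546112    0.03561242    0.39869835
#> 4 10000 0.02546112    0.02637988    0.03608502
```

At depth 100, nine times more subclonal mutations are counted above the
threshold than truly sit above it, and the bias persists to depth 1,000.
On a full sample:

```r
s <- simulateSample(SimulationConfig(
  nClonal = 50, nSubclonal = 5000, spectrum = sp,
  depthModel = depthModelFixed(100), regionSizeMb = 1, seed = 5001))

estimateTmbThreshold(s, tau = 0.05, minAltReads = 3)
#> TmbResult (threshold): TMB = 60 mutations/Mb
#>   detected 92 sites; 60 pass tau = 0.05; region 1 Mb

fit <- fitSpectrumML(s, minAltReads = 3)
estimateTmbModel(fit, tau = 0.05, regionSizeMb = 1,
                 nClonalObserved = countObservedClonal(s))
#> TmbResult (model): TMB = 51.58 mutations/Mb
#>   detected 92 sites; model-derived count pass tau = 0.05; region 1 Mb

50 + trueCountAboveThreshold(5000, 0.05, sp)   # the truth
#> [1] 50.63653
```

The threshold count (60/Mb) over-states the true TMB (50.6/Mb) by ~19%;
the spectrum-model estimate (51.6/Mb) lands within 2%. The methods
vignette (`vignettes/tmb-estimation-bias.Rmd`) documents the model, the
pass-rule conventions, the choice of default spectra, and the
identifiability limits of the spectrum fit.

## Command line

A thin wrapper over the same functions lives in
`inst/scripts/tmbias-cli.R`:

```sh
Rscript inst/scripts/tmbias-cli.R simulate --config config.json --out sample.tsv [--vcf sample.vcf]
Rscript inst/scripts/tmbias-cli.R tmb --in sample.tsv --method both --out result.json
Rscript inst/scripts/tmbias-cli.R bias-curve --alpha 0.1 --beta 100 --depths 50,100,1000 --S 200 --out curve.tsv
Rscript inst/scripts/tmbias-cli.R experiment downsampling --config config.json --out outdir/
```

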