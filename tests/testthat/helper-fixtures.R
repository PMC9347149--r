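# Shared fixture builders: small hand-constructed samples with known counts.

makeSiteSample <- function(alt, depth, isClonal = rep(FALSE, length(alt)),
                           trueVaf = alt / pmax(depth, 1L), purity = 1,
                           regionSizeMb = 1, seed = 0L) {
  stopifnot(length(alt) == length(depth))
  sitesDf <- data.frame(
    site_id = sprintf("s%03d", seq_along(alt)),
    true_vaf = trueVaf,
    depth = as.integer(depth),
    alt_count = as.integer(alt),
    is_clonal = isClonal,
    obs_vaf = ifelse(depth > 0, alt / depth, NA_real_),
    stringsAsFactors = FALSE)
  new("TumourSample", sites = sitesDf, purity = purity,
      clonalFraction = mean(isClonal), regionSizeMb = regionSizeMb,
      seed = as.integer(seed), config = list())
}

# standard-error of the mean of draws
seMean <- function(x) stats::sd(x) / sqrt(length(x))
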