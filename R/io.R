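#' Read and write tumour samples as TSV
#'
#' The TSV dialect is one row per site with columns
#' `site_id`/`true_vaf`/`depth`/`alt_count`/`is_clonal`/`obs_vaf`, preceded
#' by `##`-prefixed header lines carrying the sample-level metadata
#' (`purity`, `clonal_fraction`, `region_size_mb`, `seed`, and the
#' configuration echo in deparsed form). Numeric values are written with 17
#' significant digits, so `readSampleTsv(writeSampleTsv(x))` reproduces
#' every field bit-exactly.
#'
#' @param sample A [TumourSample-class].
#' @param path File path.
#' @return `writeSampleTsv()` returns `path` invisibly; `readSampleTsv()`
#'   returns a [TumourSample-class].
#' @name sampleTsv
NULL

.num17 <- function(x) sprintf("%.17g", x)

#' @rdname sampleTsv
#' @export
writeSampleTsv <- function(sample, path) {
  stopifnot(is(sample, "TumourSample"))
  validObject(sample)
  s <- sample@sites
  cfg <- paste(deparse(sample@config,
                       control = c("keepNA", "keepInteger", "niceNames",
                                   "showAttributes", "digits17")),
               collapse = " ")
  hdr <- c(
    paste0("## purity=", .num17(sample@purity)),
    paste0("## clonal_fraction=", .num17(sample@clonalFraction)),
    paste0("## region_size_mb=", .num17(sample@regionSizeMb)),
    paste0("## seed=", sample@seed),
    paste0("## config=", cfg),
    paste(c("site_id", "true_vaf", "depth", "alt_count", "is_clonal",
            "obs_vaf"), collapse = "\t"))
  body <- paste(s$site_id, .num17(s$true_vaf), s$depth, s$alt_count,
                ifelse(s$is_clonal, "TRUE", "FALSE"),
                ifelse(is.na(s$obs_vaf), "NA", .num17(s$obs_vaf)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.metaValue <- function(lines, key, path) {
  pat <- paste0("^## ", key, "=")
  hit <- grep(pat, lines)
  if (length(hit) != 1L)
    stop("missing or duplicated metadata line '", key, "' in ", path,
         call. = FALSE)
  sub(pat, "", lines[hit])
}

#' @rdname sampleTsv
#' @export
readSampleTsv <- function(path) {
  lines <- readLines(path)
  meta <- startsWith(lines, "##")
  purity <- as.numeric(.metaValue(lines, "purity", path))
  cf <- as.numeric(.metaValue(lines, "clonal_fraction", path))
  mb <- as.numeric(.metaValue(lines, "region_size_mb", path))
  seed <- as.integer(.metaValue(lines, "seed", path))
  cfg <- tryCatch(eval(parse(text = .metaValue(lines, "config", path))),
                  error = function(e) list())
  body <- lines[!meta]
  if (length(body) < 2L)
    stop("no site rows in ", path, call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("site_id", "true_vaf", "depth", "alt_count", "is_clonal",
            "obs_vaf")
  if (!identical(header, need))
    stop("unexpected column header in ", path, call. = FALSE)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(need))
  if (length(bad))
    stop("malformed row at line ", which(!meta)[bad[1L] + 1L], " of ", path,
         call. = FALSE)
  m <- do.call(rbind, rows)
  depth <- suppressWarnings(as.integer(m[, 3L]))
  alt <- suppressWarnings(as.integer(m[, 4L]))
  tv <- suppressWarnings(as.numeric(m[, 2L]))
  if (anyNA(depth) || anyNA(alt) || anyNA(tv)) {
    bad <- which(is.na(depth) | is.na(alt) | is.na(tv))[1L]
    stop("malformed row at line ", which(!meta)[bad + 1L], " of ", path,
         call. = FALSE)
  }
  sitesDf <- data.frame(
    site_id = m[, 1L], true_vaf = tv, depth = depth, alt_count = alt,
    is_clonal = m[, 5L] == "TRUE",
    obs_vaf = suppressWarnings(as.numeric(m[, 6L])),
    stringsAsFactors = FALSE)
  new("TumourSample", sites = sitesDf, purity = purity, clonalFraction = cf,
      regionSizeMb = mb, seed = seed, config = cfg)
}

#' Write a tumour sample as minimal VCF
#'
#' Writes one VCF v4.2 record per site on a synthetic placeholder contig
#' (`chrS`), with positions assigned deterministically from site order
#' (1000, 2000, ...). Each record carries the simulated truth in INFO key
#' `TRUE_VAF` and the read data in FORMAT fields `AD` (ref,alt) and `DP`.
#' The header documents the dialect; this is a write-only exchange format
#' for the synthetic samples, not a general VCF implementation.
#'
#' @param sample A [TumourSample-class].
#' @param path File path.
#' @param sampleName Sample column name.
#' @return `path`, invisibly.
#' @export
writeSampleVcf <- function(sample, path, sampleName = "TUMOUR") {
  stopifnot(is(sample, "TumourSample"))
  validObject(sample)
  s <- sample@sites
  pos <- seq_len(nrow(s)) * 1000L
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tmbias synthetic tumour sample (simulated data)",
    paste0("##contig=<ID=chrS,length=", max(pos) + 1000L, ">"),
    "##INFO=<ID=TRUE_VAF,Number=1,Type=Float,Description=\"Simulated true (purity-scaled) mutant allele frequency\">",
    "##INFO=<ID=CLONAL,Number=0,Type=Flag,Description=\"Site simulated as clonal\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleName), collapse = "\t"))
  info <- paste0("TRUE_VAF=", .num17(s$true_vaf),
                 ifelse(s$is_clonal, ";CLONAL", ""))
  gt <- paste0(s$depth - s$alt_count, ",", s$alt_count, ":", s$depth)
  body <- paste("chrS", pos, s$site_id, "A", "T", ".", "PASS", info,
                "AD:DP", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
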