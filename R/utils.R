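# Internal helpers: argument coercion, seeded evaluation, pass-count rule.

.asCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) ||
      abs(x - round(x)) > 1e-8)
    stop("'", name, "' must be a single integer", call. = FALSE)
  as.integer(round(x))
}

.asProb <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                    open_hi = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop("'", name, "' must be a single number", call. = FALSE)
  bad <- x < lo || x > hi || (open_lo && x <= lo) || (open_hi && x >= hi)
  if (bad)
    stop("'", name, "' must be in ", if (open_lo) "(" else "[", lo, ", ", hi,
         if (open_hi) ")" else "]", call. = FALSE)
  as.numeric(x)
}

# Evaluate expr with a local, restored RNG state. All stochastic operations
# in the package route through this so no global RNG state is consumed.
.withSeed <- function(seed, expr) {
  seed <- .asCount(seed, "seed")
  withr::with_seed(seed, expr)
}

# Derive per-unit sub-seeds from a master seed, each below 2^31.
.deriveSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Minimum alt read count for a site at depth d to have observed proportion
# at or above tau; the ceiling convention used identically in the theory,
# the simulator and the pipeline. The 1e-9 guard protects exact ties
# (e.g. d * tau = 5) against floating-point round-up.
.passCut <- function(depth, tau, minAltReads = 0L) {
  pmax(as.integer(minAltReads), as.integer(ceiling(depth * tau - 1e-9)))
}
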