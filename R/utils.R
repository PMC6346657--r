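## Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed
#'
#' All randomness in multi-replicate drivers flows from one user-supplied
#' seed; replicate `k` of stratum `s` uses a deterministic derived stream so
#' that replicates are independent of execution order. Kept below 2^31 - 1.
#'
#' @param seed base integer seed
#' @param stratum integer stratum index (e.g. parameter set)
#' @param replicate integer replicate index
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stratum = 0L, replicate = 0L) {
  ## 64-bit-safe mixing in double precision (exact below 2^53)
  x <- (as.numeric(seed) * 48271 + as.numeric(stratum) * 16807 +
          as.numeric(replicate) * 69621 + 12345) %% 2147483629
  as.integer(x)
}

## Truncated ("windowed") exponential distribution: Exp(mean) restricted to
## [lower, upper] and renormalized. Used for both Theta and M priors.

dtruncexp <- function(x, mean, lower, upper, log = FALSE) {
  r <- 1 / mean
  z <- exp(-r * lower) - exp(-r * upper)
  ld <- log(r) - r * x - log(z)
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

ptruncexp <- function(q, mean, lower, upper) {
  r <- 1 / mean
  z <- exp(-r * lower) - exp(-r * upper)
  p <- (exp(-r * lower) - exp(-r * pmin(pmax(q, lower), upper))) / z
  pmin(pmax(p, 0), 1)
}

qtruncexp <- function(p, mean, lower, upper) {
  r <- 1 / mean
  z <- exp(-r * lower) - exp(-r * upper)
  -log(exp(-r * lower) - p * z) / r
}

rtruncexp <- function(n, mean, lower, upper) {
  qtruncexp(stats::runif(n), mean, lower, upper)
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]
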