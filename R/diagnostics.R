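## Convergence diagnostics: effective sample size via Geyer's initial
## positive sequence, and the Gelman-Rubin potential scale reduction
## factor across replicate runs.

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time estimate using the initial positive sequence
#' truncation: sums of adjacent autocovariance pairs are accumulated while
#' they stay positive. A constant trace has ESS equal to its length.
#'
#' @param trace numeric vector (length >= 10)
#' @return estimated effective sample size
#' @export
ess <- function(trace) {
  n <- length(trace)
  stopifnot(n >= 10L)
  v <- stats::var(trace)
  if (v == 0) return(n)
  ac <- stats::acf(trace, lag.max = n - 1L, plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  ## Gamma_m = rho_{2m} + rho_{2m+1}; truncate at the first negative pair
  tau <- 1
  m <- 0L
  repeat {
    i1 <- 2L * m + 2L  # rho index (1-based: ac[1] = rho_0)
    i2 <- 2L * m + 3L
    if (i2 > length(ac)) break
    gam <- ac[i1] + ac[i2]
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1L
  }
  max(1, n / tau)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF across two or more replicate traces of the same quantity; values
#' near 1 indicate agreement between runs. Constant traces give 1.
#'
#' @param traces list of >= 2 numeric vectors of equal length
#' @return the potential scale reduction factor
#' @export
psrf <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2L)
  n <- unique(lengths(traces))
  stopifnot(length(n) == 1L, n >= 10L)
  m <- length(traces)
  means <- vapply(traces, mean, 0)
  vars <- vapply(traces, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)  # = B/n in the usual notation
  if (W == 0) return(1)
  V <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
  sqrt(V / W)
}
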