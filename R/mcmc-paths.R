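## Migration-path machinery: endpoint-conditioned continuous-time Markov
## chain simulation by uniformization, plus exact path densities. Paths are
## 3-column matrices (time, from, to) of backward migration events along a
## branch, ordered by increasing time.

## matrix exponential for small dense matrices (scaling and squaring with a
## Taylor series; K <= ~12 here, so this is both fast and accurate)
mat_exp <- function(A) {
  K <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(K)
  term <- diag(K)
  for (n in 1:30) {
    term <- term %*% As / n
    E <- E + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

## generator of the migration CTMC from the K x K rate matrix
mig_generator <- function(Mmat) {
  L <- Mmat
  diag(L) <- 0
  diag(L) <- -rowSums(L)
  L
}

## log-density of a migration path (skeleton) on [t0, t1] starting in deme
## `a`; if `b` is given the density is conditioned on ending in `b`
## (divided by the transition probability P_ab). Returns -Inf for paths
## inconsistent with the rates or endpoints.
path_logdens <- function(path, a, b = NULL, t0, t1, Mmat, P = NULL) {
  q_out <- rowSums(Mmat)
  ld <- 0
  t <- t0
  d <- a
  if (nrow(path)) {
    for (r in seq_len(nrow(path))) {
      if (path[r, 2L] != d) return(-Inf)
      rate <- Mmat[d, path[r, 3L]]
      if (rate <= 0) return(-Inf)
      ld <- ld - q_out[d] * (path[r, 1L] - t) + log(rate)
      t <- path[r, 1L]
      d <- path[r, 3L]
    }
  }
  ld <- ld - q_out[d] * (t1 - t)
  if (!is.null(b)) {
    if (d != b) return(-Inf)
    if (is.null(P)) P <- mat_exp(mig_generator(Mmat) * (t1 - t0))
    if (P[a, b] <= 0) return(-Inf)
    ld <- ld - log(P[a, b])
  }
  ld
}

## Sample an unconditioned migration path from deme `a` over [t0, t1]
## (plain Gillespie). Returns list(path, end).
sample_free_path <- function(a, t0, t1, Mmat, max_events = 500L) {
  q_out <- rowSums(Mmat)
  t <- t0
  d <- a
  path <- no_events
  repeat {
    if (q_out[d] <= 0) break
    t <- t + stats::rexp(1L, q_out[d])
    if (t >= t1) break
    if (nrow(path) >= max_events) return(NULL)
    j <- sample.int(ncol(Mmat), 1L, prob = Mmat[d, ])
    path <- rbind(path, c(t, d, j))
    d <- j
  }
  list(path = path, end = d)
}

## Sample an endpoint-conditioned migration path (deme `a` at t0, deme `b`
## at t1) by uniformization: draw the number of uniformized jumps from its
## conditional distribution, the embedded-chain states by backward
## filtering, attach sorted uniform times, and drop virtual (self) jumps.
## Returns NULL when the event cap is exceeded (the caller rejects).
sample_cond_path <- function(a, b, t0, t1, Mmat, max_events = 500L,
                             P = NULL) {
  tau <- t1 - t0
  K <- nrow(Mmat)
  q_out <- rowSums(Mmat)
  mu <- max(q_out)
  if (mu <= 0 || tau <= 0) {
    if (a != b) return(NULL)
    return(no_events)
  }
  L <- mig_generator(Mmat)
  R <- diag(K) + L / mu
  if (is.null(P)) P <- mat_exp(L * tau)
  Pab <- P[a, b]
  if (Pab <= 0) return(NULL)

  ## conditional number of uniformized jumps:
  ## P(N = n) = e^{-mu tau} (mu tau)^n / n! * [R^n]_ab / Pab
  mt <- mu * tau
  n_max <- min(2000L, ceiling(mt + 12 * sqrt(mt + 1) + 30))
  Rpow <- vector("list", n_max + 1L)
  Rpow[[1L]] <- diag(K)
  u <- stats::runif(1L)
  acc <- 0
  N <- NA_integer_
  lpois <- -mt - log(Pab)
  for (n in 0:n_max) {
    if (n > 0) {
      Rpow[[n + 1L]] <- Rpow[[n]] %*% R
      lpois <- lpois + log(mt) - log(n)
    }
    pn <- exp(lpois) * Rpow[[n + 1L]][a, b]
    acc <- acc + pn
    if (acc >= u) { N <- n; break }
  }
  if (is.na(N)) return(NULL)
  if (N == 0L) return(if (a == b) no_events else NULL)

  ## embedded chain states conditioned on endpoints
  states <- integer(N + 1L)
  states[1L] <- a
  for (i in seq_len(N)) {
    back <- Rpow[[N - i + 1L]][, b]
    w <- R[states[i], ] * back
    if (sum(w) <= 0) return(NULL)
    states[i + 1L] <- sample.int(K, 1L, prob = w)
  }
  if (states[N + 1L] != b) return(NULL)

  times <- t0 + sort(stats::runif(N)) * tau
  keep <- states[-(N + 1L)] != states[-1L]
  if (sum(keep) > max_events) return(NULL)
  if (!any(keep)) return(no_events)
  cbind(time = times[keep], from = states[which(keep)],
        to = states[which(keep) + 1L])
}
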