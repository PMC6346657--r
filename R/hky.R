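## HKY85 substitution model.
##
## Bases are ordered A, C, G, T throughout the package. Transitions are
## A<->G and C<->T. `tstv_ratio` is interpreted as kappa, the
## transition/transversion *rate* parameter of the HKY generator (the
## instantaneous-rate convention used by most likelihood software). Under
## equal base frequencies the expected ratio of observed transitions to
## transversions at short times is kappa/2, so kappa = 9 corresponds to an
## observed ts:tv ratio of 4.5:1; the conversion for general frequencies is
## kappa * (pi_A*pi_G + pi_C*pi_T) / (pi_A+pi_G)(pi_C+pi_T).

DNA_BASES <- c("A", "C", "G", "T")

#' HKY85 rate matrix
#'
#' Builds the HKY85 generator with transition/transversion rate parameter
#' `kappa`, normalized so that the expected substitution rate at equilibrium
#' is 1 (branch lengths are then in expected substitutions per site).
#'
#' @param tstv_ratio kappa, the transition/transversion rate parameter (> 0)
#' @param base_freqs length-4 vector of equilibrium frequencies (A, C, G, T)
#'   summing to 1
#' @return a 4x4 rate matrix with rows summing to 0
#' @export
hky_rate_matrix <- function(tstv_ratio, base_freqs = rep(0.25, 4)) {
  stopifnot(tstv_ratio > 0, length(base_freqs) == 4,
            abs(sum(base_freqs) - 1) < 1e-12, all(base_freqs > 0))
  pi <- base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (i + j) == 4 || (i + j) == 6 && abs(i - j) == 2
    ## A(1)<->G(3): i+j==4; C(2)<->T(4): i+j==6 with |i-j|==2
    Q[i, j] <- if (transition) tstv_ratio * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # mean rate at equilibrium
  Q / mu
}

## Eigendecomposition of the (reversible) HKY generator via the symmetrized
## matrix B = D^{1/2} Q D^{-1/2}; cached by the caller. Returns the pieces
## needed to form P(t) = U diag(exp(lambda t)) Uinv.
hky_eigen <- function(tstv_ratio, base_freqs = rep(0.25, 4)) {
  Q <- hky_rate_matrix(tstv_ratio, base_freqs)
  d <- sqrt(base_freqs)
  B <- (Q * rep(d, times = 4)) * rep(1 / d, each = 4)   # diag(d) Q diag(1/d)
  B <- (B + t(B)) / 2                                    # symmetrize roundoff
  es <- eigen(B, symmetric = TRUE)
  U <- es$vectors / d       # diag(1/d) %*% V
  Uinv <- t(es$vectors * d) # t(V) %*% diag(d)
  list(U = U, Uinv = Uinv, values = es$values, pi = base_freqs, Q = Q)
}

#' HKY85 transition probability matrix
#'
#' Computes P(t) = exp(Qt) for the normalized HKY generator; `t` is in
#' expected substitutions per site.
#'
#' @inheritParams hky_rate_matrix
#' @param t branch length (>= 0), expected substitutions per site
#' @param eig optional precomputed [hky_eigen()] decomposition (for speed in
#'   inner loops)
#' @return a 4x4 stochastic matrix (rows sum to 1), bases ordered A,C,G,T
#' @export
hky_transition <- function(tstv_ratio, base_freqs = rep(0.25, 4), t, eig = NULL) {
  stopifnot(t >= 0)
  if (is.null(eig)) eig <- hky_eigen(tstv_ratio, base_freqs)
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}
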