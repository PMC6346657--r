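## GenealogyState: the state of the structured-coalescent sampler.
##
## A time-calibrated rooted binary genealogy in mutational units
## (generations x mu), with an ordered list of migration events on each
## branch and the current parameter vector. Node ids: tips 1..n, internal
## n+1..2n-1 (the root is the internal node without a parent). For node v,
## `events[[v]]` is a 3-column matrix (time, from, to) of backward
## migration events on the branch from v up to its parent, ordered by
## increasing time; starting from `node_deme[v]` and applying the events
## must yield `node_deme[parent[v]]` (lineages coalesce only when in the
## same deme).

new_genealogy_state <- function(n_tips, time, parent, node_deme, events,
                                theta, M, model) {
  structure(list(n_tips = n_tips, time = time, parent = parent,
                 node_deme = node_deme, events = events,
                 theta = theta, M = M, model = model),
            class = "genealogy_state")
}

#' @export
print.genealogy_state <- function(x, ...) {
  cat(sprintf(
    "genealogy_state: %d tips, root height %.4g (mutational units), %d migration events\n",
    x$n_tips, max(x$time), sum(vapply(x$events, nrow, 0L))))
  cat(sprintf("  Theta groups: %s\n", paste(signif(x$theta, 3), collapse = " ")))
  if (length(x$M))
    cat(sprintf("  M groups: %s\n", paste(signif(x$M, 3), collapse = " ")))
  invisible(x)
}

## expand tied parameters to per-deme Theta and K x K rate matrix
expand_theta <- function(state) state$theta[state$model$theta_group]

expand_M <- function(state) {
  mg <- state$model$mig_group
  Mmat <- matrix(0, nrow(mg), ncol(mg))
  pos <- mg > 0L
  Mmat[pos] <- state$M[mg[pos]]
  Mmat
}

no_events <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("time", "from", "to")))

#' Simulate a structured-coalescent genealogy state
#'
#' Draws a genealogy with explicit migration events from the structured
#' coalescent in mutational units, given per-group parameters. Used to
#' initialize the sampler and as the forward-simulation oracle in tests.
#'
#' @param tip_deme analysis-deme index (1..K) of each tip
#' @param theta per-Theta-group values
#' @param M per-migration-group values
#' @param model a [model_spec()]
#' @return a `genealogy_state`
#' @export
simulate_state <- function(tip_deme, theta, M, model) {
  K <- model$K
  n_tips <- length(tip_deme)
  n_nodes <- 2L * n_tips - 1L
  theta_deme <- theta[model$theta_group]
  mg <- model$mig_group
  Mmat <- matrix(0, K, K)
  Mmat[mg > 0L] <- M[mg[mg > 0L]]
  mout <- rowSums(Mmat)

  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  node_deme <- integer(n_nodes)
  node_deme[seq_len(n_tips)] <- tip_deme
  events <- rep(list(no_events), n_nodes)
  pending <- rep(list(no_events), n_nodes)

  lin <- seq_len(n_tips)
  lin_deme <- tip_deme
  nxt <- n_tips + 1L
  t <- 0
  while (length(lin) > 1L) {
    k <- tabulate(lin_deme, K)
    coal <- k * (k - 1) / theta_deme
    mig <- k * mout
    R <- sum(coal) + sum(mig)
    if (R <= 0) stop("structured coalescent stuck: zero total rate")
    t <- t + stats::rexp(1L, R)
    ev <- sample.int(2L * K, 1L, prob = c(coal, mig))
    if (ev <= K) {
      i <- ev
      here <- which(lin_deme == i)
      pick <- here[sample.int(length(here), 2L)]
      ids <- lin[pick]
      node <- nxt; nxt <- nxt + 1L
      time[node] <- t; node_deme[node] <- i
      parent[ids] <- node
      events[[ids[1L]]] <- pending[[ids[1L]]]
      events[[ids[2L]]] <- pending[[ids[2L]]]
      lin <- c(lin[-pick], node)
      lin_deme <- c(lin_deme[-pick], i)
    } else {
      i <- ev - K
      pick <- sample1(which(lin_deme == i))
      j <- sample.int(K, 1L, prob = Mmat[i, ])
      id <- lin[pick]
      pending[[id]] <- rbind(pending[[id]], c(t, i, j))
      lin_deme[pick] <- j
    }
  }
  new_genealogy_state(n_tips, time, parent, node_deme, events, theta, M,
                      model)
}

## UPGMA-style initial state: average-linkage clustering on Jukes-Cantor
## corrected pairwise distances gives the start genealogy (times in
## mutational units); node demes are taken from a descendant tip and the
## branch migration paths are drawn endpoint-conditioned under the initial
## rates. Falls back to simulating from the structured coalescent when the
## alignment is uninformative or a path cannot be completed.
init_state_upgma <- function(aln, tip_deme, theta, M, model,
                             max_mig_events = 500L) {
  n <- nrow(aln$seq)
  L <- ncol(aln$seq)
  if (L == 0L || n < 3L)
    return(simulate_state(tip_deme, theta, M, model))
  p <- pairwise_diff_matrix(aln) / L
  p[p > 0.70] <- 0.70  # keep the JC correction finite
  d <- -3 / 4 * log(1 - 4 * p / 3) / 2  # per-lineage time, mutational units
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  node_deme <- integer(n_nodes)
  node_deme[seq_len(n)] <- tip_deme
  ## strictly increasing positive merge heights
  h <- hc$height
  floor_h <- max(max(h, 0) * 1e-4, 1e-7)
  for (k in seq_along(h))
    h[k] <- max(h[k], if (k == 1L) floor_h else h[k - 1L] * (1 + 1e-6),
                floor_h * k)
  id_of <- function(m) if (m < 0L) -m else n + m
  ## internal node demes: rounded median of descendant tip demes, so that
  ## parent-child deme hops stay short on lattice-like connectivity
  tip_sets <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (k in seq_along(h)) {
    a <- id_of(hc$merge[k, 1L]); b <- id_of(hc$merge[k, 2L])
    v <- n + k
    time[v] <- h[k]
    parent[a] <- v; parent[b] <- v
    tip_sets[[v]] <- c(tip_sets[[a]], tip_sets[[b]])
    node_deme[v] <- as.integer(round(stats::median(
      tip_deme[tip_sets[[v]]])))
  }

  K <- model$K
  mg <- model$mig_group
  Mmat <- matrix(0, K, K)
  Mmat[mg > 0L] <- M[mg[mg > 0L]]
  events <- rep(list(no_events), n_nodes)
  if (K > 1L) {
    for (v in seq_len(n_nodes)) {
      p_v <- parent[v]
      if (p_v == 0L) next
      path <- NULL
      ## retry with boosted proposal rates: the initial state only needs a
      ## valid (finite-density) history, not a typical one
      for (boost in c(1, 10, 100, 1000)) {
        path <- sample_cond_path(node_deme[v], node_deme[p_v], time[v],
                                 time[p_v], Mmat * boost, max_mig_events)
        if (!is.null(path)) break
      }
      if (is.null(path))
        return(simulate_state(tip_deme, theta, M, model))
      events[[v]] <- path
    }
  }
  new_genealogy_state(n, time, parent, node_deme, events, theta, M, model)
}

## ---------------------------------------------------------------------------
## density and likelihood wrappers

## flatten the state's history into sorted event vectors for the C++ sweep
state_event_table <- function(state) {
  n_tips <- state$n_tips
  internal <- (n_tips + 1L):(2L * n_tips - 1L)
  mig <- do.call(rbind, state$events)
  ev_time <- c(state$time[internal], mig[, 1L])
  ev_type <- c(rep(1L, length(internal)), rep(2L, nrow(mig)))
  ev_d1 <- c(state$node_deme[internal], as.integer(mig[, 2L]))
  ev_d2 <- c(rep(0L, length(internal)), as.integer(mig[, 3L]))
  o <- order(ev_time)
  list(time = ev_time[o], type = ev_type[o], d1 = ev_d1[o], d2 = ev_d2[o])
}

#' Structured-coalescent log-density of a genealogy state
#'
#' Log-density of the genealogy and its migration history given the state's
#' (Theta, M), in mutational time: within each inter-event interval with
#' k_i lineages in deme i the waiting-time rate is
#' sum_i k_i (k_i - 1)/Theta_i + sum_i k_i sum_j M_ij; each coalescence in
#' deme i contributes a factor 2/Theta_i and each migration from i to j a
#' factor M_ij. Histories violating deme consistency have density -Inf.
#'
#' @param state a `genealogy_state`
#' @return the log-density (may be `-Inf`)
#' @export
structured_coalescent_logdensity <- function(state) {
  k0 <- state$k0 %||%
    tabulate(state$node_deme[seq_len(state$n_tips)], state$model$K)
  state_coal_loglik_cpp(state$time, state$node_deme, state$events,
                        state$n_tips, k0,
                        state$theta_deme %||% expand_theta(state),
                        state$Mmat %||% expand_M(state))
}

## site-pattern compression of an alignment for the pruning kernel
make_mcmc_data <- function(aln, model, tstv_ratio = 9,
                           base_freqs = rep(0.25, 4)) {
  x <- aln$seq
  if (ncol(x) == 0L) {
    pat <- matrix(integer(0), nrow(x), 0)
    w <- numeric(0)
  } else {
    key <- apply(x, 2, paste0, collapse = ",")
    first <- !duplicated(key)
    pat <- x[, first, drop = FALSE] - 1L
    pat[is.na(pat)] <- -1L
    w <- as.numeric(table(key)[key[first]])
  }
  list(tip_pat = pat, weights = w,
       tip_deme = model$deme_map[aln$deme],
       eig = hky_eigen(tstv_ratio, base_freqs),
       n_sites = ncol(x))
}

#' Pruning log-likelihood of an alignment on a genealogy state
#'
#' Felsenstein's pruning algorithm under the HKY model, with per-site
#' independence; migration events do not affect substitution. Exposed
#' mainly for testing; [run_mc3()] uses it internally.
#'
#' @param state a `genealogy_state`
#' @param aln the `labeled_alignment` whose rows match tips `1..n`
#' @param tstv_ratio,base_freqs HKY parameters
#' @return log P(data | genealogy)
#' @export
felsenstein_loglik <- function(state, aln, tstv_ratio = 9,
                               base_freqs = rep(0.25, 4)) {
  data <- make_mcmc_data(aln, state$model, tstv_ratio, base_freqs)
  state_loglik(state, data)
}

state_loglik <- function(state, data) {
  ch <- which(state$parent != 0L)
  par <- state$parent[ch]
  o <- order(state$time[par])
  edge <- cbind(par[o], ch[o])
  len <- state$time[edge[, 1L]] - state$time[edge[, 2L]]
  root <- which(state$parent == 0L)
  prune_loglik_cpp(edge, len, data$tip_pat, data$weights,
                   data$eig$U, data$eig$Uinv, data$eig$values, data$eig$pi,
                   length(state$time), root)
}

## log prior density of the state's parameters
state_logprior <- function(state, priors) {
  lp <- sum(dtruncexp(state$theta, priors$theta$mean, priors$theta$lower,
                      priors$theta$upper, log = TRUE))
  if (length(state$M))
    lp <- lp + sum(dtruncexp(state$M, priors$M$mean, priors$M$lower,
                             priors$M$upper, log = TRUE))
  lp
}

## consistency check used in tests: deme labels piecewise constant and
## consistent along every path, coalescences in matching demes
validate_state <- function(state) {
  n_tips <- state$n_tips
  for (v in seq_along(state$parent)) {
    p <- state$parent[v]
    if (p == 0L) next
    if (state$time[p] <= state$time[v]) return(FALSE)
    ev <- state$events[[v]]
    d <- state$node_deme[v]
    if (nrow(ev)) {
      if (is.unsorted(ev[, 1L])) return(FALSE)
      if (any(ev[, 1L] <= state$time[v]) || any(ev[, 1L] >= state$time[p]))
        return(FALSE)
      for (r in seq_len(nrow(ev))) {
        if (ev[r, 2L] != d) return(FALSE)
        d <- ev[r, 3L]
      }
    }
    if (d != state$node_deme[p]) return(FALSE)
  }
  TRUE
}
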