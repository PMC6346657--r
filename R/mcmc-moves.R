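## Metropolis-Hastings moves on the genealogy state. Every move returns
## list(state, accept); `state$cache` holds (loglik, logcoal, logprior) so
## the power-posterior log target beta*loglik + logcoal + logprior is never
## recomputed needlessly. Moves:
##   time   - slide one internal node's time inside the window left free by
##            adjacent migration events (symmetric; scaled slide at root)
##   spr    - Wilson-Balding subtree prune-regraft with endpoint-conditioned
##            re-simulation of the pruned branch's migration path
##   path   - redraw one branch's migration path conditioned on its
##            endpoint demes
##   deme   - resample one internal node's deme and redraw the three
##            incident branch paths
##   param  - reflected log-scale random walk on one Theta or M group

refresh_cache <- function(state, data, priors) {
  state$theta_deme <- expand_theta(state)
  state$Mmat <- expand_M(state)
  state$k0 <- tabulate(state$node_deme[seq_len(state$n_tips)],
                       state$model$K)
  state$cache <- list(loglik = state_loglik(state, data),
                      logcoal = structured_coalescent_logdensity(state),
                      logprior = state_logprior(state, priors))
  state
}

log_target <- function(cache, beta) {
  beta * cache$loglik + cache$logcoal + cache$logprior
}

## generic accept/reject; `ll_same`/`prior_same` skip unchanged terms
mh_accept <- function(state, prop, data, priors, beta, log_hastings,
                      ll_same = FALSE, prior_same = !ll_same) {
  prop$cache <- list(
    loglik = if (ll_same) state$cache$loglik else state_loglik(prop, data),
    logcoal = structured_coalescent_logdensity(prop),
    logprior = if (prior_same) state$cache$logprior else
      state_logprior(prop, priors))
  lr <- log_target(prop$cache, beta) - log_target(state$cache, beta) +
    log_hastings
  if (!is.nan(lr) && log(stats::runif(1L)) < lr) {
    list(state = prop, accept = TRUE)
  } else list(state = state, accept = FALSE)
}

children_of <- function(state, v) which(state$parent == v)

## descendants of v (including v)
subtree_nodes <- function(state, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    kids <- which(state$parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

## deme on the branch above node x at time t (t within the branch)
deme_at_time <- function(state, x, t) {
  d <- state$node_deme[x]
  ev <- state$events[[x]]
  if (nrow(ev)) for (r in seq_len(nrow(ev))) {
    if (ev[r, 1L] > t) break
    d <- ev[r, 3L]
  }
  d
}

split_path <- function(path, t) {
  if (!nrow(path)) return(list(lower = no_events, upper = no_events))
  below <- path[, 1L] <= t
  list(lower = path[below, , drop = FALSE],
       upper = path[!below, , drop = FALSE])
}

## ---------------------------------------------------------------------------

move_time <- function(state, data, priors, beta, ctl) {
  n <- state$n_tips
  v <- sample1((n + 1L):(2L * n - 1L))
  kids <- children_of(state, v)
  lb <- max(vapply(kids, function(c.)
    if (nrow(state$events[[c.]])) max(state$events[[c.]][, 1L]) else
      state$time[c.], 0))
  p <- state$parent[v]
  log_h <- 0
  if (p == 0L) {  # root: multiplicative slide above lb
    t_new <- lb + (state$time[v] - lb) * exp(stats::runif(1L, -1, 1))
    log_h <- log(t_new - lb) - log(state$time[v] - lb)
  } else {
    ub <- if (nrow(state$events[[v]])) min(state$events[[v]][, 1L]) else
      state$time[p]
    if (ub <= lb) return(list(state = state, accept = FALSE))
    t_new <- stats::runif(1L, lb, ub)
  }
  prop <- state
  prop$time[v] <- t_new
  mh_accept(state, prop, data, priors, beta, log_h)
}

## whole-genealogy scale: multiplies all internal node times and migration
## event times by a common factor (log-uniform proposal); the Jacobian is
## u^(number of scaled time coordinates)
move_scale <- function(state, data, priors, beta, ctl) {
  n <- state$n_tips
  u <- exp(stats::runif(1L, -0.4, 0.4))
  prop <- state
  idx <- (n + 1L):(2L * n - 1L)
  prop$time[idx] <- state$time[idx] * u
  n_ev <- 0L
  for (v in seq_along(state$events)) {
    ev <- state$events[[v]]
    if (nrow(ev)) {
      ev[, 1L] <- ev[, 1L] * u
      prop$events[[v]] <- ev
      n_ev <- n_ev + nrow(ev)
    }
  }
  log_h <- (n - 1L + n_ev) * log(u)
  mh_accept(state, prop, data, priors, beta, log_h)
}

## parameter update: half reflected log-scale random walks, half
## independence redraws from the prior (the latter mix the near-prior
## heated chains across the full window)
move_param <- function(state, data, priors, beta, ctl) {
  nt <- length(state$theta)
  nm <- length(state$M)
  i <- sample.int(nt + nm, 1L)
  pr <- if (i <= nt) priors$theta else priors$M
  x <- if (i <= nt) state$theta[i] else state$M[i - nt]
  if (stats::runif(1L) < 0.5) {
    ## reflected random walk in log space; Hastings = Jacobian x'/x
    win <- log(c(pr$lower, pr$upper))
    y <- log(x) + stats::rnorm(1L, 0, ctl$param_sd)
    width <- win[2L] - win[1L]
    y <- (y - win[1L]) %% (2 * width)
    y <- win[1L] + if (y > width) 2 * width - y else y
    x_new <- exp(y)
    log_h <- log(x_new) - log(x)
  } else {
    ## independence draw from the prior; Hastings cancels the prior ratio
    x_new <- rtruncexp(1L, pr$mean, pr$lower, pr$upper)
    log_h <- dtruncexp(x, pr$mean, pr$lower, pr$upper, log = TRUE) -
      dtruncexp(x_new, pr$mean, pr$lower, pr$upper, log = TRUE)
  }
  prop <- state
  if (i <= nt) {
    prop$theta[i] <- x_new
    prop$theta_deme <- prop$theta[prop$model$theta_group]
  } else {
    prop$M[i - nt] <- x_new
    prop$Mmat <- expand_M(prop)
  }
  mh_accept(state, prop, data, priors, beta, log_h,
            ll_same = TRUE, prior_same = FALSE)
}

move_path <- function(state, data, priors, beta, ctl) {
  root <- which(state$parent == 0L)
  c. <- sample1(setdiff(seq_along(state$parent), root))
  p <- state$parent[c.]
  Mmat <- state$Mmat
  a <- state$node_deme[c.]; b <- state$node_deme[p]
  t0 <- state$time[c.]; t1 <- state$time[p]
  P <- mat_exp(mig_generator(Mmat) * (t1 - t0))
  new_path <- sample_cond_path(a, b, t0, t1, Mmat, ctl$max_mig_events, P)
  if (is.null(new_path)) return(list(state = state, accept = FALSE))
  log_h <- path_logdens(state$events[[c.]], a, b, t0, t1, Mmat, P) -
    path_logdens(new_path, a, b, t0, t1, Mmat, P)
  prop <- state
  prop$events[[c.]] <- new_path
  mh_accept(state, prop, data, priors, beta, log_h, ll_same = TRUE,
            prior_same = TRUE)
}

move_node_deme <- function(state, data, priors, beta, ctl) {
  K <- state$model$K
  if (K < 2L) return(list(state = state, accept = FALSE))
  n <- state$n_tips
  v <- sample1((n + 1L):(2L * n - 1L))
  d_old <- state$node_deme[v]
  d_new <- sample1(setdiff(seq_len(K), d_old))
  Mmat <- state$Mmat
  prop <- state
  prop$node_deme[v] <- d_new
  log_h <- 0
  G <- mig_generator(Mmat)
  for (c. in children_of(state, v)) {
    a <- state$node_deme[c.]
    t0 <- state$time[c.]; t1 <- state$time[v]
    P <- mat_exp(G * (t1 - t0))
    np <- sample_cond_path(a, d_new, t0, t1, Mmat, ctl$max_mig_events, P)
    if (is.null(np)) return(list(state = state, accept = FALSE))
    prop$events[[c.]] <- np
    log_h <- log_h +
      path_logdens(state$events[[c.]], a, d_old, t0, t1, Mmat, P) -
      path_logdens(np, a, d_new, t0, t1, Mmat, P)
  }
  p <- state$parent[v]
  if (p != 0L) {
    b <- state$node_deme[p]
    t0 <- state$time[v]; t1 <- state$time[p]
    P <- mat_exp(G * (t1 - t0))
    np <- sample_cond_path(d_new, b, t0, t1, Mmat, ctl$max_mig_events, P)
    if (is.null(np)) return(list(state = state, accept = FALSE))
    prop$events[[v]] <- np
    log_h <- log_h +
      path_logdens(state$events[[v]], d_old, b, t0, t1, Mmat, P) -
      path_logdens(np, d_new, b, t0, t1, Mmat, P)
  }
  mh_accept(state, prop, data, priors, beta, log_h, ll_same = TRUE,
            prior_same = TRUE)
}

move_spr <- function(state, data, priors, beta, ctl) {
  n <- state$n_tips
  n_nodes <- 2L * n - 1L
  root <- which(state$parent == 0L)
  c. <- sample1(setdiff(seq_len(n_nodes), root))
  v <- state$parent[c.]
  w <- setdiff(children_of(state, v), c.)
  g <- state$parent[v]           # 0 iff v is the root
  Mmat <- state$Mmat
  lambda_root <- 2 / mean(state$theta_deme)
  t_c <- state$time[c.]

  ## ----- detach: remaining tree, with w's branch merged through v
  detached <- subtree_nodes(state, c.)
  remaining <- setdiff(seq_len(n_nodes), c(detached, v))
  r0 <- if (g == 0L) w else root
  prop <- state
  if (g == 0L) {
    prop$parent[w] <- 0L
    prop$events[[w]] <- no_events
  } else {
    prop$parent[w] <- g
    prop$events[[w]] <- rbind(state$events[[w]], state$events[[v]])
  }

  ## ----- reverse-proposal density of the current attachment
  if (g == 0L) {
    lb_rev <- max(t_c, state$time[w])
    log_q_rev <- stats::dexp(state$time[v] - lb_rev, lambda_root, log = TRUE) +
      path_logdens(state$events[[w]], state$node_deme[w], NULL,
                   state$time[w], state$time[v], Mmat)
  } else {
    lb_rev <- max(t_c, state$time[w])
    if (state$time[g] <= lb_rev) return(list(state = state, accept = FALSE))
    log_q_rev <- -log(state$time[g] - lb_rev)
  }
  log_q_rev <- log_q_rev +
    path_logdens(state$events[[c.]], state$node_deme[c.], state$node_deme[v],
                 t_c, state$time[v], Mmat)

  ## ----- choose the new attachment: a finite edge or above the root
  cand <- setdiff(remaining, r0)
  pick <- sample.int(length(cand) + 1L, 1L)
  if (pick <= length(cand)) {
    x <- cand[pick]
    px <- prop$parent[x]
    lo <- max(t_c, prop$time[x]); hi <- prop$time[px]
    if (hi <= lo) return(list(state = state, accept = FALSE))
    t_new <- stats::runif(1L, lo, hi)
    log_q_fwd <- -log(hi - lo)
    d_att <- deme_at_time(prop, x, t_new)
    sp <- split_path(prop$events[[x]], t_new)
    prop$events[[x]] <- sp$lower
    prop$events[[v]] <- sp$upper
    prop$parent[x] <- v
    prop$parent[v] <- px
  } else {  # attach above the current root r0
    lb <- max(t_c, prop$time[r0])
    t_new <- lb + stats::rexp(1L, lambda_root)
    log_q_fwd <- stats::dexp(t_new - lb, lambda_root, log = TRUE)
    fp <- sample_free_path(prop$node_deme[r0], prop$time[r0], t_new, Mmat,
                           ctl$max_mig_events)
    if (is.null(fp)) return(list(state = state, accept = FALSE))
    log_q_fwd <- log_q_fwd +
      path_logdens(fp$path, prop$node_deme[r0], NULL, prop$time[r0], t_new,
                   Mmat)
    d_att <- fp$end
    prop$events[[r0]] <- fp$path
    prop$events[[v]] <- no_events
    prop$parent[r0] <- v
    prop$parent[v] <- 0L
  }
  prop$time[v] <- t_new
  prop$node_deme[v] <- d_att
  prop$parent[c.] <- v

  ## ----- new migration path on the pruned branch
  P <- mat_exp(mig_generator(Mmat) * (t_new - t_c))
  np <- sample_cond_path(state$node_deme[c.], d_att, t_c, t_new, Mmat,
                         ctl$max_mig_events, P)
  if (is.null(np)) return(list(state = state, accept = FALSE))
  prop$events[[c.]] <- np
  log_q_fwd <- log_q_fwd +
    path_logdens(np, state$node_deme[c.], d_att, t_c, t_new, Mmat, P)

  mh_accept(state, prop, data, priors, beta, log_q_rev - log_q_fwd)
}

## one sweep: pick a move type by weight and apply it
#' One Metropolis-Hastings sweep of the structured-coalescent sampler
#'
#' Applies one randomly chosen move (genealogy topology, node times,
#' migration paths, node demes, or parameters) targeting the power
#' posterior `L(data|G)^beta p(G|Theta,M) p(Theta) p(M)`.
#'
#' @param state a `genealogy_state` with a populated cache (see
#'   [run_mc3()]); fresh states are refreshed automatically
#' @param data internal pattern data from the alignment (built by
#'   [run_mc3()]); or a `labeled_alignment`
#' @param priors a [coal_priors()]
#' @param beta inverse temperature in `[0, 1]` (power-posterior exponent on
#'   the data likelihood)
#' @param ctl move control list; see [mcmc_config()]
#' @return list(state, accept, type)
#' @export
mcmc_step <- function(state, data, priors, beta, ctl = NULL) {
  if (inherits(data, "labeled_alignment"))
    data <- make_mcmc_data(data, state$model)
  ctl <- ctl %||% mcmc_config()
  if (is.null(state$cache)) state <- refresh_cache(state, data, priors)
  w <- ctl$move_weights
  if (state$model$K < 2L) w[c("paths", "deme")] <- 0
  type <- sample(names(w), 1L, prob = w)
  res <- switch(type,
    times = move_time(state, data, priors, beta, ctl),
    scale = move_scale(state, data, priors, beta, ctl),
    topology = move_spr(state, data, priors, beta, ctl),
    paths = move_path(state, data, priors, beta, ctl),
    deme = move_node_deme(state, data, priors, beta, ctl),
    params = move_param(state, data, priors, beta, ctl))
  res$type <- type
  res
}
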