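## Metropolis-coupled MCMC driver and path-sampling marginal likelihood.

#' MCMC configuration
#'
#' Chain schedule and proposal controls for [run_mc3()]. The default
#' temperature ladder is 1, 1.5, 3, 1e5; heating maps temperature T to the
#' power-posterior exponent beta = 1/T, so the hottest chain samples
#' essentially from the prior and the ladder doubles as the quadrature grid
#' for path sampling. Desk-scale defaults (2e5 steps, 5e4 burn-in) keep a
#' single model run tractable on one core; `paper_scale = TRUE` switches to
#' the full 5e6-step schedule with 2e6 burn-in.
#'
#' @param temperatures strictly increasing, first element 1
#' @param total_steps sweeps per chain
#' @param burn_in sweeps discarded before sampling
#' @param sample_every record a sample every this many sweeps
#' @param swap_every propose one adjacent-pair state swap every this many
#'   sweeps
#' @param move_weights named weights for the five move types
#' @param param_sd log-scale random-walk sd for parameter proposals
#' @param max_mig_events cap on migration events per branch (memory and
#'   run-time guard; proposals exceeding it are rejected)
#' @param paper_scale use the full-length chain schedule
#' @return a list of class `mcmc_config`
#' @export
mcmc_config <- function(temperatures = c(1, 1.5, 3, 1e5),
                        total_steps = if (paper_scale) 5e6 else 2e5,
                        burn_in = if (paper_scale) 2e6 else 5e4,
                        sample_every = 100L, swap_every = 10L,
                        move_weights = c(topology = 0.25, times = 0.25,
                                         scale = 0.1, paths = 0.1,
                                         deme = 0.1, params = 0.2),
                        param_sd = 0.6, max_mig_events = 200L,
                        paper_scale = FALSE) {
  stopifnot(temperatures[1L] == 1, !is.unsorted(temperatures, strictly = TRUE),
            total_steps >= 1, burn_in >= 0, burn_in < total_steps,
            all(move_weights >= 0), sum(move_weights) > 0,
            setequal(names(move_weights),
                     c("topology", "times", "scale", "paths", "deme",
                       "params")))
  structure(list(temperatures = temperatures, total_steps = total_steps,
                 burn_in = burn_in, sample_every = as.integer(sample_every),
                 swap_every = as.integer(swap_every),
                 move_weights = move_weights, param_sd = param_sd,
                 max_mig_events = as.integer(max_mig_events)),
            class = "mcmc_config")
}

#' Run the Metropolis-coupled structured-coalescent sampler
#'
#' One chain per temperature, each targeting the power posterior with
#' beta = 1/T; adjacent chains propose state swaps with the standard MC3
#' acceptance. Post-burn-in samples of the parameters and the (beta = 1
#' scale) data log-likelihood are recorded at every temperature, which is
#' what path sampling integrates.
#'
#' @param aln a `labeled_alignment`
#' @param model a [model_spec()] (its `deme_map` must cover `aln`'s demes)
#' @param priors a [coal_priors()]
#' @param config an [mcmc_config()]
#' @param seed integer seed (identical seed + config gives an identical
#'   run)
#' @param tstv_ratio,base_freqs HKY substitution parameters
#' @return an object of class `mc3_fit`: `traces` (one data frame per
#'   temperature: step, loglik, logcoal, theta.*, M.*), `beta`, acceptance
#'   and swap statistics, and the inputs
#' @export
run_mc3 <- function(aln, model, priors = coal_priors(),
                    config = mcmc_config(), seed = NULL,
                    tstv_ratio = 9, base_freqs = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(model$deme_map) >= max(aln$deme))
  data <- make_mcmc_data(aln, model, tstv_ratio, base_freqs)
  n_chain <- length(config$temperatures)
  beta <- 1 / config$temperatures
  ctl <- config

  theta0 <- rep(priors$theta$mean, model$n_theta_groups)
  M0 <- rep(min(max(10, priors$M$lower * 10), priors$M$upper / 10),
            max(model$n_mig_groups, 1L))[seq_len(model$n_mig_groups)]
  ## cascading warm start: the cold chain begins at a distance-tree state
  ## near the likelihood mode; each hotter chain inherits its colder
  ## neighbor's warm-started state and relaxes it at its own beta for a
  ## short pre-run, so every rung starts close to its own equilibrium
  warm_sweeps <- max(200L, ceiling(config$burn_in / (4L * n_chain)))
  chains <- vector("list", n_chain)
  chains[[1L]] <- refresh_cache(
    init_state_upgma(aln, data$tip_deme, theta0, M0, model,
                     config$max_mig_events),
    data, priors)
  for (i in seq_len(n_chain)) {
    if (i > 1L) chains[[i]] <- chains[[i - 1L]]
    for (s in seq_len(warm_sweeps))
      chains[[i]] <- mcmc_step(chains[[i]], data, priors, beta[i], ctl)$state
  }

  n_samp <- floor(config$total_steps / config$sample_every)
  par_names <- c(sprintf("theta.%d", seq_len(model$n_theta_groups)),
                 if (model$n_mig_groups)
                   sprintf("M.%d", seq_len(model$n_mig_groups)))
  traces <- lapply(seq_len(n_chain), function(i)
    matrix(NA_real_, n_samp, 3L + length(par_names),
           dimnames = list(NULL, c("step", "loglik", "logcoal", par_names))))
  acc <- matrix(0, n_chain, length(config$move_weights),
                dimnames = list(NULL, names(config$move_weights)))
  tries <- acc
  swap_try <- swap_acc <- numeric(max(n_chain - 1L, 1L))
  row <- 0L

  for (step in seq_len(config$total_steps)) {
    for (i in seq_len(n_chain)) {
      res <- mcmc_step(chains[[i]], data, priors, beta[i], ctl)
      chains[[i]] <- res$state
      tries[i, res$type] <- tries[i, res$type] + 1
      acc[i, res$type] <- acc[i, res$type] + res$accept
    }
    if (n_chain > 1L && step %% config$swap_every == 0L) {
      i <- sample.int(n_chain - 1L, 1L)
      swap_try[i] <- swap_try[i] + 1
      lr <- (beta[i] - beta[i + 1L]) *
        (chains[[i + 1L]]$cache$loglik - chains[[i]]$cache$loglik)
      if (log(stats::runif(1L)) < lr) {
        swap_acc[i] <- swap_acc[i] + 1
        tmp <- chains[[i]]
        chains[[i]] <- chains[[i + 1L]]
        chains[[i + 1L]] <- tmp
      }
    }
    if (step %% config$sample_every == 0L) {
      row <- row + 1L
      for (i in seq_len(n_chain)) {
        ch <- chains[[i]]
        traces[[i]][row, ] <- c(step, ch$cache$loglik, ch$cache$logcoal,
                                ch$theta, ch$M)
      }
    }
  }

  structure(list(
    traces = lapply(traces, as.data.frame),
    beta = beta, config = config, model = model, priors = priors,
    accept_rate = acc / pmax(tries, 1), swap_try = swap_try,
    swap_acc = swap_acc, n_sites = data$n_sites,
    final_states = chains), class = "mc3_fit")
}

#' @export
print.mc3_fit <- function(x, ...) {
  cat(sprintf("mc3_fit: model '%s', %d chains (T = %s), %g steps\n",
              x$model$name, length(x$beta),
              paste(signif(1 / x$beta, 3), collapse = ", "),
              x$config$total_steps))
  ml <- tryCatch(path_sampling_ml(x), error = function(e) NULL)
  if (!is.null(ml))
    cat(sprintf("  log marginal likelihood (Bezier): %.3f\n", ml$log_ml))
  invisible(x)
}

## post-burn-in rows of a trace
post_burnin <- function(fit, chain = 1L) {
  tr <- fit$traces[[chain]]
  tr[tr$step > fit$config$burn_in, , drop = FALSE]
}

#' Posterior samples of the cold chain
#'
#' @param fit an `mc3_fit`
#' @return data frame of post-burn-in cold-chain samples
#' @export
posterior_samples <- function(fit) post_burnin(fit, 1L)

#' Path-sampling marginal likelihood of a fitted model
#'
#' Takes the post-burn-in mean log-likelihood at each inverse temperature
#' and integrates the path with [bezier_marginal_likelihood()].
#'
#' @param fit an `mc3_fit`
#' @return a `marginal_likelihood` object
#' @export
path_sampling_ml <- function(fit) {
  means <- vapply(seq_along(fit$beta), function(i)
    mean(post_burnin(fit, i)$loglik), 0)
  bezier_marginal_likelihood(stats::setNames(means, fit$beta))
}

#' Bezier-corrected path-sampling estimate of the log marginal likelihood
#'
#' Thermodynamic integration: log m.l. = integral over beta in [0, 1] of
#' E_beta[log L]. With a sparse temperature ladder the straight-line
#' (trapezoid) rule badly underestimates the integral, because the true
#' path hugs its plateau over most of the first interval and plunges only
#' very close to beta = 0; the size of that error grows with the depth of
#' the plunge and therefore differs between models. The corrected estimate
#' therefore integrates the first (near-prior) interval under a smooth
#' curve with the theoretically expected hyperbolic tail,
#' `l(beta) = a - b/(beta + c)`, matched to both endpoint values and to
#' the interior slope at the second point, and the remaining intervals
#' under a cubic Hermite/Bezier interpolant (Catmull-Rom tangents). Both
#' pieces integrate in closed form; the path is extended as a constant
#' over the sliver between 0 and the smallest available beta. The plain
#' trapezoid estimate is returned alongside for comparison.
#'
#' @param mean_loglik_by_beta named numeric vector: names are beta values
#'   (must include 1 and a near-zero value), entries are posterior mean
#'   log-likelihoods
#' @return an object of class `marginal_likelihood` with `log_ml`
#'   (corrected), `trapezoid`, `per_beta`, `method`
#' @export
bezier_marginal_likelihood <- function(mean_loglik_by_beta) {
  b <- as.numeric(names(mean_loglik_by_beta))
  y <- as.numeric(mean_loglik_by_beta)
  if (length(b) < 2L || anyNA(b))
    stop("need mean log-likelihoods at >= 2 named beta values")
  o <- order(b)
  b <- b[o]; y <- y[o]
  stopifnot(all(b >= 0), all(b <= 1))

  n <- length(b)
  ## tangents: central differences inside, one-sided at the ends
  m <- numeric(n)
  m[1L] <- (y[2L] - y[1L]) / (b[2L] - b[1L])
  m[n] <- (y[n] - y[n - 1L]) / (b[n] - b[n - 1L])
  if (n > 2L) for (i in 2:(n - 1L))
    m[i] <- (y[i + 1L] - y[i - 1L]) / (b[i + 1L] - b[i - 1L])

  hermite_seg <- function(i) {
    h <- b[i + 1L] - b[i]
    h * ((y[i] + y[i + 1L]) / 2 + h * (m[i] - m[i + 1L]) / 12)
  }

  ## first segment: hyperbolic-tail curve a - b/(beta + c), slope at the
  ## right end taken one-sided from the interior
  first_seg <- function() {
    if (n < 3L) return(hermite_seg(1L))
    s1 <- (y[3L] - y[2L]) / (b[3L] - b[2L])
    delta <- y[2L] - y[1L]
    if (!(delta > 0) || !(s1 > 0) || delta <= s1 * (b[2L] - b[1L]))
      return(hermite_seg(1L))  # no plunge: plain interpolation
    f <- function(cc)
      s1 * (b[2L] + cc)^2 * (1 / (b[1L] + cc) - 1 / (b[2L] + cc)) - delta
    hi <- b[2L]
    while (f(hi) > 0) hi <- hi * 4  # f decreasing; bracket the root
    lo <- b[2L] * 1e-12
    if (f(lo) < 0) return(hermite_seg(1L))
    cc <- stats::uniroot(f, c(lo, hi), tol = b[2L] * 1e-12)$root
    bb <- s1 * (b[2L] + cc)^2
    aa <- y[2L] + bb / (b[2L] + cc)
    aa * (b[2L] - b[1L]) - bb * log((b[2L] + cc) / (b[1L] + cc))
  }

  bez <- first_seg()
  trap <- (b[2L] - b[1L]) * (y[1L] + y[2L]) / 2
  if (n > 2L) for (i in 2:(n - 1L)) {
    bez <- bez + hermite_seg(i)
    trap <- trap + (b[i + 1L] - b[i]) * (y[i] + y[i + 1L]) / 2
  }
  ## constant extension over [0, b_min] and [b_max, 1]
  edge <- b[1L] * y[1L] + (1 - b[n]) * y[n]
  structure(list(log_ml = bez + edge, trapezoid = trap + edge,
                 per_beta = stats::setNames(y, b), method = "bezier"),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("log marginal likelihood: %.3f (Bezier), %.3f (trapezoid)\n",
              x$log_ml, x$trapezoid))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest interval containing a fraction `prob` of the samples.
#'
#' @param x numeric sample vector
#' @param prob coverage probability (default 0.95)
#' @return length-2 numeric (lower, upper)
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - k)
  width <- x[starts + k] - x[starts]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Summarize a fitted model
#'
#' Posterior medians, 95% HPD intervals and effective sample sizes of the
#' cold-chain parameters, plus the path-sampling marginal likelihood.
#'
#' @param object an `mc3_fit`
#' @param ... unused
#' @return a list with `params` (data frame) and `log_ml`
#' @export
summary.mc3_fit <- function(object, ...) {
  s <- posterior_samples(object)
  pars <- setdiff(colnames(s), c("step", "loglik", "logcoal"))
  tab <- do.call(rbind, lapply(pars, function(p) {
    v <- s[[p]]
    hpd <- hpd_interval(v)
    data.frame(parameter = p, median = stats::median(v),
               hpd_lower = hpd[1L], hpd_upper = hpd[2L], ess = ess(v))
  }))
  ml <- path_sampling_ml(object)
  list(params = tab, log_ml = ml$log_ml, ml = ml)
}
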