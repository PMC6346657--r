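## Model selection: replicate marginal-likelihood estimates per model,
## relative model probabilities, the permutation t-test ambiguity rule,
## and the posterior-draw slope test against habitat covariates.

#' Replicate marginal-likelihood estimates for one model
#'
#' Runs the sampler `n_estimates * n_runs_per_estimate` times and averages
#' each consecutive group of `n_runs_per_estimate` Bezier log marginal
#' likelihoods into one replicate estimate (the replication scheme used to
#' feed the permutation t-test).
#'
#' @param aln a `labeled_alignment`
#' @param model a [model_spec()]
#' @param priors a [coal_priors()]
#' @param config an [mcmc_config()]
#' @param n_estimates number of replicate estimates (>= 2 for
#'   [select_model()])
#' @param n_runs_per_estimate independent runs averaged per estimate
#' @param seed base seed; run r uses a derived stream
#' @return an object of class `model_evidence`: `model`, `log_ml`
#'   (per-estimate vector), `mean_log_ml`, `n_params`, `fits` (the last
#'   run's fit, for diagnostics)
#' @export
model_evidence <- function(aln, model, priors = coal_priors(),
                           config = mcmc_config(), n_estimates = 3L,
                           n_runs_per_estimate = 1L, seed = 1L) {
  runs <- n_estimates * n_runs_per_estimate
  lml <- numeric(runs)
  fit <- NULL
  for (r in seq_len(runs)) {
    fit <- run_mc3(aln, model, priors, config,
                   seed = derive_seed(seed, stratum = r))
    lml[r] <- path_sampling_ml(fit)$log_ml
  }
  est <- colMeans(matrix(lml, n_runs_per_estimate, n_estimates))
  structure(list(model = model$name, log_ml = est, mean_log_ml = mean(est),
                 n_params = count_parameters(model), last_fit = fit),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("model_evidence '%s': mean log m.l. %.3f over %d estimates (%s)\n",
              x$model, x$mean_log_ml, length(x$log_ml),
              paste(sprintf("%.2f", x$log_ml), collapse = ", ")))
  invisible(x)
}

#' Relative model probabilities from log marginal likelihoods
#'
#' p_i = exp(lml_i - max) / sum_j exp(lml_j - max); invariant to adding a
#' constant to every log marginal likelihood.
#'
#' @param log_mls named numeric vector of log marginal likelihoods
#' @return named probabilities summing to 1
#' @export
relative_probabilities <- function(log_mls) {
  stopifnot(length(log_mls) >= 2L)
  w <- exp(log_mls - max(log_mls))
  w / sum(w)
}

#' Two-sample permutation t-test
#'
#' Two-sided test of equal means using the two-sample pooled-variance t
#' statistic, with the reference distribution obtained by permuting group
#' labels: exhaustively when the number of splits is at most `max_exact`,
#' otherwise by Monte-Carlo with `n_perm` random permutations. The observed
#' split is part of the reference set, so p >= 1/#splits.
#'
#' With three replicates per group the smallest attainable two-sided
#' exhaustive p is 2/20 = 0.1, so three-replicate comparisons can never be
#' called unambiguous at 0.05 under the default; the one-sided alternative
#' (`"greater"`: first group larger), whose floor is 1/20, is available for
#' that design.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each)
#' @param max_exact largest number of splits enumerated exhaustively
#' @param n_perm Monte-Carlo permutations otherwise
#' @param alternative `"two.sided"` (default) or `"greater"`
#' @return the permutation p-value
#' @export
permutation_t_test <- function(groupA, groupB, max_exact = 1e4,
                               n_perm = 9999L,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 2L, nB >= 2L, all(is.finite(c(groupA, groupB))))
  pool <- c(groupA, groupB)
  tstat <- function(idxA) {
    a <- pool[idxA]; b <- pool[-idxA]
    sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) /
      (nA + nB - 2)
    d <- mean(a) - mean(b)
    if (sp2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  side <- if (alternative == "two.sided") abs else identity
  t_obs <- side(tstat(seq_len(nA)))
  if (choose(nA + nB, nA) <= max_exact) {
    splits <- utils::combn(nA + nB, nA, simplify = FALSE)
    t_perm <- vapply(splits, function(i) side(tstat(i)), 0)
    mean(t_perm >= t_obs - 1e-12)
  } else {
    t_perm <- vapply(seq_len(n_perm), function(i)
      side(tstat(sample.int(nA + nB, nA))), 0)
    (sum(t_perm >= t_obs - 1e-12) + 1) / (n_perm + 1)
  }
}

#' Select the best metapopulation model from replicate evidence
#'
#' Ranks models by mean log marginal likelihood, compares the best against
#' the second best with the permutation t-test on their replicate
#' estimates, and flags the selection as ambiguous when p > 0.05. Ties in
#' the mean (practically impossible with real-valued estimates) are broken
#' toward the model with fewer parameters.
#'
#' @param evidence list of >= 2 [model_evidence()] objects (>= 2 replicate
#'   estimates each)
#' @param alpha ambiguity threshold on the permutation p (default 0.05)
#' @return an object of class `selection_result`: `best`, `second`, `p`,
#'   `ambiguous`, `probabilities`, `table`
#' @export
select_model <- function(evidence, alpha = 0.05) {
  stopifnot(length(evidence) >= 2L,
            all(vapply(evidence, function(e) length(e$log_ml) >= 2L, TRUE)))
  means <- vapply(evidence, function(e) e$mean_log_ml, 0)
  npar <- vapply(evidence, function(e) e$n_params, 0)
  nm <- vapply(evidence, function(e) e$model, "")
  o <- order(-means, npar)  # parsimony tie-break, deterministic
  best <- evidence[[o[1L]]]
  second <- evidence[[o[2L]]]
  p <- permutation_t_test(best$log_ml, second$log_ml)
  probs <- relative_probabilities(stats::setNames(means, nm))
  structure(list(best = best$model, second = second$model, p = p,
                 ambiguous = p > alpha, probabilities = probs,
                 table = data.frame(model = nm[o], mean_log_ml = means[o],
                                    n_params = npar[o], row.names = NULL)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("best model: %s (vs %s, permutation p = %.3g%s)\n",
              x$best, x$second, x$p,
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Posterior-draw slope test of Theta against an island covariate
#'
#' For each of `n_draws` draws, one posterior sample of Theta is taken per
#' island and the ordinary least-squares slope of ln(Theta) on the
#' covariate (habitat area or census size) is recorded; the relationship is
#' called significant when the slope is positive in at least `level` of
#' draws.
#'
#' @param theta_posteriors list (one element per island) of posterior Theta
#'   sample vectors
#' @param covariate numeric covariate per island (same order)
#' @param n_draws number of draws (default 10000)
#' @param level required positive-slope fraction (default 0.95)
#' @return an object of class `slope_test`: `fraction_positive`,
#'   `significant`, `n_draws`
#' @export
posterior_slope_test <- function(theta_posteriors, covariate,
                                 n_draws = 10000L, level = 0.95) {
  k <- length(theta_posteriors)
  stopifnot(k >= 3L, length(covariate) == k)
  if (stats::sd(covariate) == 0) stop("constant covariate")
  x <- covariate - mean(covariate)
  sxx <- sum(x^2)
  draws <- vapply(theta_posteriors, function(s)
    sample(s, n_draws, replace = TRUE), numeric(n_draws))
  ## OLS slope per draw: sum(x * centered y) / sum(x^2), vectorized
  ly <- log(draws)
  slopes <- as.vector(ly %*% x) / sxx  # x is centered, so no y-centering
  frac <- mean(slopes > 0)
  structure(list(fraction_positive = frac, significant = frac >= level,
                 n_draws = as.integer(n_draws)),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("posterior slope test: positive slope in %.1f%% of %d draws%s\n",
              100 * x$fraction_positive, x$n_draws,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
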