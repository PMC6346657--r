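test_that("pruning likelihood matches trivial closed forms", {
  mod <- one_deme_model()
  ## two tips, zero-length branches, both 'A', one site: log pi_A
  st <- manual_state(time = c(0, 0, 0), parent = c(3, 3, 0),
                     deme = c(1, 1, 1), theta = 0.01)
  aln <- aln_from_strings(c("A", "A"), c(1, 1))
  expect_equal(felsenstein_loglik(st, aln), log(0.25), tolerance = 1e-9)
  ## empty alignment: log-likelihood 0 for any genealogy
  aln0 <- labeled_alignment(matrix(integer(0), 2, 0), c(1, 1))
  expect_equal(felsenstein_loglik(st, aln0), 0)
})

test_that("pruning likelihood matches exhaustive ancestral-state summation", {
  set.seed(17)
  for (rep in 1:3) {
    ## random 3-tip ultrametric tree: tips 1-3, internals 4 (recent), 5 root
    t1 <- runif(1, 0.01, 0.2); t2 <- t1 + runif(1, 0.01, 0.2)
    time <- c(0, 0, 0, t1, t2)
    parent <- c(4L, 4L, 5L, 5L, 0L)
    tips <- matrix(sample.int(4, 6, replace = TRUE), 3, 2)
    st <- manual_state(time, parent, rep(1L, 5), 0.01)
    aln <- labeled_alignment(tips, rep(1, 3))
    expect_equal(felsenstein_loglik(st, aln),
                 brute_force_loglik(time, parent, tips),
                 tolerance = 1e-8)
  }
})

test_that("pruning likelihood agrees with phangorn on a simulated dataset", {
  skip_if_not_installed("phangorn")
  skip_if_not_installed("ape")
  p <- sim_params(deme_size = 1000, mig_prop = 0.01, n_demes = 2,
                  sample_size = 5, mut_rate = 1e-5, locus_length = 200)
  set.seed(23)
  gen <- simulate_genealogy(p)
  aln <- simulate_sequences(gen, p)
  st <- manual_state(gen$time * p$mut_rate, gen$parent,
                     rep(1L, length(gen$time)), 0.01)
  ll <- felsenstein_loglik(st, aln)
  tree <- as_phylo(gen, scale = p$mut_rate)
  chars <- matrix(coalselect:::DNA_BASES[aln$seq], nrow(aln$seq))
  rownames(chars) <- tree$tip.label
  pd <- phangorn::phyDat(chars)
  fit <- phangorn::pml(tree, pd, model = "HKY",
                       bf = rep(0.25, 4), Q = c(1, 9, 1, 1, 9, 1))
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  ## under a reversible model only the sum of the two root branch lengths
  ## matters; node times here are bookkeeping, so the root can be slid by
  ## trading length between its two branches
  set.seed(29)
  tips2 <- matrix(sample.int(4, 40, replace = TRUE), 2, 20)
  aln2 <- labeled_alignment(tips2, c(1, 1))
  ll_split <- function(a, b) {
    st <- manual_state(time = c(0, a - b, a), parent = c(3, 3, 0),
                       deme = rep(1, 3), theta = 0.01)
    felsenstein_loglik(st, aln2)
  }
  expect_equal(ll_split(0.1, 0.1), ll_split(0.15, 0.05), tolerance = 1e-9)
  expect_equal(ll_split(0.1, 0.1), ll_split(0.19, 0.01), tolerance = 1e-9)
  ## 3 tips: slide the root along the branch to the outgroup tip
  tips3 <- matrix(sample.int(4, 30, replace = TRUE), 3, 10)
  aln3 <- labeled_alignment(tips3, rep(1, 3))
  ll_root <- function(delta) {
    ## tips 1,2 join at node 4 (t = 0.05); root 5 above; tip 3 hangs from
    ## the root; moving the root by delta keeps the path 4-5-3 constant
    manual <- manual_state(
      time = c(0, 0, 2 * delta, 0.05, 0.2 + delta),
      parent = c(4, 4, 5, 5, 0), deme = rep(1, 5), theta = 0.01)
    felsenstein_loglik(manual, aln3)
  }
  expect_equal(ll_root(0), ll_root(0.03), tolerance = 1e-9)
  expect_equal(ll_root(0), ll_root(0.07), tolerance = 1e-9)
})

test_that("structured-coalescent density matches closed forms", {
  ## one deme, two lineages, coalescence at time t: log[(2/theta) e^{-2t/theta}]
  th <- 0.02; t <- 0.013
  st <- manual_state(time = c(0, 0, t), parent = c(3, 3, 0),
                     deme = c(1, 1, 1), theta = th)
  expect_equal(structured_coalescent_logdensity(st),
               log(2 / th) - 2 * t / th, tolerance = 1e-12)
  ## lineages in different demes with no migration events: impossible
  mod2 <- two_deme_model()
  st2 <- coalselect:::new_genealogy_state(
    2L, c(0, 0, t), c(3L, 3L, 0L), c(1L, 2L, 1L),
    rep(list(coalselect:::no_events), 3), th, 1e-8, mod2)
  expect_equal(structured_coalescent_logdensity(st2), -Inf)
  ## with one migration event the density picks up the rate factors
  ev <- rep(list(coalselect:::no_events), 3)
  tm <- 0.004; M <- 3
  ev[[2]] <- matrix(c(tm, 2, 1), 1, 3)
  st3 <- coalselect:::new_genealogy_state(
    2L, c(0, 0, t), c(3L, 3L, 0L), c(1L, 2L, 1L), ev, th, M, mod2)
  ## intervals: [0,tm): both apart, rate = 2M (each lineage migrates at M);
  ## [tm,t): together, rate = 2/theta + 2M; event factors M and 2/theta
  expected <- -(2 * M) * tm + log(M) -
    (2 / th + 2 * M) * (t - tm) + log(2 / th)
  expect_equal(structured_coalescent_logdensity(st3), expected,
               tolerance = 1e-12)
})

test_that("both density computation routes agree on simulated states", {
  mod <- two_deme_model()
  set.seed(31)
  for (i in 1:5) {
    st <- coalselect:::simulate_state(rep(1:2, each = 4), 0.02, 5, mod)
    ev <- coalselect:::state_event_table(st)
    k0 <- tabulate(st$node_deme[1:st$n_tips], 2)
    d1 <- coalselect:::struct_coal_loglik_cpp(
      ev$time, ev$type, ev$d1, ev$d2, k0, rep(0.02, 2),
      matrix(c(0, 5, 5, 0), 2, 2))
    expect_equal(structured_coalescent_logdensity(st), d1,
                 tolerance = 1e-10)
    expect_true(coalselect:::validate_state(st))
  }
})

test_that("forward-simulated event frequencies match competing-risk ratios", {
  ## two demes, one lineage each: the first event is a migration; the next
  ## event is a coalescence with probability (2/theta)/(2/theta + 2M)
  mod <- two_deme_model()
  th <- 0.05; M <- 40
  p_coal <- (2 / th) / (2 / th + 2 * M)
  set.seed(37)
  one_mig <- replicate(2000, {
    st <- coalselect:::simulate_state(c(1L, 2L), th, M, mod)
    sum(vapply(st$events, nrow, 0L)) == 1L
  })
  expect_equal(mean(one_mig), p_coal, tolerance = 0.05)
})

test_that("small-matrix exponential matches Matrix::expm", {
  skip_if_not_installed("Matrix")
  set.seed(41)
  for (K in c(2, 5, 10)) {
    Mm <- matrix(runif(K * K, 0, 3), K, K); diag(Mm) <- 0
    G <- coalselect:::mig_generator(Mm)
    expect_equal(coalselect:::mat_exp(G * 0.7),
                 as.matrix(Matrix::expm(G * 0.7)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("endpoint-conditioned path sampler matches the conditioned law", {
  ## two demes: P(0 events | a = b) from uniformization must equal
  ## exp(-q tau) / P_aa(tau); compare frequencies against the analytic value
  Mm <- matrix(c(0, 2, 2, 0), 2, 2)
  tau <- 0.4
  P <- coalselect:::mat_exp(coalselect:::mig_generator(Mm) * tau)
  p0 <- exp(-2 * tau) / P[1, 1]
  set.seed(43)
  n0 <- replicate(3000, nrow(coalselect:::sample_cond_path(1, 1, 0, tau, Mm)) == 0)
  expect_equal(mean(n0), p0, tolerance = 0.04)
  ## conditioned on different endpoints, paths have odd event counts
  odd <- replicate(500, nrow(coalselect:::sample_cond_path(1, 2, 0, tau, Mm)) %% 2 == 1)
  expect_true(all(odd))
  ## path density: no-event path from a to a
  expect_equal(coalselect:::path_logdens(coalselect:::no_events, 1, 1, 0,
                                         tau, Mm),
               -2 * tau - log(P[1, 1]), tolerance = 1e-10)
})

test_that("zero-site data recover the prior (posterior-prior consistency)", {
  ## with no sites the likelihood is flat, so marginal parameter posteriors
  ## must equal the windowed exponential priors for a structured model
  ## two tips in two demes: the smallest structured state, whose fast
  ## excursions make single-run KS tests well calibrated
  aln0 <- labeled_alignment(matrix(integer(0), 2, 0), 1:2)
  pri <- coal_priors(M_lower = 0.1, M_upper = 100, M_mean = 10)
  cfg <- mcmc_config(temperatures = 1, total_steps = 300000,
                     burn_in = 30000, sample_every = 100)
  fit <- run_mc3(aln0, two_deme_model(), pri, cfg, seed = 4)
  s <- posterior_samples(fit)
  thin <- s[seq(1, nrow(s), 18), ]  # near-independent draws for the KS
  ks_th <- ks.test(thin$theta.1,
                   function(q) coalselect:::ptruncexp(q, 0.01, 1e-5, 1e-1))
  ks_M <- ks.test(thin$M.1,
                  function(q) coalselect:::ptruncexp(q, 10, 0.1, 100))
  expect_gt(ks_th$p.value, 0.01)
  expect_gt(ks_M$p.value, 0.01)
})

test_that("two-tip posterior matches the grid posterior (TV < 0.02)", {
  set.seed(47)
  p <- sim_params(deme_size = 5e4, mig_prop = 0, n_demes = 1,
                  sample_size = 2, locus_length = 200,
                  expansion_factor = 1)
  aln <- simulate_dataset(p, seed = 9)
  mod <- one_deme_model()
  pri <- coal_priors()
  ## grid posterior p(theta | D) with the genealogy integrated out
  data <- coalselect:::make_mcmc_data(aln, mod)
  Lt <- function(t) coalselect:::state_loglik(
    manual_state(c(0, 0, t), c(3, 3, 0), rep(1, 3), 0.01), data)
  tg <- exp(seq(log(1e-7), log(2), length.out = 1200))
  llt <- vapply(tg, Lt, 0)
  wt <- c(diff(tg) / 2, 0) + c(0, diff(tg) / 2)
  post_t <- function(theta) {
    ld <- llt + log(2 / theta) - 2 * tg / theta
    m <- max(ld); m + log(sum(exp(ld - m) * wt))
  }
  thg <- exp(seq(log(1e-5), log(1e-1), length.out = 250))
  lp <- vapply(thg, post_t, 0) +
    coalselect:::dtruncexp(thg, 0.01, 1e-5, 1e-1, log = TRUE)
  wth <- c(diff(thg) / 2, 0) + c(0, diff(thg) / 2)
  pg <- exp(lp - max(lp)) * wth
  pg <- pg / sum(pg)
  ## five equal-mass bins of the grid posterior
  cdf <- cumsum(pg)
  edges <- thg[vapply(c(0.2, 0.4, 0.6, 0.8), function(q)
    which.min(abs(cdf - q)), 1L)]
  cfg <- mcmc_config(temperatures = 1, total_steps = 60000, burn_in = 10000,
                     sample_every = 10)
  fit <- run_mc3(aln, mod, pri, cfg, seed = 3)
  th <- posterior_samples(fit)$theta.1
  counts <- table(cut(th, c(0, edges, Inf))) / length(th)
  expect_lt(0.5 * sum(abs(as.numeric(counts) - 0.2)), 0.02)
})

test_that("identical seed and config give bit-identical traces", {
  aln <- make_two_deme_aln(seed = 5, sample_size = 4)
  cfg <- mcmc_config(total_steps = 400, burn_in = 100, sample_every = 10)
  f1 <- run_mc3(aln, two_deme_model(), coal_priors(), cfg, seed = 11)
  f2 <- run_mc3(aln, two_deme_model(), coal_priors(), cfg, seed = 11)
  expect_identical(f1$traces, f2$traces)
  ## single temperature reduces to plain MCMC
  cfg1 <- mcmc_config(temperatures = 1, total_steps = 400, burn_in = 100,
                      sample_every = 10)
  f3 <- run_mc3(aln, two_deme_model(), coal_priors(), cfg1, seed = 11)
  expect_length(f3$traces, 1L)
})

test_that("heated chains order mean log-likelihood and swap acceptance", {
  aln <- make_two_deme_aln(seed = 6, sample_size = 6)
  cfg <- mcmc_config(temperatures = c(1, 1.2, 1e5), total_steps = 4000,
                     burn_in = 1000, sample_every = 10, swap_every = 5)
  fit <- run_mc3(aln, two_deme_model(), coal_priors(), cfg, seed = 2)
  means <- vapply(seq_along(fit$beta), function(i)
    mean(fit$traces[[i]]$loglik[fit$traces[[i]]$step > 1000]), 0)
  ## log-likelihood mean non-increasing as chains heat up
  expect_true(all(diff(means) < 50))
  expect_lt(means[3], means[1])
  ## swaps between adjacent cool chains accept more than the cool/prior pair
  rate <- fit$swap_acc / pmax(fit$swap_try, 1)
  expect_gt(rate[1], rate[2])
})

test_that("sampler moves preserve state validity", {
  aln <- make_two_deme_aln(seed = 8, sample_size = 5)
  cfg <- mcmc_config(total_steps = 600, burn_in = 100, sample_every = 50)
  fit <- run_mc3(aln, two_deme_model(), coal_priors(), cfg, seed = 13)
  for (st in fit$final_states) {
    expect_true(coalselect:::validate_state(st))
    expect_true(is.finite(structured_coalescent_logdensity(st)))
  }
})
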