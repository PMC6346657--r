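test_that("simulation model set matches the seven hypotheses", {
  models <- build_simulation_models(10)
  expect_named(models, c("panmixia", "regional_shared", "regional_free",
                         "island", "island_regional", "stepping_stone_2p",
                         "stepping_stone_full"))
  counts <- vapply(models, count_parameters, 0L)
  expect_equal(unname(counts),
               c(1L, 2L, 13L, 2L, 2L, 2L, 28L))
  expect_equal(count_parameters(models$stepping_stone_full), 28L)
  expect_equal(models$stepping_stone_full$n_theta_groups, 10L)
  expect_equal(models$stepping_stone_full$n_mig_groups, 18L)
  ## regional models lump adjacent pairs
  expect_equal(models$regional_shared$deme_map, rep(1:5, each = 2))
  ## island model: all ordered pairs share one rate
  expect_true(all(models$island$mig_group[upper.tri(diag(10))] == 1L))
})

test_that("archipelago model set carries the stated parameter counts", {
  isl <- sprintf("I%d", 1:8)
  models <- build_hawaii_models(isl, region2a_boundary = 4,
                                region2b_boundary = 3,
                                region3_boundaries = c(3, 6))
  expect_length(models, 7L)
  ## two-currents: K = 3, 3 Theta, 6 m/mu
  m3 <- models$regional_3_two_currents
  expect_equal(m3$K, 3L)
  expect_equal(m3$n_theta_groups, 3L)
  expect_equal(m3$n_mig_groups, 6L)
  ## 2-region: 2 Theta, 2 migration parameters
  expect_equal(count_parameters(models$regional_2_mhi_nwhi), 4L)
  expect_equal(models$regional_2_mhi_nwhi$n_theta_groups, 2L)
  expect_equal(models$regional_2_mhi_nwhi$n_mig_groups, 2L)
  ## full stepping-stone: n Theta and 2n - 2 migration parameters
  full <- models$stepping_stone_full
  expect_equal(full$n_theta_groups, 8L)
  expect_equal(full$n_mig_groups, 2L * 8L - 2L)
  expect_equal(count_parameters(models$panmixia), 1L)
  expect_equal(count_parameters(models$island), 2L)
  ## invalid boundary
  expect_error(build_hawaii_models(isl, region2a_boundary = 8),
               "boundary")
  ## optional custom partition appends an eighth model
  m8 <- build_hawaii_models(isl, custom_partition = c(1, 1, 2, 2, 2, 3, 3, 3))
  expect_length(m8, 8L)
  expect_equal(m8$custom$K, 3L)
})

test_that("relative probabilities are a shift-invariant softmax", {
  lml <- c(a = 0, b = -log(2))
  expect_equal(unname(relative_probabilities(lml)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(relative_probabilities(lml + 1234.5),
               relative_probabilities(lml), tolerance = 1e-12)
  seven <- stats::setNames(rep(-100, 7), letters[1:7])
  expect_equal(unname(relative_probabilities(seven)), rep(1 / 7, 7))
  big <- c(a = 0, b = -100, c = -200)
  expect_gte(relative_probabilities(big)[["a"]], 1 - 1e-40)
})

test_that("permutation t-test matches exhaustive enumeration", {
  ## 3 vs 3, no overlap, all distinct: only the observed split and its
  ## mirror reach |t|, so the two-sided exhaustive p is 2/20
  expect_equal(permutation_t_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  ## identical groups: p = 1
  expect_equal(permutation_t_test(c(5, 6, 7), c(5, 6, 7)), 1)
  ## one-sided option has floor 1/20 for 3 vs 3
  expect_equal(permutation_t_test(c(10, 11, 12), c(1, 2, 3),
                                  alternative = "greater"), 1 / 20)
  ## p is bounded below by 1/#splits
  set.seed(51)
  for (i in 1:5) {
    p <- permutation_t_test(rnorm(3), rnorm(3))
    expect_gte(p, 2 / 20 - 1e-12)
    expect_lte(p, 1)
  }
  ## agreement with a direct enumeration oracle on a random 4 vs 3 case
  a <- c(0.3, 1.2, -0.5, 0.9); b <- c(2.0, 1.8, 0.1)
  tstat <- function(x, y) {
    sp <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp * (1 / length(x) + 1 / length(y)))
  }
  pool <- c(a, b)
  t_all <- combn(7, 4, function(i) abs(tstat(pool[i], pool[-i])))
  p_ref <- mean(t_all >= abs(tstat(a, b)) - 1e-12)
  expect_equal(permutation_t_test(a, b), p_ref, tolerance = 1e-12)
})

test_that("select_model ranks, tests ambiguity, and is order-invariant", {
  ev <- function(name, lml, npar) structure(
    list(model = name, log_ml = lml, mean_log_ml = mean(lml),
         n_params = npar), class = "model_evidence")
  clear <- list(ev("A", c(-100, -101, -99, -100.5), 2),
                ev("B", c(-152, -150, -154, -151), 28),
                ev("C", c(-400, -401, -399, -400), 1))
  sel <- select_model(clear)
  expect_equal(sel$best, "A")
  expect_equal(sel$second, "B")
  expect_false(sel$ambiguous)
  expect_equal(sum(sel$probabilities), 1)
  sel_rev <- select_model(rev(clear))
  expect_equal(sel_rev$best, sel$best)
  expect_equal(sel_rev$p, sel$p)
  ## interleaved replicate values: ambiguous
  fuzzy <- list(ev("A", c(-10, -12, -11), 2), ev("B", c(-11, -10.5, -11.5), 3))
  expect_true(select_model(fuzzy)$ambiguous)
  ## single model is a precondition violation
  expect_error(select_model(clear[1]))
})

test_that("posterior slope test behaves at its design points", {
  set.seed(61)
  ## identical posteriors across islands: fraction near 0.5
  same <- replicate(4, exp(rnorm(500, -4, 0.3)), simplify = FALSE)
  r <- posterior_slope_test(same, c(10, 20, 30, 40), n_draws = 4000)
  expect_gt(r$fraction_positive, 0.40)
  expect_lt(r$fraction_positive, 0.60)
  expect_false(r$significant)
  ## ln Theta centered on c * area with tight spread: fraction near 1
  area <- c(10, 20, 30, 40)
  tight <- lapply(area, function(a) exp(rnorm(500, 0.1 * a - 6, 0.05)))
  r2 <- posterior_slope_test(tight, area, n_draws = 2000)
  expect_gt(r2$fraction_positive, 0.99)
  expect_true(r2$significant)
  ## single draw is degenerate but well-defined
  r3 <- posterior_slope_test(tight, area, n_draws = 1)
  expect_true(r3$fraction_positive %in% c(0, 1))
  expect_error(posterior_slope_test(tight, rep(1, 4)), "constant")
})

test_that("windowed exponential prior machinery is self-consistent", {
  set.seed(71)
  x <- coalselect:::rtruncexp(4000, 0.01, 1e-5, 1e-1)
  expect_true(all(x >= 1e-5 & x <= 1e-1))
  ks <- ks.test(x, function(q) coalselect:::ptruncexp(q, 0.01, 1e-5, 1e-1))
  expect_gt(ks$p.value, 0.01)
  ## density integrates to 1 over the window
  igr <- integrate(function(t) coalselect:::dtruncexp(t, 0.01, 1e-5, 1e-1),
                   1e-5, 1e-1)
  expect_equal(igr$value, 1, tolerance = 1e-6)
})
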