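test_that("Phi_ST equals the hand-computed AMOVA decomposition on a toy", {
  ## demes {AA, AA} and {AT, TT}: squared distances d(1,3)=d(2,3)=d(3,4)=1,
  ## d(1,4)=d(2,4)=2. SSD_total = 7/4, SSD_within = 0 + 1/2,
  ## sigma2_w = (1/2)/2 = 1/4, n_c = 2, sigma2_a = (5/4 - 1/4)/2 = 1/2,
  ## Phi_ST = (1/2)/(3/4) = 2/3.
  aln <- aln_from_strings(c("AA", "AA", "AT", "TT"), c(1, 1, 2, 2))
  phi <- pairwise_phi_st(aln)
  expect_equal(phi[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(phi[2, 1], phi[1, 2])
  expect_equal(diag(phi), rep(0, 2), ignore_attr = TRUE)
})

test_that("Phi_ST is 1 for fixed differences and ~0 for identical demes", {
  fixed <- aln_from_strings(c("AAAA", "AAAA", "TTTT", "TTTT"), c(1, 1, 2, 2))
  expect_equal(pairwise_phi_st(fixed)[1, 2], 1, tolerance = 1e-12)
  ## identical balanced haplotype composition: zero among-deme variance
  same <- aln_from_strings(c("AAAA", "TTTT", "AAAA", "TTTT"), c(1, 1, 2, 2))
  expect_lte(pairwise_phi_st(same)[1, 2], 0)
  ## monomorphic pair defined as 0 and flagged
  mono <- aln_from_strings(c("AA", "AA", "AA", "AA"), c(1, 1, 2, 2))
  phi <- pairwise_phi_st(mono)
  expect_equal(phi[1, 2], 0)
  expect_true(attr(phi, "monomorphic")[1, 2])
})

test_that("Weir-Cockerham theta matches the moment equations on paper", {
  ## two demes, 5+5 samples, two haplotypes at counts (4,1) and (1,4):
  ## per allele p = (0.8, 0.2), pbar = 0.5, MSA = 0.9, MSW = 1.6/8 = 0.2,
  ## n_c = 5, a = 0.14, b = 0.2; two symmetric alleles give
  ## theta = 0.28/0.68 = 7/17.
  aln <- aln_from_strings(c("A", "A", "A", "A", "T",
                            "T", "T", "T", "T", "A"),
                          rep(1:2, each = 5))
  th <- pairwise_wc_theta(aln)
  expect_equal(th[1, 2], 7 / 17, tolerance = 1e-12)
})

test_that("Weir-Cockerham theta equals the one-way ANOVA moment estimator", {
  set.seed(21)
  p <- sim_params(deme_size = 500, mig_prop = 0.02, n_demes = 2,
                  sample_size = 7, mut_rate = 2e-5, locus_length = 300)
  aln <- simulate_dataset(p)
  hap <- coalselect:::haplotype_index(aln)
  grp <- factor(aln$deme)
  n <- tabulate(aln$deme, 2)
  n_c <- sum(n) - sum(n^2) / sum(n)
  A <- B <- 0
  for (u in unique(hap)) {
    y <- as.numeric(hap == u)
    av <- anova(lm(y ~ grp))
    a <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / n_c
    A <- A + a
    B <- B + av$`Mean Sq`[2]
  }
  expect_equal(pairwise_wc_theta(aln)[1, 2], A / (A + B), tolerance = 1e-10)
})

test_that("theta is 1 for fixed haplotype differences", {
  aln <- aln_from_strings(c("AAT", "AAT", "GGA", "GGA"), c(1, 1, 2, 2))
  expect_equal(pairwise_wc_theta(aln)[1, 2], 1, tolerance = 1e-12)
})

test_that("Phi_ST equals theta when all haplotypes are one difference apart", {
  ## with unit distances between all distinct haplotypes the AMOVA distance
  ## matrix equals the identity-based allele mismatch matrix
  aln <- aln_from_strings(c("A", "A", "C", "A", "C", "C", "C", "G"),
                          rep(1:2, each = 4))
  expect_equal(pairwise_phi_st(aln)[1, 2], pairwise_wc_theta(aln)[1, 2],
               tolerance = 1e-12)
})

test_that("estimators are invariant to relabeling samples and demes", {
  set.seed(31)
  p <- sim_params(deme_size = 800, mig_prop = 0.01, n_demes = 3,
                  sample_size = 5, mut_rate = 1e-5)
  aln <- simulate_dataset(p)
  phi <- pairwise_phi_st(aln)
  th <- pairwise_wc_theta(aln)
  ## permute samples within the alignment
  o <- sample(nrow(aln$seq))
  aln2 <- labeled_alignment(aln$seq[o, ], aln$deme[o])
  expect_equal(unclass(pairwise_phi_st(aln2)), unclass(phi),
               ignore_attr = TRUE)
  ## permute deme order: matrix is permutation-equivariant
  pm <- c(3L, 1L, 2L)
  aln3 <- labeled_alignment(aln$seq, pm[aln$deme],
                            lattice = order(pm))
  phi3 <- pairwise_phi_st(aln3)
  expect_equal(unclass(phi3[pm, pm]), unclass(phi), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(pairwise_wc_theta(aln3)[pm, pm]), unclass(th),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("haplotype diversity follows Nei's formula", {
  expect_equal(haplotype_diversity(
    aln_from_strings(c("AA", "AA", "AA"), c(1, 1, 1))), 0)
  expect_equal(haplotype_diversity(
    aln_from_strings(c("AA", "AT"), c(1, 1))), 1)
  ## frequencies (0.5, 0.3, 0.2) with n = 10: (10/9) * (1 - 0.38)
  seqs <- c(rep("A", 5), rep("C", 3), rep("G", 2))
  expect_equal(haplotype_diversity(aln_from_strings(seqs, rep(1, 10))),
               (10 / 9) * (1 - 0.38), tolerance = 1e-12)
})

test_that("island-model F_ST anchor reproduces the 100-migrant value", {
  expect_equal(round(fst_expected_island(100), 3), 0.002)
  expect_equal(fst_expected_island(100), 1 / 401, tolerance = 1e-12)
  expect_equal(fst_expected_island(100, ploidy = 1), 1 / 201,
               tolerance = 1e-12)
  expect_equal(fst_expected_island(0), 1)
})

test_that("Mantel test matches exhaustive enumeration on 4x4 matrices", {
  set.seed(41)
  for (i in 1:3) {
    g <- matrix(0, 4, 4); g[upper.tri(g)] <- runif(6)
    g <- g + t(g)
    geo <- abs(outer(1:4, 1:4, "-"))
    exact <- mantel_exact(g, geo)
    res <- mantel_test(g, geo, n_perm = 40000)
    expect_equal(res$r, exact$r, tolerance = 1e-12)
    expect_equal(res$p, exact$p, tolerance = 0.01)
  }
})

test_that("Mantel statistic agrees with vegan and handles edge cases", {
  skip_if_not_installed("vegan")
  set.seed(43)
  g <- matrix(0, 6, 6); g[upper.tri(g)] <- runif(15); g <- g + t(g)
  geo <- abs(outer(1:6, 1:6, "-"))
  ref <- vegan::mantel(as.dist(g), as.dist(geo), permutations = 99)
  res <- mantel_test(g, geo)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-10)
  ## proportional matrices: maximal statistic (irregular spacing so no
  ## permutation ties the observed correlation)
  pos <- c(0, 1, 3, 7, 12, 20)
  geo_irr <- abs(outer(pos, pos, "-"))
  res2 <- mantel_test(2.5 * geo_irr, geo_irr, n_perm = 199)
  expect_equal(res2$r, 1, tolerance = 1e-12)
  ## only permutations that reproduce the identity can tie r = 1, so p sits
  ## at (or within resampled-identity counts of) its floor 1/(n_perm + 1)
  expect_gte(res2$p, 1 / 200)
  expect_lte(res2$p, 4 / 200)
  ## constant matrix: undefined r, p = 1
  geo4 <- abs(outer(1:4, 1:4, "-"))
  expect_warning(res3 <- mantel_test(matrix(1, 4, 4) - diag(4), geo4))
  expect_equal(res3$p, 1)
  expect_true(is.na(res3$r))
})

test_that("power sweep bookkeeping behaves", {
  ## mtDNA-like regime with haplotype sharing, so neither statistic
  ## degenerates to a constant matrix
  p <- list(tiny = sim_params(deme_size = 5000, mig_prop = 0.002,
                              n_demes = 4, sample_size = 6,
                              mut_rate = 2e-7, locus_length = 500))
  pt <- ibd_power_sweep(p, n_reps = 4, alpha = 1, n_perm = 49, seed = 2)
  expect_s3_class(pt, "data.frame")
  expect_equal(pt$prop_significant, c(1, 1))  # alpha = 1: always significant
  pt0 <- ibd_power_sweep(p, n_reps = 3, alpha = 1e-9, n_perm = 49, seed = 2)
  expect_equal(pt0$prop_significant, c(0, 0))  # p >= 1/(n_perm+1) > alpha
})
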