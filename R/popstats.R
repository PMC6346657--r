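## F-statistic estimators and the Mantel isolation-by-distance test.
##
## Both differentiation estimators are computed for every pair of demes
## (two-population estimates), matching how they feed the Mantel test:
## Phi_ST is the AMOVA fixation index with the number-of-pairwise-
## differences molecular distance, theta is the Weir-Cockerham moment
## estimator treating each distinct haplotype as one allele. Negative
## estimates are retained unclipped (the Mantel correlation is scale-free
## and clipping would bias it toward zero).

#' Pairwise sequence difference matrix
#'
#' Number of differing sites between every pair of sequences; sites missing
#' in either member of a pair are excluded.
#'
#' @param aln a `labeled_alignment`
#' @return an n x n symmetric integer-valued matrix
#' @export
pairwise_diff_matrix <- function(aln) {
  x <- aln$seq
  ok <- !is.na(x)
  sim <- matrix(0, nrow(x), nrow(x))
  for (b in 1:4) {
    ind <- (x == b) & ok
    storage.mode(ind) <- "numeric"
    sim <- sim + tcrossprod(ind)
  }
  okn <- ok
  storage.mode(okn) <- "numeric"
  tcrossprod(okn) - sim
}

## variance components of a two-deme AMOVA from a full distance matrix of
## squared molecular distances
amova_two_pop <- function(d2, grp) {
  n <- tabulate(grp, 2L)
  N <- sum(n)
  ssd_total <- sum(d2) / (2 * N)
  ssd_within <- sum(vapply(1:2, function(g) {
    idx <- grp == g
    sum(d2[idx, idx]) / (2 * n[g])
  }, 0))
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)             # MSD within, df = N - P
  n_c <- N - sum(n^2) / N                     # (N - sum n^2/N)/(P-1), P = 2
  sigma_a <- (ssd_among / 1 - sigma_w) / n_c  # MSD among, df = P - 1 = 1
  c(among = sigma_a, within = sigma_w)
}

#' Pairwise AMOVA Phi_ST matrix
#'
#' For each pair of demes, the two-population AMOVA fixation index
#' Phi_ST = sigma2_among / (sigma2_among + sigma2_within) using the number
#' of pairwise differences between haplotypes as the (squared) molecular
#' distance. Pairs with no molecular variance at all are defined as 0 and
#' flagged in the `"monomorphic"` attribute.
#'
#' @param aln a `labeled_alignment` with >= 2 demes and >= 2 samples per deme
#' @return a symmetric `n_demes x n_demes` matrix (class
#'   `pairwise_fst_matrix`), zero diagonal, `statistic` attribute `"phi_st"`
#' @export
pairwise_phi_st <- function(aln) {
  check_pairwise_input(aln)
  d2 <- pairwise_diff_matrix(aln)
  pairwise_stat_matrix(aln, function(idx, grp) {
    v <- amova_two_pop(d2[idx, idx, drop = FALSE], grp)
    if (sum(v) == 0) NA_real_ else v["among"] / sum(v)
  }, "phi_st")
}

#' Pairwise Weir-Cockerham theta matrix
#'
#' Haploid Weir-Cockerham theta for each pair of demes, treating each
#' distinct haplotype as one allele: per-allele among/within variance
#' components from the one-way analysis of variance on allele indicators,
#' summed over alleles. Monomorphic pairs are defined as 0 and flagged.
#'
#' @inheritParams pairwise_phi_st
#' @return a symmetric matrix as in [pairwise_phi_st()], `statistic`
#'   attribute `"wc_theta"`
#' @export
pairwise_wc_theta <- function(aln) {
  check_pairwise_input(aln)
  hap <- haplotype_index(aln)
  pairwise_stat_matrix(aln, function(idx, grp) {
    wc_theta_two_pop(hap[idx], grp)
  }, "wc_theta")
}

check_pairwise_input <- function(aln) {
  if (aln$n_demes < 2L) stop("need at least 2 demes")
  if (any(tabulate(aln$deme, aln$n_demes) < 2L))
    stop("need at least 2 samples per deme")
}

## integer haplotype id per sequence (exact string identity)
haplotype_index <- function(aln) {
  key <- apply(aln$seq, 1, paste0, collapse = ",")
  match(key, unique(key))
}

pairwise_stat_matrix <- function(aln, pair_fun, statistic) {
  D <- aln$n_demes
  out <- matrix(0, D, D, dimnames = list(aln$deme_names, aln$deme_names))
  mono <- matrix(FALSE, D, D)
  for (a in seq_len(D - 1L)) for (b in (a + 1L):D) {
    idx <- which(aln$deme %in% c(a, b))
    grp <- ifelse(aln$deme[idx] == a, 1L, 2L)
    val <- pair_fun(idx, grp)
    if (is.na(val)) {
      mono[a, b] <- mono[b, a] <- TRUE
      val <- 0
    }
    out[a, b] <- out[b, a] <- val
  }
  structure(out, statistic = statistic, monomorphic = mono,
            class = c("pairwise_fst_matrix", "matrix", "array"))
}

## Weir-Cockerham theta, haploid, two populations, haplotypes as alleles.
## Per-allele one-way ANOVA components: MSA with r-1 = 1 df, MSW with N-r df;
## a = (MSA - MSW)/n_c, b = MSW; theta = sum(a)/sum(a + b). Returns NA for
## a monomorphic pair.
wc_theta_two_pop <- function(hap, grp) {
  n <- tabulate(grp, 2L)
  N <- sum(n)
  alleles <- unique(hap)
  if (length(alleles) < 2L) return(NA_real_)
  n_c <- N - sum(n^2) / N
  A <- 0; B <- 0
  for (u in alleles) {
    p <- c(mean(hap[grp == 1L] == u), mean(hap[grp == 2L] == u))
    pbar <- sum(n * p) / N
    msa <- sum(n * (p - pbar)^2)            # df = 1
    msw <- sum(n * p * (1 - p)) / (N - 2)   # within SS of 0/1 indicator
    A <- A + (msa - msw) / n_c
    B <- B + msw
  }
  if (A + B == 0) return(NA_real_)
  A / (A + B)
}

#' Haplotype diversity
#'
#' Nei's unbiased gene diversity over haplotype frequencies:
#' h = n/(n-1) * (1 - sum p_i^2).
#'
#' @param aln a `labeled_alignment` with >= 2 sequences
#' @return a number in `[0, 1]`
#' @export
haplotype_diversity <- function(aln) {
  n <- nrow(aln$seq)
  stopifnot(n >= 2L)
  p <- tabulate(haplotype_index(aln)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Expected equilibrium F_ST under Wright's island model
#'
#' The classic closed-form anchor F_ST = 1 / (2 * ploidy * Nm + 1), i.e.
#' 1/(4Nm + 1) for the usual autosomal convention: 100 migrants per
#' generation corresponds to F_ST of about 0.002. Set `ploidy = 1` for the
#' strictly haploid variant 1/(2Nm + 1).
#'
#' @param Nm effective number of migrants per generation
#' @param ploidy 2 (default, the convention in which the 100-migrant anchor
#'   is usually quoted) or 1
#' @return expected F_ST
#' @export
fst_expected_island <- function(Nm, ploidy = 2) {
  stopifnot(Nm >= 0, ploidy %in% c(1, 2))
  1 / (2 * ploidy * Nm + 1)
}

#' Mantel test of isolation by distance
#'
#' One-tailed (greater) permutation test of the Pearson correlation between
#' the off-diagonal upper triangles of a genetic and a geographic distance
#' matrix, with simultaneous row/column permutation:
#' p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1).
#'
#' @param gen_mat symmetric genetic-distance (or differentiation) matrix
#' @param geo_mat symmetric geographic-distance matrix of equal dimension
#' @param n_perm number of permutations (default 999)
#' @return a list with elements `r`, `p`, `n_perm` (class `mantel_result`)
#' @export
mantel_test <- function(gen_mat, geo_mat, n_perm = 999L) {
  D <- nrow(gen_mat)
  stopifnot(nrow(geo_mat) == D, ncol(gen_mat) == D, ncol(geo_mat) == D)
  ut <- upper.tri(gen_mat)
  x <- gen_mat[ut]; y <- geo_mat[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(structure(list(r = NA_real_, p = 1, n_perm = as.integer(n_perm)),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(x, y)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(D)
    stats::cor(gen_mat[o, o][ut], y)
  }, 0)
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, one-tailed p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Isolation-by-distance power sweep
#'
#' For each simulation parameter set, the proportion of replicate datasets
#' in which the Mantel test of pairwise differentiation against lattice
#' distance is significant at level `alpha`, for both Phi_ST and
#' Weir-Cockerham theta.
#'
#' @param param_sets a named list of [sim_params()] (default: the full
#'   [parameter_set_table()])
#' @param n_reps replicate datasets per parameter set
#' @param alpha significance level (default 0.05)
#' @param n_perm Mantel permutations (default 999)
#' @param seed base seed; replicate k of set s uses a derived stream
#' @return a data frame (class `power_table`) with columns `param_set`,
#'   `statistic`, `prop_significant`, `n_reps`, `alpha`
#' @export
ibd_power_sweep <- function(param_sets = parameter_set_table(), n_reps = 100L,
                            alpha = 0.05, n_perm = 999L, seed = 1L) {
  stopifnot(n_reps >= 0)
  res <- list()
  for (s in seq_along(param_sets)) {
    ps <- param_sets[[s]]
    sig <- matrix(NA, n_reps, 2, dimnames = list(NULL, c("phi_st", "wc_theta")))
    for (k in seq_len(n_reps)) {
      aln <- simulate_dataset(ps, seed = derive_seed(seed, s, k))
      geo <- abs(outer(aln$lattice, aln$lattice, "-"))
      for (stat in c("phi_st", "wc_theta")) {
        g <- if (stat == "phi_st") pairwise_phi_st(aln) else
          pairwise_wc_theta(aln)
        sig[k, stat] <- mantel_test(g, geo, n_perm = n_perm)$p < alpha
      }
    }
    res[[s]] <- data.frame(
      param_set = names(param_sets)[s] %||% as.character(s),
      statistic = colnames(sig),
      prop_significant = if (n_reps > 0) colMeans(sig) else NA_real_,
      n_reps = as.integer(n_reps), alpha = alpha, row.names = NULL)
  }
  out <- do.call(rbind, res)
  class(out) <- c("power_table", "data.frame")
  out
}
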