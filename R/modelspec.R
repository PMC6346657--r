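## Metapopulation model specifications.
##
## A model_spec maps the original sampling demes onto K analysis demes
## (possibly lumped), assigns each analysis deme's Theta = Ne*mu to a
## shared-parameter group, and assigns each ordered pair of analysis demes
## either to a shared migration-rate (M = m/mu) group or to "no migration"
## (rate fixed at zero). The number of free parameters is the number of
## distinct Theta groups plus the number of distinct migration groups.

#' Construct a metapopulation model specification
#'
#' @param name model name
#' @param deme_map integer vector mapping each original deme to an analysis
#'   deme in `1..K`
#' @param theta_group integer vector of length K assigning each analysis
#'   deme's Theta to a tie group (`1..n_theta_groups`)
#' @param mig_group K x K integer matrix: `mig_group[i, j]` is the tie group
#'   of the backward migration rate from analysis deme i to analysis deme j,
#'   or 0 if that rate is fixed at zero; the diagonal must be 0
#' @return an object of class `model_spec`
#' @export
model_spec <- function(name, deme_map, theta_group, mig_group) {
  deme_map <- as.integer(deme_map)
  K <- max(deme_map)
  stopifnot(length(theta_group) == K, all(diag(mig_group) == 0),
            nrow(mig_group) == K, ncol(mig_group) == K,
            all(sort(unique(deme_map)) == seq_len(K)))
  tg <- as.integer(theta_group)
  stopifnot(all(sort(unique(tg)) == seq_len(max(tg))))
  mg <- matrix(as.integer(mig_group), K, K)
  ng <- max(mg)
  if (K > 1L) {
    stopifnot(ng >= 1L, all(sort(unique(mg[mg > 0L])) == seq_len(ng)))
    if (!connected_graph(mg > 0L))
      stop("nonzero-migration graph must be connected when K > 1")
  }
  structure(list(name = name, deme_map = deme_map, K = K,
                 theta_group = tg, mig_group = mg,
                 n_theta_groups = max(tg), n_mig_groups = ng),
            class = "model_spec")
}

connected_graph <- function(adj) {
  K <- nrow(adj)
  if (K == 1L) return(TRUE)
  seen <- c(1L)
  repeat {
    nb <- which(apply(adj[seen, , drop = FALSE] | t(adj[, seen, drop = FALSE]),
                      2, any))
    new <- setdiff(nb, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == K
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': K = %d analysis demes, %d parameters (%d Theta + %d M)\n",
              x$name, x$K, count_parameters(x), x$n_theta_groups,
              x$n_mig_groups))
  invisible(x)
}

#' Number of free parameters of a model
#'
#' Free Theta groups plus free migration-rate groups.
#'
#' @param model a [model_spec()]
#' @return an integer
#' @export
count_parameters <- function(model) {
  model$n_theta_groups + model$n_mig_groups
}

## connectivity helpers ------------------------------------------------------

## ordered-pair group matrix for a linear stepping-stone over K demes:
## tied = one shared group; free = one group per ordered neighbor pair
stepping_stone_mig <- function(K, tied = TRUE) {
  mg <- matrix(0L, K, K)
  if (K == 1L) return(mg)
  g <- 0L
  for (i in seq_len(K - 1L)) {
    g <- g + 1L; mg[i, i + 1L] <- if (tied) 1L else g
    g <- g + 1L; mg[i + 1L, i] <- if (tied) 1L else g
  }
  mg
}

## all-ordered-pairs (island) connectivity, optionally one group per pair
island_mig <- function(K, tied = TRUE) {
  mg <- matrix(if (tied) 1L else 0L, K, K)
  if (!tied) {
    idx <- which(row(mg) != col(mg))
    mg[idx] <- seq_along(idx)
  }
  diag(mg) <- 0L
  mg
}

#' The seven metapopulation models of the simulation study
#'
#' For `n_demes` demes on a linear lattice (default 10):
#' (a) panmixia; (b) five lumped pairs in a stepping-stone with shared
#' Theta and m/mu; (c) the same with free parameters; (d) an island model
#' over all demes; (e) an island model over the five lumped pairs;
#' (f) a stepping-stone with one shared Theta and one shared m/mu (the
#' generating model of the stepping-stone simulations); (g) a full
#' stepping-stone with a distinct Theta per deme and a distinct rate per
#' ordered neighbor pair.
#'
#' @param n_demes number of original demes (even, for the lumped-pairs
#'   models)
#' @return a named list of 7 [model_spec()] objects
#' @export
build_simulation_models <- function(n_demes = 10L) {
  n_demes <- as.integer(n_demes)
  stopifnot(n_demes >= 2L, n_demes %% 2L == 0L)
  ident <- seq_len(n_demes)
  pairs <- rep(seq_len(n_demes / 2L), each = 2L)
  K5 <- n_demes / 2L
  list(
    panmixia = model_spec("panmixia", rep(1L, n_demes), 1L,
                          matrix(0L, 1, 1)),
    regional_shared = model_spec("regional_shared", pairs, rep(1L, K5),
                                 stepping_stone_mig(K5, tied = TRUE)),
    regional_free = model_spec("regional_free", pairs, seq_len(K5),
                               stepping_stone_mig(K5, tied = FALSE)),
    island = model_spec("island", ident, rep(1L, n_demes),
                        island_mig(n_demes, tied = TRUE)),
    island_regional = model_spec("island_regional", pairs, rep(1L, K5),
                                 island_mig(K5, tied = TRUE)),
    stepping_stone_2p = model_spec("stepping_stone_2p", ident,
                                   rep(1L, n_demes),
                                   stepping_stone_mig(n_demes, tied = TRUE)),
    stepping_stone_full = model_spec("stepping_stone_full", ident,
                                     seq_len(n_demes),
                                     stepping_stone_mig(n_demes, tied = FALSE))
  )
}

#' Archipelago-style model set for empirical data
#'
#' Builds the model set compared for each empirical dataset over `islands`
#' ordered along the archipelago: panmixia; two 2-region models (regions
#' exchange migrants at free rates, each region panmictic with its own
#' Theta); a 3-region "two-currents" model with migration between all three
#' regions; an island model; a two-parameter stepping-stone; a full
#' stepping-stone; and optionally a custom partition.
#'
#' Region boundaries are given as the index of the last island of each
#' region (so `boundary = 5` splits islands 1..5 from 6..n).
#'
#' @param islands character vector of island names, ordered along the chain
#' @param region2a_boundary,region2b_boundary last-island index of the first
#'   region for the two 2-region hypotheses
#' @param region3_boundaries length-2 integer vector for the 3-region model
#' @param custom_partition optional integer vector (one entry per island)
#'   defining an extra empirical-structure model
#' @return a named list of 7 (or 8) [model_spec()] objects
#' @export
build_hawaii_models <- function(islands,
                                region2a_boundary = ceiling(length(islands) / 2),
                                region2b_boundary = region2a_boundary,
                                region3_boundaries = NULL,
                                custom_partition = NULL) {
  n <- length(islands)
  stopifnot(n >= 3L)
  if (is.null(region3_boundaries))
    region3_boundaries <- unique(c(region2a_boundary,
                                   min(region2a_boundary + 2L, n - 1L)))
  check_boundary <- function(b) {
    if (any(b < 1L) || any(b >= n)) stop("boundary not between adjacent islands")
  }
  check_boundary(region2a_boundary); check_boundary(region2b_boundary)
  check_boundary(region3_boundaries)
  region_map <- function(bounds) {
    findInterval(seq_len(n) - 1L, bounds) + 1L
  }
  ident <- seq_len(n)
  m2a <- region_map(region2a_boundary)
  m2b <- region_map(region2b_boundary)
  m3 <- region_map(sort(region3_boundaries))
  out <- list(
    panmixia = model_spec("panmixia", rep(1L, n), 1L, matrix(0L, 1, 1)),
    regional_2_mhi_nwhi = model_spec("regional_2_mhi_nwhi", m2a, 1:2,
                                     island_mig(2L, tied = FALSE)),
    regional_2_current = model_spec("regional_2_current", m2b, 1:2,
                                    island_mig(2L, tied = FALSE)),
    regional_3_two_currents = model_spec("regional_3_two_currents", m3, 1:3,
                                         island_mig(3L, tied = FALSE)),
    island = model_spec("island", ident, rep(1L, n),
                        island_mig(n, tied = TRUE)),
    stepping_stone_2p = model_spec("stepping_stone_2p", ident, rep(1L, n),
                                   stepping_stone_mig(n, tied = TRUE)),
    stepping_stone_full = model_spec("stepping_stone_full", ident, ident,
                                     stepping_stone_mig(n, tied = FALSE))
  )
  if (!is.null(custom_partition)) {
    cp <- as.integer(custom_partition)
    stopifnot(length(cp) == n)
    Kc <- max(cp)
    out$custom <- model_spec("custom", cp, seq_len(Kc),
                             island_mig(Kc, tied = FALSE))
  }
  out
}

#' Windowed exponential priors on Theta and M
#'
#' Exponential priors with the stated means, truncated to the stated
#' windows and renormalized: Theta (= Ne*mu, inheritance scalar 1 for
#' haploid maternally inherited loci) on `[1e-5, 1e-1]` with mean 0.01, and
#' M (= m/mu) on `[1e-4, 1e6]` with mean 1e5.
#'
#' @param theta_lower,theta_upper,theta_mean window and mean for Theta
#' @param M_lower,M_upper,M_mean window and mean for M
#' @return an object of class `coal_priors`
#' @export
coal_priors <- function(theta_lower = 1e-5, theta_upper = 1e-1,
                        theta_mean = 0.01,
                        M_lower = 1e-4, M_upper = 1e6, M_mean = 1e5) {
  stopifnot(theta_lower < theta_mean, theta_mean < theta_upper,
            M_lower < M_mean, M_mean < M_upper)
  structure(list(theta = list(lower = theta_lower, upper = theta_upper,
                              mean = theta_mean),
                 M = list(lower = M_lower, upper = M_upper, mean = M_mean)),
            class = "coal_priors")
}
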