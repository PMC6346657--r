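## Shared fixtures and small oracles used across test files.

## alignment from explicit character sequences
aln_from_strings <- function(seqs, deme, ...) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  labeled_alignment(chars, deme, ...)
}

## a tiny strongly structured dataset used by several sampler tests
make_two_deme_aln <- function(seed = 5, sample_size = 8, deme_size = 5e4,
                              mig_prop = 2e-4) {
  p <- sim_params(deme_size = deme_size, mig_prop = mig_prop, n_demes = 2,
                  sample_size = sample_size)
  simulate_dataset(p, seed = seed)
}

two_deme_model <- function() {
  model_spec("ss2", 1:2, c(1L, 1L), matrix(c(0L, 1L, 1L, 0L), 2, 2))
}

one_deme_model <- function() {
  model_spec("pan", 1L, 1L, matrix(0L, 1, 1))
}

## genealogy-state constructor for hand-built trees (no migration events)
manual_state <- function(time, parent, deme, theta, M = numeric(0),
                         model = one_deme_model()) {
  n_tips <- (length(time) + 1L) / 2L
  coalselect:::new_genealogy_state(
    n_tips, time, as.integer(parent), as.integer(deme),
    rep(list(coalselect:::no_events), length(time)), theta, M, model)
}

## Brute-force pruning oracle: sums over all ancestral state assignments.
## tree: list(parent, time), tip codes 1..4 per site in a matrix.
brute_force_loglik <- function(time, parent, tips, tstv = 9,
                               freqs = rep(0.25, 4)) {
  n_nodes <- length(time)
  n_tips <- nrow(tips)
  internal <- (n_tips + 1L):n_nodes
  eig <- coalselect:::hky_eigen(tstv, freqs)
  Pm <- lapply(seq_len(n_nodes), function(v) {
    if (parent[v] == 0L) return(NULL)
    hky_transition(tstv, freqs, time[parent[v]] - time[v], eig = eig)
  })
  ll <- 0
  for (s in seq_len(ncol(tips))) {
    states <- rep(list(1:4), length(internal))
    tot <- 0
    for (assign in seq_len(4^length(internal))) {
      idx <- assign - 1L
      anc <- integer(n_nodes)
      anc[seq_len(n_tips)] <- tips[, s]
      for (k in seq_along(internal)) {
        anc[internal[k]] <- (idx %% 4L) + 1L
        idx <- idx %/% 4L
      }
      pr <- freqs[anc[which(parent == 0L)]]
      for (v in seq_len(n_nodes)) {
        if (parent[v] == 0L) next
        pr <- pr * Pm[[v]][anc[parent[v]], anc[v]]
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

## exhaustive Mantel oracle over all permutations of a small matrix
mantel_exact <- function(gen_mat, geo_mat) {
  D <- nrow(gen_mat)
  ut <- upper.tri(gen_mat)
  r_obs <- cor(gen_mat[ut], geo_mat[ut])
  perms <- rbind(1:D, NULL)
  allp <- as.matrix(expand.grid(rep(list(1:D), D)))
  allp <- allp[apply(allp, 1, function(x) length(unique(x)) == D), ,
               drop = FALSE]
  r_all <- apply(allp, 1, function(o) cor(gen_mat[o, o][ut], geo_mat[ut]))
  list(r = r_obs, p = mean(r_all >= r_obs - 1e-12))
}
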