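## Structured-coalescent simulation on a one-dimensional lattice.
##
## Time runs backward from sampling (t = 0) in generations. Within deme i,
## each unordered pair of lineages coalesces at rate 1/N_i(t) per
## generation, where N_i(t) = deme_size for t < expansion_time and
## deme_size/expansion_factor earlier (the instantaneous expansion, viewed
## backward, is a contraction). Each lineage migrates to each adjacent
## lattice neighbor at rate mig_prop per generation; edge demes have one
## neighbor. Generations are continuous (exponential waiting times), the
## standard diffusion-limit approximation to a discrete Wright-Fisher
## lattice, adequate at the deme sizes considered here (>= 1e3).

lattice_neighbors <- function(i, n_demes) {
  out <- c(i - 1L, i + 1L)
  out[out >= 1L & out <= n_demes]
}

#' Simulate a structured-coalescent genealogy
#'
#' Generates one realization of the genealogy of `sample_size` haploid
#' samples from each deme under the stepping-stone (or panmictic) scenario
#' in `params`.
#'
#' @param params a [sim_params()] object
#' @return an object of class `genealogy`: vectors `time` (generations
#'   before sampling), `parent` (0 for the root), `deme` (deme index at each
#'   node), with tips `1..n_tips` at time 0
#' @export
simulate_genealogy <- function(params) {
  D <- if (params$panmictic) 1L else params$n_demes
  per_deme <- if (params$panmictic) params$n_demes * params$sample_size else
    params$sample_size
  n_tips <- D * per_deme
  res <- sim_genealogy_cpp(D, per_deme, params$deme_size,
                           params$deme_size / params$expansion_factor,
                           params$expansion_time,
                           if (params$panmictic) 0 else params$mig_prop)
  deme <- res$deme
  if (params$panmictic) {
    ## partition samples into pseudo-demes in blocks of sample_size
    deme[seq_len(n_tips)] <- rep(seq_len(params$n_demes),
                                 each = params$sample_size)
  }
  structure(list(n_tips = n_tips, time = res$time, parent = res$parent,
                 deme = deme, n_demes = params$n_demes),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("genealogy: %d tips, TMRCA = %.4g generations\n",
              x$n_tips, max(x$time)))
  invisible(x)
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' Branch lengths are in generations (or multiply by the mutation rate for
#' substitutions per site).
#'
#' @param gen a [simulate_genealogy()] result
#' @param scale multiplier applied to branch lengths
#' @return an `ape::phylo` object
#' @export
as_phylo <- function(gen, scale = 1) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("as_phylo() requires the ape package")
  n <- gen$n_tips
  n_nodes <- length(gen$time)
  ## phylo convention: tips 1..n, root n+1, internals in preorder-ish ids
  internal <- which(seq_len(n_nodes) > n)
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[internal[order(gen$time[internal], decreasing = TRUE)]] <-
    n + seq_along(internal)
  has_par <- gen$parent != 0L
  edge <- cbind(new_id[gen$parent[has_par]], new_id[which(has_par)])
  len <- (gen$time[gen$parent[has_par]] - gen$time[which(has_par)]) * scale
  o <- order(edge[, 1L], edge[, 2L])
  out <- structure(list(edge = edge[o, , drop = FALSE],
                        edge.length = len[o],
                        tip.label = sprintf("t%d", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(out)
}

#' Simulate sequences along a genealogy under HKY85
#'
#' The root sequence is drawn from the equilibrium base frequencies and each
#' site evolves independently along branches with branch length equal to
#' branch duration (generations) times `mut_rate`.
#'
#' @param gen a [simulate_genealogy()] result
#' @param params the [sim_params()] used to generate it
#' @return a [labeled_alignment()] with one sequence per tip
#' @export
simulate_sequences <- function(gen, params) {
  L <- params$locus_length
  eig <- hky_eigen(params$tstv_ratio, params$base_freqs)
  n_nodes <- length(gen$time)
  seqs <- matrix(0L, n_nodes, L)
  ord <- order(gen$time, decreasing = TRUE)  # root first, tips last
  root <- ord[1L]
  seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = params$base_freqs)
  for (node in ord[-1L]) {
    par <- gen$parent[node]
    bl <- (gen$time[par] - gen$time[node]) * params$mut_rate
    P <- hky_transition(params$tstv_ratio, params$base_freqs, bl, eig = eig)
    ps <- seqs[par, ]
    out <- integer(L)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
    seqs[node, ] <- out
  }
  tip_deme <- gen$deme[seq_len(gen$n_tips)]
  ids <- unlist(lapply(seq_len(gen$n_demes), function(d)
    sprintf("deme%d_ind%d", d, seq_len(sum(tip_deme == d)))))
  labeled_alignment(seqs[seq_len(gen$n_tips), , drop = FALSE],
                    deme = tip_deme, ids = ids,
                    lattice = seq_len(gen$n_demes))
}

#' Simulate one labeled sequence dataset
#'
#' Convenience wrapper: genealogy plus sequences.
#'
#' @inheritParams simulate_genealogy
#' @param seed optional integer seed (set before simulation)
#' @return a `labeled_alignment`
#' @export
simulate_dataset <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_sequences(simulate_genealogy(params), params)
}
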