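#' Simulation parameters for the stepping-stone study
#'
#' Bundles everything needed to simulate one haploid sequence dataset:
#' a one-dimensional lattice of equally sized demes exchanging a fixed
#' proportion of migrants with each adjacent neighbor, an instantaneous
#' order-of-magnitude population expansion `expansion_time` generations
#' before sampling (demes were `deme_size / expansion_factor` before it),
#' and HKY85 sequence evolution.
#'
#' `mig_prop` is the per-generation backward migration probability per
#' adjacent neighbor: a neighboring pair of demes exchanges
#' `deme_size * mig_prop` effective migrants in each direction, so edge
#' demes have total emigration rate `mig_prop` and interior demes
#' `2 * mig_prop`. When `panmictic = TRUE` the dataset is simulated as one
#' population of size `deme_size` and the samples are partitioned into
#' `n_demes` pseudo-demes in blocks of `sample_size` (in sampling order);
#' `mig_prop` is ignored.
#'
#' @param deme_size per-deme (post-expansion) effective population size N_e
#' @param mig_prop per-generation proportion of migrants exchanged with each
#'   adjacent neighbor, in `[0, 1)`
#' @param n_demes number of demes on the lattice
#' @param expansion_factor fold-increase in deme size at the expansion
#' @param expansion_time generations before sampling when the expansion
#'   occurred
#' @param sample_size haploid samples drawn per deme
#' @param locus_length sequence length in bp
#' @param mut_rate per-site per-generation mutation rate
#' @param tstv_ratio HKY kappa (see [hky_rate_matrix()])
#' @param base_freqs equilibrium base frequencies (A, C, G, T)
#' @param panmictic simulate a single unstructured population and partition
#'   samples into pseudo-demes afterwards
#' @param label optional label (e.g. Table row number)
#' @return an object of class `sim_params`
#' @export
sim_params <- function(deme_size, mig_prop = 0, n_demes = 10L,
                       expansion_factor = 10, expansion_time = 1e4,
                       sample_size = 20L, locus_length = 500L,
                       mut_rate = 1e-7, tstv_ratio = 9,
                       base_freqs = rep(0.25, 4),
                       panmictic = FALSE, label = NULL) {
  stopifnot(deme_size > 0, mig_prop >= 0, mig_prop < 1, n_demes >= 1,
            expansion_factor > 0, expansion_time > 0, sample_size >= 1,
            locus_length >= 1, mut_rate >= 0, tstv_ratio > 0,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-12)
  structure(list(
    n_demes = as.integer(n_demes), deme_size = deme_size,
    mig_prop = mig_prop, expansion_factor = expansion_factor,
    expansion_time = expansion_time, sample_size = as.integer(sample_size),
    locus_length = as.integer(locus_length), mut_rate = mut_rate,
    tstv_ratio = tstv_ratio, base_freqs = base_freqs,
    panmictic = isTRUE(panmictic),
    label = label %||% if (isTRUE(panmictic)) "panmixia" else
      sprintf("Ne%g_m%g", deme_size, mig_prop)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params '%s': %d demes x %d samples, %d bp\n",
              x$label, x$n_demes, x$sample_size, x$locus_length))
  if (x$panmictic) {
    cat(sprintf("  panmictic control, Ne = %g\n", x$deme_size))
  } else {
    cat(sprintf("  Ne = %g per deme, m = %g per neighbor (Ne m = %g)\n",
                x$deme_size, x$mig_prop, x$deme_size * x$mig_prop))
  }
  cat(sprintf("  expansion x%g at %g generations BP; mu = %g/site/gen; kappa = %g\n",
              x$expansion_factor, x$expansion_time, x$mut_rate, x$tstv_ratio))
  invisible(x)
}

#' The ten simulation parameter sets of the validation study
#'
#' Nine stepping-stone combinations of per-deme effective size
#' N_e in \{1e4, 1e5, 1e6\} and migrant proportion m such that the effective
#' number of migrants N_e m is 10, 100 or 1000, plus a panmictic control
#' simulated as a single population of N_e = 1e6 subdivided into 10
#' pseudo-demes. All other settings are the shared defaults of
#' [sim_params()].
#'
#' @return a named list of 10 `sim_params` objects (`set1` ... `set9`,
#'   `panmixia`)
#' @export
parameter_set_table <- function() {
  ne  <- c(1e4, 1e5, 1e6, 1e4, 1e5, 1e6, 1e4, 1e5, 1e6)
  nem <- c(10, 10, 10, 100, 100, 100, 1000, 1000, 1000)
  sets <- lapply(seq_along(ne), function(i)
    sim_params(deme_size = ne[i], mig_prop = nem[i] / ne[i],
               label = sprintf("set%d", i)))
  names(sets) <- sprintf("set%d", seq_along(ne))
  sets$panmixia <- sim_params(deme_size = 1e6, panmictic = TRUE,
                              label = "panmixia")
  sets
}
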