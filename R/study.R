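## End-to-end drivers: the simulation validation study and the
## empirical-style analysis of an arbitrary FASTA + deme-map dataset.
## Every run writes tidy TSV tables plus a JSON manifest from which all
## outputs are re-derivable (seed, explicit config, package version).

study_manifest <- function(out_dir, seed, config, extra = list()) {
  manifest <- c(list(
    package = "coalselect",
    version = as.character(utils::packageVersion("coalselect")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulation validation study
#'
#' For each requested parameter set: simulates `n_reps` replicate datasets,
#' runs the isolation-by-distance power sweep over them, and (for
#' `n_evidence_reps` > 0) estimates the marginal likelihood of the seven
#' metapopulation models on the first replicates, recording per-replicate
#' relative probabilities and winners. Per-replicate evidence rows are
#' checkpointed to `evidence/` as they complete, and finished replicates
#' are skipped on restart.
#'
#' @param out_dir output directory (created if needed)
#' @param param_sets named list of [sim_params()] (default the full
#'   [parameter_set_table()])
#' @param n_reps replicates per set for the power sweep
#' @param n_evidence_reps replicates per set entered into model selection
#'   (0 disables the coalescent stage)
#' @param sample_size_evidence per-deme sample size used for the coalescent
#'   stage (the power sweep always uses each set's own sample size)
#' @param alpha,n_perm Mantel test settings
#' @param priors,config sampler settings for the evidence stage
#' @param seed base seed
#' @return invisibly, a list with the power table and the evidence table
#' @export
run_simulation_study <- function(out_dir, param_sets = parameter_set_table(),
                                 n_reps = 100L, n_evidence_reps = 0L,
                                 sample_size_evidence = 5L,
                                 alpha = 0.05, n_perm = 999L,
                                 priors = coal_priors(),
                                 config = mcmc_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study_manifest(out_dir, seed, config,
                 list(mode = "sim-study", n_reps = n_reps,
                      n_evidence_reps = n_evidence_reps,
                      alpha = alpha, n_perm = n_perm,
                      param_sets = lapply(param_sets, unclass)))

  power <- if (n_reps > 0) {
    pt <- ibd_power_sweep(param_sets, n_reps = n_reps, alpha = alpha,
                          n_perm = n_perm, seed = seed)
    write_tsv(pt, file.path(out_dir, "power_table.tsv"))
    pt
  } else {
    write_tsv(data.frame(param_set = character(), statistic = character(),
                         prop_significant = numeric(), n_reps = integer(),
                         alpha = numeric()),
              file.path(out_dir, "power_table.tsv"))
    NULL
  }

  ev_rows <- list()
  if (n_evidence_reps > 0) {
    ck_dir <- file.path(out_dir, "evidence")
    dir.create(ck_dir, showWarnings = FALSE)
    for (s in seq_along(param_sets)) {
      ps <- param_sets[[s]]
      set_name <- names(param_sets)[s]
      models <- build_simulation_models(ps$n_demes)
      for (k in seq_len(n_evidence_reps)) {
        ck <- file.path(ck_dir, sprintf("%s_rep%d.tsv", set_name, k))
        if (file.exists(ck)) {  # restart support
          ev_rows[[ck]] <- utils::read.table(ck, header = TRUE, sep = "\t")
          next
        }
        ps_k <- ps
        ps_k$sample_size <- as.integer(sample_size_evidence)
        aln <- simulate_dataset(ps_k, seed = derive_seed(seed, 100L + s, k))
        lml <- vapply(models, function(mod)
          path_sampling_ml(run_mc3(aln, mod, priors, config,
                                   seed = derive_seed(seed, 200L + s, k)))$log_ml,
          0)
        rp <- relative_probabilities(lml)
        row <- data.frame(param_set = set_name, replicate = k,
                          model = names(lml), log_ml = unname(lml),
                          rel_prob = unname(rp),
                          winner = names(lml)[which.max(lml)],
                          row.names = NULL)
        write_tsv(row, ck)
        ev_rows[[ck]] <- row
      }
    }
    write_tsv(do.call(rbind, ev_rows), file.path(out_dir, "evidence_table.tsv"))
  }
  invisible(list(power = power,
                 evidence = if (length(ev_rows)) do.call(rbind, ev_rows)))
}

#' Empirical-style analysis of a FASTA + deme-map dataset
#'
#' Reads an alignment with its sample-to-deme map, builds an
#' archipelago-style model set over the observed demes (or uses a supplied
#' one), runs replicate marginal-likelihood estimates per model, and writes
#' the evidence table, the selection result, and sampler diagnostics. With
#' a covariate table (TSV: columns `island` plus `area_km2` and/or
#' `census`), the posterior-draw slope test is run for the best model when
#' it has per-deme Theta parameters.
#'
#' @param fasta,deme_tsv input files (see [read_alignment()])
#' @param out_dir output directory
#' @param models optional named list of [model_spec()]; default
#'   [build_hawaii_models()] over the observed demes (requires >= 3 demes;
#'   with one deme only panmixia is estimable and a model list must be
#'   supplied)
#' @param n_estimates replicate marginal-likelihood estimates per model
#' @param covariate_tsv optional island covariate table
#' @param priors,config sampler settings
#' @param seed base seed
#' @return invisibly, a list with the evidence table, `selection_result`,
#'   and diagnostics
#' @export
run_empirical <- function(fasta, deme_tsv, out_dir, models = NULL,
                          n_estimates = 3L, covariate_tsv = NULL,
                          priors = coal_priors(), config = mcmc_config(),
                          seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(fasta, deme_tsv)
  if (min(tabulate(aln$deme, aln$n_demes)) < 2L)
    stop("need >= 2 samples per deme")
  if (is.null(models)) {
    if (aln$n_demes < 3L)
      stop("need >= 3 demes for the default model set (with ",
           aln$n_demes, " deme(s) only panmixia is estimable; pass `models`)")
    models <- build_hawaii_models(aln$deme_names)
  }
  study_manifest(out_dir, seed, config,
                 list(mode = "empirical", fasta = fasta, deme_tsv = deme_tsv,
                      n_estimates = n_estimates,
                      models = vapply(models, function(m) m$name, "")))

  evidence <- vector("list", length(models))
  for (i in seq_along(models)) {
    evidence[[i]] <- model_evidence(aln, models[[i]], priors, config,
                                    n_estimates = n_estimates,
                                    seed = derive_seed(seed, i))
  }
  ev_tab <- do.call(rbind, lapply(evidence, function(e)
    data.frame(model = e$model, replicate = seq_along(e$log_ml),
               log_ml = e$log_ml, mean_log_ml = e$mean_log_ml,
               n_params = e$n_params, row.names = NULL)))
  write_tsv(ev_tab, file.path(out_dir, "evidence_table.tsv"))

  sel <- select_model(evidence)
  best_fit <- evidence[[match(sel$best, vapply(evidence, `[[`, "", "model"))]]$last_fit
  diag_tab <- summary(best_fit)$params
  write_tsv(diag_tab, file.path(out_dir, "diagnostics.tsv"))
  jsonlite::write_json(
    list(best = sel$best, second = sel$second, p = sel$p,
         ambiguous = sel$ambiguous,
         probabilities = as.list(sel$probabilities)),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  slope <- NULL
  if (!is.null(covariate_tsv)) {
    cov <- utils::read.table(covariate_tsv, header = TRUE, sep = "\t")
    best_model <- models[[match(sel$best, vapply(models, `[[`, "", "name"))]]
    if (best_model$n_theta_groups >= 3L) {
      samp <- posterior_samples(best_fit)
      isl <- aln$deme_names[match(seq_len(best_model$n_theta_groups),
                                  best_model$theta_group[best_model$deme_map])]
      cov <- cov[match(isl, cov$island), ]
      cov_col <- intersect(c("area_km2", "census"), names(cov))[1L]
      theta_post <- lapply(seq_len(best_model$n_theta_groups), function(g)
        samp[[sprintf("theta.%d", g)]])
      slope <- posterior_slope_test(theta_post, cov[[cov_col]])
      jsonlite::write_json(unclass(slope), file.path(out_dir, "slope_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(list(evidence = ev_tab, selection = sel, diagnostics = diag_tab,
                 slope = slope))
}
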