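# End-to-end orchestration: cohort -> preprocess -> search -> evaluate, and
# the prediction-horizon sweep.

#' Preprocess a split episode set
#'
#' GP-imputes every window (fallback means from the training split),
#' z-scores with statistics learned on the training split, trains the
#' denoising autoencoder on the training split and applies it to all splits.
#'
#' @param es a split `nasga_episodes` with possible `NA` entries.
#' @param gconfig a [gpr_config()].
#' @param dconfig a [dae_config()]; `NULL` skips denoising.
#' @return list: `episodes` (complete, normalized, denoised), `normalizer`,
#'   `dae`.
#' @export
preprocess_episodes <- function(es, gconfig = gpr_config(),
                                dconfig = dae_config()) {
  train_idx <- which(es$split == "train")
  means <- apply(es$x[train_idx, , , drop = FALSE], 3,
                 function(m) mean(m, na.rm = TRUE))
  means[!is.finite(means)] <- 0
  names(means) <- es$features
  es <- impute_episodes(es, gconfig, feature_means = means)
  norm <- fit_normalizer(es[train_idx])
  es <- apply_normalizer(es, norm)
  dae <- NULL
  if (!is.null(dconfig)) {
    dae <- train_dae(es[train_idx], dconfig)
    es <- denoise(es, dae)
  }
  list(episodes = es, normalizer = norm, dae = dae)
}

#' Run the full pipeline on one cohort at one horizon
#'
#' @param cohort a `nasga_cohort_data` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param horizon prediction horizon T in hours.
#' @param ga a [ga_config()].
#' @param tconfig a [train_config()] for child training during search.
#' @param N node count per cell.
#' @param seed master seed (forks cohort/preprocess/search streams).
#' @param dconfig a [dae_config()] or `NULL`.
#' @param baseline also train the gated-recurrent baseline (default FALSE).
#' @param replicates bootstrap replicates for CIs.
#' @return list: `eval` (searched-model test metrics), `baseline` (or NULL),
#'   `search` (best chromosome + stats), `episodes`.
#' @export
run_pipeline <- function(cohort, horizon, ga, tconfig, N, seed = 1,
                         dconfig = dae_config(seed = fork_seed(seed, "dae")),
                         baseline = FALSE, replicates = 500) {
  built <- build_cohort(cohort, horizon, seed = fork_seed(seed, "cohort"))
  prep <- preprocess_episodes(built$episodes, dconfig = dconfig)
  es <- prep$episodes
  ga$seed <- fork_seed(seed, "search")
  res <- run_search(es, ga, tconfig, N)
  final <- materialize_model(res$best, res$store, tconfig,
                             seed = fork_seed(seed, "final"))
  ev <- evaluate_model(final, es, replicates = replicates,
                       seed = fork_seed(seed, "boot"))
  bl <- NULL
  if (baseline) {
    btc <- tconfig
    btc$seed <- fork_seed(seed, "baseline")
    bl <- baseline_recurrent(es, btc, replicates = replicates,
                             seed = fork_seed(seed, "bootbl"))
  }
  list(eval = ev, baseline = bl, search = res, episodes = es,
       model = final)
}

#' Prediction-horizon sweep
#'
#' Re-runs cohorting, preprocessing, search and evaluation per horizon on the
#' same underlying cohort. On synthetic data with a decaying precursor
#' signal, AUROC is expected to fall (qualitatively) as the horizon grows.
#'
#' @param cohort a `nasga_cohort_data`.
#' @param horizons integer vector of horizons in \[0, 12\].
#' @param ga,tconfig,N,seed,dconfig,replicates as in [run_pipeline()].
#' @return data.frame: horizon, auroc, ci_lower, ci_upper, sensitivity,
#'   specificity, n_test.
#' @export
horizon_sweep <- function(cohort, horizons, ga, tconfig, N, seed = 1,
                          dconfig = dae_config(seed = fork_seed(seed, "dae")),
                          replicates = 500) {
  rows <- lapply(horizons, function(Th) {
    res <- tryCatch(
      run_pipeline(cohort, Th, ga, tconfig, N,
                   seed = fork_seed(seed, paste0("sweep", Th)),
                   dconfig = dconfig, replicates = replicates),
      error = function(e) stop_config("horizon %d: %s", Th, conditionMessage(e)))
    data.frame(horizon = Th, auroc = res$eval$auroc$auroc,
               ci_lower = res$eval$auroc$ci_lower,
               ci_upper = res$eval$auroc$ci_upper,
               sensitivity = res$eval$sensitivity,
               specificity = res$eval$specificity,
               n_test = sum(res$episodes$split == "test"))
  })
  do.call(rbind, rows)
}
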