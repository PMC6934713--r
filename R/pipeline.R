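#' Run the full analysis pipeline on a synthetic cohort
#'
#' One-call driver chaining every stage: cohort simulation, cleaning
#' (imputation, Haar denoising, trimming, variance QC), feature extraction,
#' stratified cross-validation of the pose-wise random-forest ensemble, and
#' interpretation (full-data MDI ranking, fold consistency, effect sizes on
#' the top features, boundary-distance correlations with the covariates).
#' Every random quantity derives from \code{seed}, so a rerun with the same
#' arguments reproduces the report exactly.
#'
#' @param sim_config A \code{\link{simulation_config}}; its
#'   \code{rng_seed} is overridden by \code{seed}.
#' @param seed Master seed for the run.
#' @param k Cross-validation folds (default 5).
#' @param cleaning A \code{\link{cleaning_config}}.
#' @param features A \code{\link{feature_config}}.
#' @param params A \code{\link{forest_params}} template.
#' @param top_k Importance list length (default 20).
#' @param xy_only If \code{TRUE}, drop all z-axis joint channels before
#'   feature extraction (84 features instead of 124).
#' @param balance_n If non-\code{NULL}, subsample the ASD group to this
#'   size before evaluation (balanced differential experiment).
#' @return List of class \code{"movement_report"}: \code{cv}
#'   (\code{movement_cv}), \code{qc} (\code{qc_report}), \code{ranking}
#'   (full-data \code{\link{total_mdi}}), \code{fold_overlap},
#'   \code{effect_sizes} (top-k features), \code{correlations} (per
#'   covariate), \code{features} (the \code{movement_features} used),
#'   \code{manifest}, and the configs.
#' @export
run_pipeline <- function(sim_config = simulation_config(), seed = 1L,
                         k = 5, cleaning = cleaning_config(),
                         features = feature_config(),
                         params = forest_params(), top_k = 20,
                         xy_only = FALSE, balance_n = NULL) {
  sim_config$rng_seed <- as.integer(seed)
  ds <- simulate_dataset(sim_config)
  cl <- clean_dataset(ds$recordings, cleaning)
  recs <- cl$recordings
  if (xy_only) recs <- project_xy(recs)
  fx <- featurize_dataset(recs, participants = ds$cohort, config = features)
  if (!is.null(balance_n)) fx <- balance_groups(fx, balance_n, seed)
  cv <- run_cv(fx, k = k, seed = seed, params = params, top_k = top_k)
  full_params <- params
  full_params$rng_seed <- .hash_seed(seed, "full-model")
  full_model <- movement_ensemble(fx, full_params)
  ranking <- total_mdi(full_model)
  overlap <- fold_consistency(cv, ranking, top_k)
  eff <- effect_size_report(fx, top_features(ranking, top_k))
  pr <- cv$predictions
  covs <- fx$participants[match(pr$participant_id,
                                fx$participants$participant_id), ]
  cor_rows <- lapply(c("age_years", "bot2_percentile", "srs2_score",
                       "rbsr_score", "latent_severity"), function(v)
    cbind(covariate = v,
          correlate_distance(pr$boundary_distance, covs[[v]])))
  correlations <- do.call(rbind, cor_rows)
  structure(list(cv = cv, qc = cl$qc, ranking = ranking,
                 fold_overlap = overlap, effect_sizes = eff,
                 correlations = correlations, features = fx,
                 model = full_model, manifest = ds$manifest,
                 sim_config = sim_config, seed = seed),
            class = "movement_report")
}

#' @export
print.movement_report <- function(x, ...) {
  cat(sprintf("<movement_report> seed %d: %d participants, %d recordings simulated\n",
              x$seed, nrow(x$features$participants), nrow(x$manifest)))
  print(x$qc)
  print(x$cv)
  cat(sprintf("Top-20 fold overlap: %.2f\n", x$fold_overlap))
  cat("Top features:\n")
  print(utils::head(x$ranking, 5), row.names = FALSE)
  cat("Boundary-distance correlations (Pearson):\n")
  print(x$correlations[, c("covariate", "pearson_r", "pearson_p", "n")],
        row.names = FALSE)
  invisible(x)
}
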