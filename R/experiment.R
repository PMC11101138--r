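# Config-driven orchestration: simulate -> preprocess -> stratified CV ->
# train the chosen variants per fold -> evaluate -> aggregate.

#' Experiment configuration
#'
#' Bundles everything needed to reproduce one full synthetic experiment. The
#' test scale (16-cube volumes, 196 stimulations, 3 folds, latent n = 64) is
#' sized so the full five-variant matrix runs on one CPU in minutes; the full
#' scale mirrors a complete mapping session (64-cube, ~1200 stimulations,
#' 10 folds, latent n = 512).
#'
#' @param scale `"test"` or `"full"`.
#' @param variants variants to run (letters or names).
#' @param phantom a [phantom_config()].
#' @param training a [training_config()].
#' @param k_folds number of cross-validation folds.
#' @param latent_dim latent length n.
#' @param seed master seed: data generation, fold assignment and per-fold
#'   weight initialization all derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("test", "full"),
                              variants = c("a", "b", "c", "d", "e"),
                              phantom = NULL, training = NULL,
                              k_folds = NULL, latent_dim = NULL,
                              seed = 1L) {
  scale <- match.arg(scale)
  seed <- as.integer(seed)
  phantom <- phantom %||% phantom_config(scale, seed = seed)
  k_folds <- k_folds %||% if (scale == "full") 10L else 3L
  latent_dim <- latent_dim %||% if (scale == "full") 512L else 64L
  training <- training %||% if (scale == "full") training_config(seed = seed)
    else training_config(max_epochs = 50L, seed = seed)
  structure(list(scale = scale,
                 variants = vapply(variants, model_variant, character(1)),
                 phantom = phantom, training = training,
                 k_folds = as.integer(k_folds),
                 latent_dim = as.integer(latent_dim), seed = seed),
            class = "experiment_config")
}

#' Run a cross-validated model-comparison experiment
#'
#' Generates (or takes) a phantom dataset, preprocesses it, builds
#' intensity-stratified folds, then for every fold x variant trains a fresh
#' model (weights cleared and re-initialized each round, both stages
#' retrained) on the fold's training set and evaluates it on the fold's test
#' set. Also evaluates the mean-training-volume baseline on every fold.
#'
#' @param config an [experiment_config()].
#' @param dataset optional pre-generated raw [stim_dataset()]; by default one
#'   is generated from `config$phantom`.
#' @return An object of class `mepfield_experiment`: per-stimulation
#'   `records`, the variant-level `report`, the intensity-stratified report
#'   for the Direct Variational model (when run), the fold definitions and
#'   full provenance.
#' @export
run_experiment <- function(config = experiment_config(), dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dataset <- dataset %||% generate_dataset(config$phantom)
  prep <- preprocess_dataset(dataset)
  ds <- prep$dataset
  folds <- stratified_kfold(ds, config$k_folds, seed = config$seed)
  records <- list()
  for (v in config$variants) {
    for (f in folds) {
      train <- subset_by_id(ds, f$train_ids)
      test <- subset_by_id(ds, f$test_ids)
      ctrl <- config$training
      # fresh initialization each CV round, deterministic per (seed, fold, variant)
      ctrl$seed <- config$seed + 1009L * f$fold_id +
        101L * match(v, config$variants)
      fit <- mepfield_fit(train, v, config$latent_dim, ctrl)
      pred <- predict(fit, test, type = "matrix")
      records[[length(records) + 1L]] <-
        evaluate_records(pred, test, fold = f$fold_id, model = v)
    }
  }
  for (f in folds) {
    train <- subset_by_id(ds, f$train_ids)
    test <- subset_by_id(ds, f$test_ids)
    base <- baseline_mean_volume(train$X, nrow(test$X))
    records[[length(records) + 1L]] <-
      evaluate_records(base, test, fold = f$fold_id, model = "baseline_mean")
  }
  records <- do.call(rbind, records)
  model_rows <- records$model %in% config$variants
  report <- aggregate_metrics(records[model_rows, ], "model")
  by_intensity <- if ("direct_variational" %in% config$variants)
    stratify_by_intensity(
      records[records$model == "direct_variational", ]) else NULL
  structure(list(records = records, report = report,
                 by_intensity = by_intensity, folds = folds,
                 config = config,
                 n_records = nrow(ds$X), removed = ds$removed,
                 scaling = prep$scaling),
            class = "mepfield_experiment")
}

#' @export
print.mepfield_experiment <- function(x, ...) {
  cat(sprintf("<mepfield_experiment> %s scale: %d stimulations after preprocessing (removed %d zero-MEP, %d low-field), %d folds\n",
              x$config$scale, x$n_records, x$removed["zero_mep"],
              x$removed["low_efield"], x$config$k_folds))
  rep <- x$report
  for (v in unique(rep$model)) {
    nr <- rep[rep$model == v & rep$metric == "nrmse", ]
    r2 <- rep[rep$model == v & rep$metric == "r2", ]
    cat(sprintf("  %-22s NRMSE %.3f +/- %.3f   R2 %.3f +/- %.3f\n",
                v, nr$mean, nr$sem_95, r2$mean, r2$sem_95))
  }
  base <- x$records[x$records$model == "baseline_mean", ]
  if (nrow(base))
    cat(sprintf("  %-22s NRMSE %.3f (mean-volume null model)\n",
                "baseline_mean", mean(base$nrmse, na.rm = TRUE)))
  invisible(x)
}
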