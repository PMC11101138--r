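#' Fit an inverse MEP-to-E-field model
#'
#' Trains one of the five model variants on a preprocessed stimulation
#' dataset, running the applicable regime: the two-stage variants (a, c, d)
#' first learn an E-field latent space by (variational) autoencoding, freeze
#' the decoder, then train the MEP mapper against it; the single-stage
#' variants (b, e) train the whole reverse path at once.
#'
#' @param dataset a preprocessed [stim_dataset()] (see
#'   [preprocess_dataset()]).
#' @param variant model variant, letter `"a"`..`"e"` or full name (default
#'   the Direct Variational model, the best-performing variant).
#' @param latent_dim latent length n for the variational paths.
#' @param control a [training_config()].
#' @return An object of class `mepfield`, with methods for `predict`,
#'   `print`, `summary`, `coef`, `plot`, `residuals` and `simulate`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(phantom_config("test", shape = 8, n_jitter = 0))
#' prep <- preprocess_dataset(ds)
#' fit <- mepfield_fit(prep$dataset, variant = "e",
#'                     control = training_config(max_epochs = 3))
#' vol <- predict(fit, prep$dataset$meps[1, ])[[1]]
#' }
#' @export
mepfield_fit <- function(dataset, variant = "direct_variational",
                         latent_dim = 64L, control = training_config()) {
  stopifnot(inherits(dataset, "stim_dataset"))
  variant <- model_variant(variant)
  bundle <- assemble_model(variant, dataset$dim[1], ncol(dataset$meps),
                           latent_dim, seed = control$seed)
  traces <- list()
  if (variant %in% two_stage_variants) {
    res <- train_forward_stage(bundle, dataset, control)
    bundle <- res$bundle
    traces$forward <- res$trace
  }
  res <- train_reverse_stage(bundle, dataset, control)
  bundle <- res$bundle
  traces$reverse <- res$trace
  structure(list(bundle = bundle, variant = variant, traces = traces,
                 dim = dataset$dim, voxel_size = dataset$voxel_size,
                 mask = dataset$mask, muscles = dataset$muscles,
                 scaling = dataset$scaling, control = control,
                 n_train = nrow(dataset$X), call = match.call()),
            class = "mepfield")
}

#' Reconstruct E-field volumes from MEP vectors
#'
#' Runs the trained inference (reverse) path. Variational variants use the
#' posterior mean by default (deterministic); `sampling = TRUE` draws from
#' the posterior, optionally averaging `n_samples` draws. Outputs are
#' multiplied by the cortical mask, so they are exactly zero outside it and
#' in \[0, 1\] inside.
#'
#' @param object a fitted `mepfield` model.
#' @param newdata scaled MEP input: a numeric vector, an N x m matrix, or a
#'   [stim_dataset()].
#' @param type `"volume"` for a list of [efield_volume()]s, `"matrix"` for an
#'   N x V matrix.
#' @param sampling draw z from the posterior instead of using its mean.
#' @param n_samples number of posterior draws to average when sampling.
#' @param ... unused.
#' @return Reconstructions in the scaled \[0, 1\] field range.
#' @export
predict.mepfield <- function(object, newdata, type = c("volume", "matrix"),
                             sampling = FALSE, n_samples = 1L, ...) {
  type <- match.arg(type)
  meps <- if (inherits(newdata, "stim_dataset")) newdata$meps else newdata
  if (is.null(dim(meps))) meps <- matrix(as.numeric(meps), nrow = 1L)
  if (ncol(meps) != object$bundle$m)
    stop_mf("MEP input has %d muscles; model expects %d", ncol(meps),
            object$bundle$m)
  pred <- predict_bundle(object$bundle, meps, object$mask, sampling, n_samples)
  if (type == "matrix") return(pred)
  lapply(seq_len(nrow(pred)), function(i)
    efield_volume(array(pred[i, ], object$dim), object$voxel_size,
                  scaled = TRUE))
}

#' @export
print.mepfield <- function(x, ...) {
  cat(sprintf("Inverse MEP-to-E-field model: %s (variant %s)\n",
              x$variant, variant_letter(x$variant)))
  cat(sprintf("  trained on %d stimulations, %s volume, m = %d muscles\n",
              x$n_train, paste(x$dim, collapse = "x"), x$bundle$m))
  for (nm in names(x$traces)) {
    tr <- x$traces[[nm]]
    cat(sprintf("  %s stage: %d epochs, final loss %.5g\n",
                nm, nrow(tr), tr$loss[nrow(tr)]))
  }
  invisible(x)
}

#' @export
summary.mepfield <- function(object, ...) {
  counts <- vapply(object$bundle$components, component_param_count, numeric(1))
  out <- list(variant = object$variant, params = counts,
              frozen = object$bundle$frozen,
              latent_dim = object$bundle$latent_dim,
              traces = lapply(object$traces, function(tr)
                tr[nrow(tr), c("epoch", "loss", "mse", "kl", "l1", "lr")]))
  class(out) <- "summary.mepfield"
  out
}

#' @export
print.summary.mepfield <- function(x, ...) {
  cat(sprintf("Variant: %s | latent n = %d\n", x$variant, x$latent_dim))
  cat("Parameters:\n")
  for (nm in names(x$params))
    cat(sprintf("  %-8s %8d%s\n", nm, x$params[[nm]],
                if (nm %in% x$frozen) " [frozen]" else ""))
  for (nm in names(x$traces)) {
    tr <- x$traces[[nm]]
    cat(sprintf("%s stage: stopped at epoch %d, loss %.5g (mse %.5g, kl %.5g, l1 %.5g), lr %.3g\n",
                nm, tr$epoch, tr$loss, tr$mse, tr$kl, tr$l1, tr$lr))
  }
  invisible(x)
}

#' @export
coef.mepfield <- function(object, component = NULL, ...) {
  comps <- object$bundle$components
  if (!is.null(component)) comps <- comps[component]
  lapply(comps, function(c) lapply(component_layers(c), function(l) l$params))
}

#' @export
plot.mepfield <- function(x, stage = names(x$traces), ...) {
  op <- graphics::par(mfrow = c(1, length(stage)))
  on.exit(graphics::par(op))
  for (nm in stage) {
    tr <- x$traces[[nm]]
    graphics::plot(tr$epoch, tr$loss, type = "l", log = "y",
                   xlab = "epoch", ylab = "training loss",
                   main = sprintf("%s stage (%s)", nm, x$variant), ...)
  }
  invisible(x)
}

#' @export
residuals.mepfield <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "stim_dataset"))
  pred <- predict(object, dataset, type = "matrix")
  sqrt(rowSums((pred - dataset$X)^2))
}

#' Posterior reconstruction draws
#'
#' For the variational variants, draws `nsim` reconstructions of each MEP
#' vector by sampling z from the learned posterior; deterministic variants
#' return the single point reconstruction repeated.
#'
#' @param object a fitted `mepfield` model.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param newdata MEP input as in [predict.mepfield()].
#' @param ... unused.
#' @return List of length `nsim` of N x V reconstruction matrices.
#' @export
simulate.mepfield <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  variational <- object$bundle$components$mapper$kind == "var"
  with_seed(seed, lapply(seq_len(nsim), function(i)
    predict(object, newdata, type = "matrix", sampling = variational)))
}
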