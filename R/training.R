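# Optimization schedule and the two training regimes.

#' Training configuration
#'
#' Mini-batch Adadelta with a plateau-driven learning-rate decay and
#' relative-improvement early stopping: starting from learning rate 1, five
#' consecutive epochs without a relative training-loss improvement of at
#' least `min_improvement` multiply the learning rate by `plateau_factor`;
#' twenty such epochs stop training.
#'
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param rho,eps Adadelta accumulator decay and stabilizer.
#' @param plateau_patience epochs of stall before a learning-rate drop.
#' @param plateau_factor multiplicative learning-rate decay.
#' @param stop_patience epochs of stall before stopping.
#' @param min_improvement minimum relative loss improvement that counts.
#' @param max_epochs hard cap on epochs (the stopping rule is primary).
#' @param l1_weight sparsity penalty weight on the reconstruction.
#' @param kl_weight weight of the KL term relative to the reconstruction MSE.
#'   The default `NULL` scales it as `(L/64)^3` for volume side L: because the
#'   MSE is a per-sample sum over voxels, its magnitude grows with the volume,
#'   and this default keeps the per-voxel MSE:KL balance of the full-scale
#'   (64-cube) objective — where the weight is exactly 1, the equations as
#'   written — at any reduced problem size.
#' @param seed integer seed for weight init, batch shuffling and sampling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 8L, lr = 1, rho = 0.95, eps = 1e-6,
                            plateau_patience = 5L, plateau_factor = 0.7,
                            stop_patience = 20L, min_improvement = 1e-5,
                            max_epochs = 500L, l1_weight = 1e-4,
                            kl_weight = NULL, seed = 1L) {
  stopifnot(batch_size >= 1, lr > 0, plateau_patience > 0, stop_patience > 0,
            plateau_factor > 0, plateau_factor < 1, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr, rho = rho,
                 eps = eps, plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 stop_patience = as.integer(stop_patience),
                 min_improvement = min_improvement,
                 max_epochs = as.integer(max_epochs),
                 l1_weight = l1_weight, kl_weight = kl_weight,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Learning-rate schedule state
#'
#' @param lr initial learning rate.
#' @param min_improvement relative improvement threshold.
#' @param plateau_patience,plateau_factor,stop_patience schedule constants.
#' @return A schedule state list.
#' @export
schedule_state <- function(lr = 1, min_improvement = 1e-5,
                           plateau_patience = 5L, plateau_factor = 0.7,
                           stop_patience = 20L) {
  list(lr = lr, best = Inf, plateau = 0L, stall = 0L, stop = FALSE,
       min_improvement = min_improvement,
       plateau_patience = as.integer(plateau_patience),
       plateau_factor = plateau_factor,
       stop_patience = as.integer(stop_patience))
}

#' Step the plateau learning-rate schedule
#'
#' Pure function of (state, loss): an epoch improves when the loss beats the
#' best so far by a relative factor of at least `min_improvement`; otherwise
#' the plateau and stall counters advance. After `plateau_patience` stalled
#' epochs the learning rate is multiplied by `plateau_factor` and the plateau
#' counter resets; after `stop_patience` stalled epochs `state$stop` is TRUE.
#'
#' @param state a [schedule_state()].
#' @param epoch_loss this epoch's training loss.
#' @return The updated state.
#' @export
lr_schedule_step <- function(state, epoch_loss) {
  improved <- !is.finite(state$best) ||
    (state$best - epoch_loss) >= state$min_improvement * abs(state$best)
  if (improved) {
    state$best <- epoch_loss
    state$plateau <- 0L
    state$stall <- 0L
  } else {
    state$plateau <- state$plateau + 1L
    state$stall <- state$stall + 1L
    if (state$plateau >= state$plateau_patience) {
      state$lr <- state$lr * state$plateau_factor
      state$plateau <- 0L
    }
  }
  state$stop <- state$stall >= state$stop_patience
  state
}

#' Early-stopping check
#'
#' TRUE exactly when the epoch's loss completes `stop_patience` consecutive
#' epochs without a relative improvement of `min_improvement`.
#'
#' @inheritParams lr_schedule_step
#' @return Logical.
#' @export
early_stop_check <- function(state, epoch_loss)
  lr_schedule_step(state, epoch_loss)$stop

# ---------------------------------------------------------------------------

stage_plan <- function(variant, stage) {
  # trainable components and the objective per (variant, stage)
  if (stage == "forward") {
    switch(variant,
      ae_decoder = list(train = c("encoder", "decoder"), kl = FALSE),
      vae_decoder = ,
      vae_sampler_decoder = list(train = c("encoder", "sampler", "decoder"),
                                 kl = TRUE),
      stop_mf("variant '%s' has no forward (autoencoding) stage", variant))
  } else {
    switch(variant,
      ae_decoder = ,
      vae_decoder = list(train = "mapper", kl = FALSE),
      direct_conv = list(train = c("mapper", "decoder"), kl = FALSE),
      vae_sampler_decoder = list(train = c("mapper", "sampler"), kl = TRUE),
      direct_variational = list(train = c("mapper", "sampler", "decoder"),
                                kl = TRUE))
  }
}

trainable_layers <- function(bundle, comps)
  unlist(lapply(comps, function(nm)
    component_layers(bundle$components[[nm]])), recursive = FALSE)

batch_gt <- function(X, ids) matrix(t(X[ids, , drop = FALSE]), ncol = 1L)

# One training stage over a preprocessed dataset. X: N x V scaled fields,
# Y: N x m scaled MEPs. Returns list(bundle, trace).
train_stage_run <- function(bundle, X, Y, stage, config) {
  plan <- stage_plan(bundle$variant, stage)
  beta <- config$kl_weight %||% (bundle$input_side / 64)^3
  layers <- trainable_layers(bundle, plan$train)
  frozen_layers <- trainable_layers(
    bundle, setdiff(names(bundle$components), plan$train))
  n <- nrow(X)
  sched <- schedule_state(config$lr, config$min_improvement,
                          config$plateau_patience, config$plateau_factor,
                          config$stop_patience)
  trace <- vector("list", config$max_epochs)
  stage_seed <- (config$seed %% 1000000L) * 2L + (stage == "reverse")
  with_seed(stage_seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tot <- msum <- ksum <- lsum <- 0
      for (st in seq(1L, n, by = config$batch_size)) {
        ids <- ord[st:min(st + config$batch_size - 1L, n)]
        B <- length(ids)
        gt <- batch_gt(X, ids)
        y <- Y[ids, , drop = FALSE]
        out <- if (stage == "forward")
          net_forward_autoenc(bundle, gt, B, training = TRUE, sampling = TRUE)
        else
          net_forward_reverse(bundle, y, B, training = TRUE, sampling = TRUE)
        diff <- out$pred - gt
        mse <- sum(diff^2) / B
        kl <- if (plan$kl) beta * kl_gaussian(out$mu, out$logvar) else 0
        # l1 activity penalty kept on the per-sample scale of the MSE term
        l1 <- config$l1_weight * sum(abs(out$pred)) / B
        dpred <- 2 * diff / B + config$l1_weight * sign(out$pred) / B
        dmu <- if (plan$kl) beta * out$mu / B else NULL
        dlv <- if (plan$kl) beta * 0.5 * (exp(out$logvar) - 1) / B else NULL
        if (stage == "forward")
          net_backward_autoenc(bundle, dpred, dmu, dlv, B)
        else
          net_backward_reverse(bundle, dpred, dmu, dlv, B)
        for (l in layers)
          adadelta_step(l, sched$lr, config$rho, config$eps)
        tot <- tot + (mse + kl + l1) * B
        msum <- msum + mse * B
        ksum <- ksum + kl * B
        lsum <- lsum + l1 * B
      }
      epoch_loss <- tot / n
      trace[[epoch]] <- data.frame(
        epoch = epoch, loss = epoch_loss, mse = msum / n, kl = ksum / n,
        l1 = lsum / n, lr = sched$lr,
        frozen_sum = layers_checksum(frozen_layers)[["sum"]])
      sched <- lr_schedule_step(sched, epoch_loss)
      if (sched$stop) break
    }
  })
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  class(trace) <- c("training_trace", class(trace))
  list(bundle = bundle, trace = trace)
}

#' Train the autoencoding (forward) stage
#'
#' Trains encoder(+sampler)+decoder to reconstruct the masked, scaled
#' E-fields: plain MSE (+ l1) for the AE variant, MSE + KL (+ l1) for the
#' VAE variants. Afterwards the decoder (and, in the VAE variants, the
#' encoder) is frozen: its weights are never updated again.
#'
#' @param bundle a `network_bundle` for a two-stage variant (a, c, d).
#' @param dataset a preprocessed [stim_dataset()].
#' @param config a [training_config()].
#' @return List with the updated `bundle` and the epoch `trace`.
#' @export
train_forward_stage <- function(bundle, dataset, config = training_config()) {
  stopifnot(inherits(bundle, "network_bundle"), inherits(dataset, "stim_dataset"))
  if (!bundle$variant %in% two_stage_variants)
    stop_mf("variant '%s' is single-stage: it has no forward stage",
            bundle$variant)
  check_training_inputs(bundle, dataset)
  res <- train_stage_run(bundle, dataset$X, dataset$meps, "forward", config)
  res$bundle$frozen <- union(res$bundle$frozen, c("encoder", "decoder"))
  res$bundle$trained <- union(res$bundle$trained, "forward")
  res$bundle$decoder_checksum <- component_checksum(res$bundle, "decoder")
  res
}

#' Train the MEP-mapping (reverse) stage
#'
#' Trains the mapper (+sampler) against the decoder. For the two-stage
#' variants the decoder must have been trained and frozen by
#' [train_forward_stage()]; gradients flow through it but its weights do not
#' move. For the single-stage variants (b, e) the decoder trains jointly
#' here. Objectives: MSE (+ l1) for a, b, c; MSE + KL (+ l1) with the
#' MEP-conditioned posterior for d and e. The mapper is frozen afterwards.
#'
#' @inheritParams train_forward_stage
#' @return List with the updated `bundle` and the epoch `trace`.
#' @export
train_reverse_stage <- function(bundle, dataset, config = training_config()) {
  stopifnot(inherits(bundle, "network_bundle"), inherits(dataset, "stim_dataset"))
  if (bundle$variant %in% two_stage_variants &&
      !("decoder" %in% bundle$frozen))
    stop_mf("variant '%s' needs a trained, frozen decoder before the reverse stage",
            bundle$variant)
  check_training_inputs(bundle, dataset)
  res <- train_stage_run(bundle, dataset$X, dataset$meps, "reverse", config)
  res$bundle$frozen <- union(res$bundle$frozen, "mapper")
  res$bundle$trained <- union(res$bundle$trained, "reverse")
  res
}

check_training_inputs <- function(bundle, dataset) {
  if (!dataset$efield_scaled || !dataset$mep_scaled)
    stop_mf("dataset must be preprocessed (scaled) before training")
  if (dataset$dim[1] != bundle$input_side)
    stop_mf("dataset volumes are %d^3 but the bundle expects %d^3",
            dataset$dim[1], bundle$input_side)
  if (ncol(dataset$meps) != bundle$m)
    stop_mf("dataset has %d muscles but the bundle expects m = %d",
            ncol(dataset$meps), bundle$m)
}

# Reverse-path prediction for a matrix of scaled MEP vectors. Returns an
# N x V matrix of masked reconstructions in [0, 1].
predict_bundle <- function(bundle, meps, mask = NULL, sampling = FALSE,
                           n_samples = 1L) {
  if (is.null(dim(meps))) meps <- matrix(meps, nrow = 1L)
  B <- nrow(meps)
  one_pass <- function() {
    out <- net_forward_reverse(bundle, meps, B, training = FALSE,
                               sampling = sampling)
    t(matrix(out$pred, ncol = B)) # sample-major rows -> one row per sample
  }
  pred <- if (sampling && n_samples > 1L) {
    Reduce(`+`, lapply(seq_len(n_samples), function(i) one_pass())) / n_samples
  } else one_pass()
  if (!is.null(mask))
    pred <- sweep(pred, 2L, as.numeric(mask$grid), "*")
  pred
}
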