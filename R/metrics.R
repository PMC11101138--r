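# Reconstruction metrics: NRMSE (primary), R-squared (secondary) and
# centre-of-gravity error (tertiary).

as_grid <- function(x) {
  if (inherits(x, "efield_volume")) as.numeric(x$grid) else as.numeric(x)
}

#' Normalized root mean square error
#'
#' `sqrt(||pred - gt||_2^2 / ||gt||_2^2)`: zero iff the volumes are equal, 1
#' when predicting all zeros, and invariant to a common rescaling of both
#' volumes. The squared form (the plain ratio of squared norms) is available
#' with `squared = TRUE`.
#'
#' @param pred,gt volumes ([efield_volume()] or arrays) of the same shape.
#' @param squared return the ratio of squared norms instead of its root.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(pred, gt, squared = FALSE) {
  p <- as_grid(pred)
  g <- as_grid(gt)
  if (length(p) != length(g))
    stop_mf("shape mismatch: %d vs %d voxels", length(p), length(g))
  den <- sum(g^2)
  if (den == 0)
    stop_mf("NRMSE undefined: ground-truth volume is all zero")
  r <- sum((p - g)^2) / den
  if (squared) r else sqrt(r)
}

#' Reconstruction R-squared within the cortical mask
#'
#' `1 - sum_k (gt_k - pred_k)^2 / sum_k (gt_k - mean(gt))^2` over the voxels
#' k inside the mask, with the mean taken over the same voxels. 1 for a
#' perfect reconstruction, 0 for predicting the mask mean everywhere.
#'
#' @param pred,gt volumes of the same shape.
#' @param mask a [cortex_mask()] restricting the voxel set K.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(pred, gt, mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  p <- as_grid(pred)
  g <- as_grid(gt)
  k <- which(mask$grid != 0)
  if (length(k) == 0) stop_mf("empty mask")
  gk <- g[k]
  den <- sum((gk - mean(gk))^2)
  if (den == 0)
    stop_mf("R-squared undefined: ground truth constant within the mask")
  1 - sum((gk - p[k])^2) / den
}

#' Centre of gravity of a masked volume
#'
#' Intensity-weighted mean voxel coordinate over the mask, in 0-based voxel
#' units with axis order (x, y, z); multiply by the voxel size for mm.
#'
#' @param volume an [efield_volume()] or 3D array.
#' @param mask optional [cortex_mask()]; defaults to all voxels.
#' @return Numeric 3-vector.
#' @export
center_of_gravity <- function(volume, mask = NULL) {
  g <- if (inherits(volume, "efield_volume")) volume$grid else volume
  d <- dim(g)
  k <- if (is.null(mask)) seq_len(prod(d)) else which(mask$grid != 0)
  v <- as.numeric(g)[k]
  tot <- sum(v)
  if (tot <= 0)
    stop_mf("centre of gravity undefined: zero total intensity in the mask")
  xyz <- arrayInd(k, d) - 1 # 0-based voxel coordinates
  as.numeric(crossprod(xyz, v) / tot)
}

#' Centre-of-gravity error
#'
#' Euclidean distance between the CoGs of the ground-truth and reconstructed
#' volumes, in voxel units (multiply by voxel size for mm). Symmetric in its
#' arguments.
#'
#' @param gt,pred volumes of the same shape.
#' @param mask optional [cortex_mask()].
#' @return Nonnegative scalar.
#' @export
cog_error <- function(gt, pred, mask = NULL) {
  sqrt(sum((center_of_gravity(gt, mask) - center_of_gravity(pred, mask))^2))
}

#' Per-stimulation evaluation records
#'
#' Computes NRMSE, R-squared and CoG error for each reconstruction against
#' its ground truth, together with the stratifiers used in the analyses:
#' stimulation intensity, scaled MEP mean and variance, and the number of
#' active (nonzero) muscles. Records whose metric is undefined (all-zero
#' ground truth, constant ground truth in the mask, or zero-intensity CoG)
#' are flagged via NA so aggregation can exclude them.
#'
#' @param pred N x V matrix of reconstructions (e.g. from
#'   `predict(fit, ..., type = "matrix")`).
#' @param dataset the [stim_dataset()] holding the matching ground truths.
#' @param fold optional fold label attached to every record.
#' @param model optional model label attached to every record.
#' @return A data.frame with one row per stimulation.
#' @export
evaluate_records <- function(pred, dataset, fold = NA_integer_,
                             model = NA_character_) {
  stopifnot(inherits(dataset, "stim_dataset"), is.matrix(pred),
            nrow(pred) == nrow(dataset$X))
  mask <- dataset$mask
  k <- which(mask$grid != 0)
  d <- dataset$dim
  out <- lapply(seq_len(nrow(pred)), function(i) {
    g <- dataset$X[i, ]
    p <- pred[i, ]
    nr <- tryCatch(nrmse(p, g), error = function(e) NA_real_)
    r2 <- tryCatch(r_squared(array(p, d), array(g, d), mask),
                   error = function(e) NA_real_)
    cg <- tryCatch(center_of_gravity(array(g, d), mask),
                   error = function(e) rep(NA_real_, 3))
    cp <- tryCatch(center_of_gravity(array(p, d), mask),
                   error = function(e) rep(NA_real_, 3))
    ce <- if (anyNA(c(cg, cp))) NA_real_ else sqrt(sum((cg - cp)^2))
    data.frame(id = dataset$coil$id[i], model = model, fold = fold,
               nrmse = nr, r2 = r2,
               cog_gt_x = cg[1], cog_gt_y = cg[2], cog_gt_z = cg[3],
               cog_pred_x = cp[1], cog_pred_y = cp[2], cog_pred_z = cp[3],
               cog_error = ce,
               intensity_pct_rmt = dataset$coil$intensity_pct_rmt[i],
               mep_mean = mean(dataset$meps[i, ]),
               mep_variance = stats::var(dataset$meps[i, ]),
               n_active = sum(dataset$meps[i, ] > 0))
  })
  do.call(rbind, out)
}

#' Mean-training-volume baseline
#'
#' The natural null model for the inverse task: predict the voxelwise mean of
#' the training volumes for every test stimulation. Any useful inverse model
#' must beat its NRMSE.
#'
#' @param train_X N x V matrix of training volumes.
#' @param n_test number of test predictions to emit.
#' @return An `n_test` x V matrix repeating the mean volume.
#' @export
baseline_mean_volume <- function(train_X, n_test) {
  mu <- colMeans(train_X)
  matrix(mu, n_test, length(mu), byrow = TRUE)
}
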