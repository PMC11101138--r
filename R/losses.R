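# Training objectives: reconstruction MSE, closed-form Gaussian KL, and the
# sparsity penalty on the reconstructed volume.

infer_n_samples <- function(x) {
  if (is.list(x)) return(length(x))
  d <- dim(x)
  if (!is.null(d) && length(d) == 4L) d[4] else 1L
}

as_numeric_stack <- function(x) {
  if (is.list(x))
    return(unlist(lapply(x, function(v)
      as.numeric(if (inherits(v, "efield_volume")) v$grid else v)),
      use.names = FALSE))
  as.numeric(x)
}

#' Mean squared reconstruction error
#'
#' Per-sample sum of squared voxel differences, averaged over the N samples
#' in the batch: `(1/N) sum_i ||pred_i - gt_i||_2^2`. Note the normalization
#' is per sample, not per voxel, which sets the scale of the MSE term
#' relative to the KL term.
#'
#' @param pred,gt matching volumes: 3D arrays (N = 1), 4D arrays with the
#'   sample index last, or lists of volumes/arrays.
#' @return Nonnegative scalar, zero iff `pred == gt`.
#' @export
mse_loss <- function(pred, gt) {
  n <- infer_n_samples(pred)
  if (n != infer_n_samples(gt))
    stop_mf("batch sizes differ: %d vs %d", n, infer_n_samples(gt))
  p <- as_numeric_stack(pred)
  g <- as_numeric_stack(gt)
  if (length(p) != length(g))
    stop_mf("shape mismatch: %d vs %d values", length(p), length(g))
  sum((p - g)^2) / n
}

#' Closed-form Gaussian KL divergence
#'
#' `KL[N(mu, diag(exp(logvar))) || N(0, I)] =
#' 0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)`. For a matrix (one row per
#' sample) the per-sample divergences are averaged over the batch, matching
#' the 1/N of [mse_loss()]. Nonnegative; zero iff `mu = 0, logvar = 0`.
#'
#' @param mu,logvar numeric vectors, or matrices with one sample per row.
#' @return Scalar KL divergence (batch mean).
#' @export
kl_gaussian <- function(mu, logvar) {
  if (!identical(dim(mu) %||% length(mu), dim(logvar) %||% length(logvar)))
    stop_mf("mu and logvar shapes differ")
  per <- exp(logvar) + mu^2 - 1 - logvar
  if (is.matrix(mu)) mean(rowSums(per)) / 2 else sum(per) / 2
}

#' Sparsity penalty
#'
#' `weight * sum(abs(x))`, applied as activity regularization on the
#' reconstructed volume: masking makes the target volumes sparse, so an l1
#' penalty on the output is appropriate.
#'
#' @param x numeric array (typically the decoder output before masking).
#' @param weight penalty weight.
#' @return Nonnegative scalar.
#' @export
l1_penalty <- function(x, weight = 1e-4) {
  if (weight < 0) stop_mf("`weight` must be nonnegative")
  weight * sum(abs(as_numeric_stack(x)))
}

loss_report <- function(mse, kl = 0, l1 = 0) {
  structure(list(total = mse + kl + l1, mse_term = mse, kl_term = kl,
                 l1_term = l1), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> total %.6g = mse %.6g + kl %.6g + l1 %.6g\n",
              x$total, x$mse_term, x$kl_term, x$l1_term))
  invisible(x)
}

#' Variational training objectives
#'
#' `loss_l2()` is the autoencoding objective of the VAE variants:
#' reconstruction MSE plus the KL divergence of the E-field-conditioned
#' posterior from the standard-normal prior. `loss_l3()` is arithmetically
#' identical but the posterior is conditioned on the MEP vector (the
#' single-stage Direct Variational objective and the reverse-stage objective
#' of the VAE-Sampler-Decoder). Both accept an optional precomputed l1 term.
#'
#' @param pred,gt volumes as in [mse_loss()].
#' @param mu,logvar posterior parameters as in [kl_gaussian()].
#' @param l1 optional sparsity term to include in the total.
#' @return A `loss_report` with `total = mse + kl + l1`.
#' @export
loss_l2 <- function(pred, gt, mu, logvar, l1 = 0)
  loss_report(mse_loss(pred, gt), kl_gaussian(mu, logvar), l1)

#' @rdname loss_l2
#' @export
loss_l3 <- function(pred, gt, mu, logvar, l1 = 0)
  loss_report(mse_loss(pred, gt), kl_gaussian(mu, logvar), l1)
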