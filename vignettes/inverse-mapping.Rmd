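---
title: "Reconstructing TMS-induced cortical E-fields from multi-muscle MEPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing TMS-induced cortical E-fields from multi-muscle MEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inverse problem

Transcranial magnetic stimulation (TMS) over the motor cortex evokes motor
evoked potentials (MEPs) in peripheral muscles. The forward direction — from
the induced cortical electric field to the muscle response — is causal: the
field `X` (a 64x64x64, 1 mm^3 voxel grid, nonzero only inside the primary
motor cortex mask) selectively recruits corticomotor neurons, producing an
m = 15 vector `y` of peak-to-peak MEP amplitudes. `mepfield` addresses the
inverse imaging task: given only `y`, estimate the field volume `X` that
produced it.

The model family assumes a latent cortico-motor code `z` (length n) linking
the two domains. Writing the decoder as `P(X | z)` and a surrogate posterior
`Q(z | .)`, the package implements five 3D-convolutional architectures:

* **ae_decoder (a)** — a plain convolutional autoencoder learns `z` from the
  fields; a convolutional mapper then learns `z` from `y` against the frozen
  decoder.
* **direct_conv (b)** — the same mapper plus decoder trained jointly from
  `y` to `X` in a single stage, no autoencoding.
* **vae_decoder (c)** — a variational autoencoder (KL-regularized posterior
  `Q(z|X)`) learns the latent space; a fully connected deterministic mapper
  is then fit to the frozen decoder.
* **vae_sampler_decoder (d)** — as (c), but the reverse stage maps `y` to a
  posterior `Q(z|y)`, reloads the variational sampling layer learned on the
  forward path and retrains it.
* **direct_variational (e)** — the single-stage variational model: mapper,
  sampler and decoder jointly minimize reconstruction error plus
  `KL[Q(z|y) || N(0, I)]`. This is the variant that performs best, and the
  package default.

Objectives: the reconstruction term is the batch mean of per-sample squared
norms, `(1/N) sum_i ||Xhat_i - X_i||^2`; the variational variants add the
closed-form diagonal-Gaussian KL divergence (`kl_gaussian()`), and every
objective adds an l1 activity penalty (weight `1e-4`) on the reconstructed
volume, appropriate because the masked targets are ~95-98% zeros.

## Preprocessing

`preprocess_dataset()` applies, in order:

1. **Zero-MEP removal** — stimulations whose MEP vector is identically zero
   are dropped (they sit in the null space of the cortico-motor map).
2. **Low-field outlier removal** — stimulations whose maximum masked field
   intensity is strictly below 10 mV/m are dropped. The filter runs on raw
   V/m fields (the threshold is physical), before any scaling; a record at
   exactly 10 mV/m is retained (literal reading of the strict inequality).
3. **Global E-field min-max scaling** — one divisor for the whole dataset:
   the maximum masked voxel over all stimulations becomes 1; voxels outside
   the cortical mask become exactly 0.
4. **Per-muscle MEP min-max scaling** — each muscle divided by its own
   dataset-wide maximum. A muscle that is never active would have an
   undefined divisor; its channel is mapped to zeros with a warning rather
   than dropped, keeping the network input width m fixed.

Scaling constants are computed on the full dataset (matching how a
subject-level analysis scales "the entire set of stimulations") and stored in
a `scaling_params` object so the transform is invertible and reusable.

## Training regime

Mini-batches of 8; Adadelta with initial learning rate 1. Adadelta's original
description (Zeiler 2012) sets the stabilizer at `eps = 1e-6`, which we adopt
(`rho = 0.95`); on CPU-scale problems the smaller `1e-7` warms up the
accumulators too slowly. If the training loss fails to improve by a relative
`1e-5` for 5 consecutive epochs, the learning rate is multiplied by 0.7;
after 20 such epochs training stops. The same relative-improvement criterion
defines both the plateau and the stop, and the monitored quantity is the
training loss. A `max_epochs` cap (500 by default) is a safety net only.

Two-stage variants (a, c, d) train the autoencoding path first; the decoder
(and encoder) is then frozen — its parameters are bit-identical through the
reverse stage, which the package audits with parameter checksums at every
epoch. Single-stage variants (b, e) train mapper(+sampler)+decoder jointly.
Each cross-validation round re-initializes all weights (Glorot-uniform,
seeded) and retrains both stages.

### Numerical choices

* **KL weight across problem sizes.** Because the reconstruction term is a
  per-sample *sum* over voxels, its magnitude scales with the volume: at the
  full 64-cube it is ~64x larger than at the 16-cube test scale. With an
  unweighted KL the reduced-scale objective therefore sits in a different
  regime — the KL dominates and the information-optimal solution is posterior
  collapse (the model reproduces the mean volume and ignores the MEPs; we
  observed exactly this). `training_config()` consequently defaults the KL
  weight to `(L/64)^3`: exactly 1 — the objective as written — at full scale,
  and the same per-voxel MSE:KL balance at any smaller scale. The weight is
  exposed (`kl_weight`) for experimentation.
* **Saturation of the bounded ReLU.** The decoder output activation
  `min(1, max(0, x))` keeps reconstructions in the scaled field range, but
  with ~95% of target voxels equal to zero the exact subgradient makes the
  all-zero output an absorbing state (all units saturate at 0 and gradients
  vanish). The backward pass therefore propagates a small slope (0.01)
  through the saturated zones, in the spirit of a leaky ReLU; the forward map
  is unchanged, so the \[0, 1\] output contract holds exactly.
* **Initialization.** Glorot-uniform weights with per-run seeds; biases start
  at 0.01 so the ReLU chain is active at initialization (with zero biases the
  initial output is identically zero and no gradient flows). The logvar heads
  start at -4 so the posterior begins nearly deterministic (`z ~ mu`) and
  widens only as the KL term demands — a standard stabilization against early
  posterior collapse.
* **l1 penalty scale.** The activity penalty is accumulated per sample and
  divided by the batch size, keeping its scale relative to the MSE term
  independent of `batch_size`.
* **Inference.** Variational mappers use the posterior mean by default
  (deterministic inference); Monte-Carlo averaging over posterior draws is
  available via `predict(..., sampling = TRUE, n_samples = s)`. Predicted
  volumes are multiplied by the cortical mask, so they are exactly zero
  outside it.
* **Latent width.** The latent length n is not dictated by the architecture;
  defaults are n = 512 at full scale and n = 64 at test scale, with the
  mapper's hidden fully connected width at 256.

## The synthetic phantom

No subject data ships with the package, so `generate_dataset()` builds a
phantom with the statistical structure the pipeline expects:

* a **curved motor-strip ribbon mask** (single connected component; ~2% of
  the 64-cube at full scale, 5% of the 16-cube at test scale, where the
  coarser lattice needs a larger fraction to stay connected);
* a **7x7 stimulation grid** (10 mm spacing, 60x60 mm) centred on the ribbon
  hotspot, plus `n_jitter` random in-extent stimulations per intensity, at
  110/120/130/140 %RMT — test scale uses the 49 grid vertices per intensity
  (196 records), full scale adds 251 jittered points per intensity (~1200
  records, mirroring a dense mapping session);
* a **smooth focal field**: Gaussian kernel (sigma 8 mm) around the mask
  voxel nearest the coil projection, amplitude growing quadratically with
  %RMT, attenuated with coil-to-cortex distance (sigma 10 mm) and modulated
  by the angle between coil orientation and the local ribbon tangent. Field
  maxima span roughly 1-200 mV/m, deliberately straddling the 10 mV/m outlier
  cutoff so the filter is exercised. A coil beyond 28 mm of the mask yields
  an all-zero field (fringe stimulation);
* **overlapping muscle representations**: 15 normalized Gaussian blobs
  (sigma 6 mm) spread along the ribbon, so central stimulations co-activate
  many muscles while fringe stimulations activate few or none;
* a **saturating recruitment map**: each muscle responds through a logistic
  in its integrated drive `<w_k, E>` with per-muscle gain (300-3000 uV),
  threshold (10-40 mV/m) and slope 8 mV/m, additive Gaussian noise
  (sd 15 uV), floored and rectified so weak drives give exact zeros. The MEP
  noise level is a free knob with no claimed fidelity — no quantitative noise
  model is available for the real recordings.

What the phantom does *not* emulate: anatomically real BA4 geometry,
physically accurate coil fields (no magnetic dipole model), EMG cross-talk,
inter-subject variability. Tests passing on the phantom demonstrate that the
pipeline's mechanics and the qualitative structure of the results carry over,
not that real-subject accuracy would match.

With the default seeds, the phantom reproduces the qualitative regularities
the real data shows: MEP mean and variance increase with stimulation
intensity, a handful of stimulations are silent (zero MEP everywhere), and
reconstruction error concentrates where muscle activation is sparse and weak.

## Evaluation

Per stimulation, `evaluate_records()` computes:

* **NRMSE** `sqrt(||Xhat - X||^2 / ||X||^2)` — the primary metric. The
  printed form of the metric is the ratio of squared norms; the name and the
  magnitudes reported with it indicate the square root, which we implement as
  primary with the squared form behind `nrmse(..., squared = TRUE)`.
* **R^2** within the mask K: `1 - sum_K (X - Xhat)^2 / sum_K (X - mean_K X)^2`,
  with both sums and the mean restricted to mask voxels.
* **CoG error**: Euclidean distance between intensity-weighted centres of
  gravity, computed in 0-based voxel coordinates, axis order (x, y, z);
  multiply by the voxel size for mm.

Undefined metrics (all-zero ground truth, constant field in the mask, zero
total intensity) flag the record with `NA` rather than failing; aggregation
excludes them. `aggregate_metrics()` averages within cross-validation folds
first, then reports the mean and `1.96 * sd / sqrt(n_folds)` (the 95% SEM
half-width) across fold means; per-stimulation pooling is available by
treating each record as its own fold. "Active muscle" means a scaled MEP
strictly greater than zero — the generator produces exact zeros; for real
data an epsilon threshold would be substituted.

## Problem sizes

The shipped defaults are sized for a single CPU. The test-scale experiment
(`experiment_config("test")`) uses 16-cube volumes, 196 stimulations, 3
folds, latent n = 64 and a 50-epoch cap: one variant trains in a few minutes.
The full-scale configuration (64-cube, ~1200 stimulations, 10 folds, n = 512,
the 500-epoch cap with early stopping) reproduces the complete design and is
intended for long runs. The acceptance script and the test suite use the
test scale with reduced epoch budgets chosen so the whole pipeline — data
generation, preprocessing, cross-validated training of the variant pairs, and
evaluation — completes in minutes while still demonstrating skill over the
mean-volume baseline.

## Known limitations

* The optimizer follows the reference regime (Adadelta, lr 1, plateau decay);
  on small CPU-scale problems it underfits relative to what an adaptive
  first-order method tuned for the task would reach. Comparisons between
  variants remain meaningful because all variants share the regime.
* Reduced-scale experiments are noisy: with ~150 records, per-fold metrics
  vary across seeds, which is why replicate comparisons (e vs a) are assessed
  over several seeds.
* The phantom's recruitment parameters are plausible rather than fitted to
  any recording; absolute NRMSE/R^2 values on the phantom are not comparable
  to values on real subject data.
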