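# mepfield

Inverse mapping of TMS-induced cortical E-fields from multi-muscle MEPs.

## The problem

Transcranial magnetic stimulation (TMS) over the primary motor cortex evokes
motor evoked potentials (MEPs) in peripheral muscles. The causal chain runs
from the induced cortical electric field **X** (a 64×64×64 voxel intensity
volume, nonzero only inside the motor-cortex mask) to the observed muscle
response **y** (a vector of peak-to-peak amplitudes from m = 15 hand and
forearm muscles). `mepfield` solves the *inverse imaging* problem: given only
the MEP vector, reconstruct the E-field volume that produced it — i.e.
estimate *where and how strongly* the cortex was stimulated from the muscle
response alone. This is useful for motor mapping, presurgical evaluation and
the study of overlapping cortical muscle representations.

The package is written for computational neuroscientists: it implements five
3D convolutional network variants linking X and y through a latent
cortico-motor code **z** (length n),

```
forward  (two-stage variants):  X → z → X̂     (autoencoding, decoder frozen)
reverse  (all variants):        y → z → X̂     (mapper + decoder, inference path)
```

* `ae_decoder` (a) and `direct_conv` (b): purely convolutional, trained with
  the reconstruction loss `L1 = (1/N) Σᵢ ‖X̂ᵢ − X̃ᵢ‖²`;
* `vae_decoder` (c) and `vae_sampler_decoder` (d): variational autoencoder
  forward path with `L2 = MSE + KL[Q(z|X) ‖ N(0, I)]`, where
  `KL = ½ Σ (exp(logσ²) + μ² − 1 − logσ²)`;
* `direct_variational` (e): single-stage with `L3 = MSE + KL[Q(z|y) ‖ N(0, I)]`
  — the best-performing variant and the package default.

All objectives add an ℓ1 activity penalty (10⁻⁴) on the reconstruction.
Training uses mini-batches of 8, Adadelta (lr 1) with a ×0.7 plateau decay
and 20-epoch relative-improvement early stopping. Evaluation uses NRMSE
`√(‖X̂−X̃‖²/‖X̃‖²)` (primary), R² within the cortical mask (secondary) and the
centre-of-gravity error in voxels (tertiary), aggregated as mean ± 95% SEM
across stratified cross-validation folds.

Because the subject recordings behind the original study are not deposited,
the package ships a synthetic motor-strip phantom (`generate_dataset()`) with
the same statistical structure: a ~2%-of-volume curved cortical ribbon, a
7×7 cm stimulation grid at four intensities (110–140 %RMT), smooth focal
fields, and a saturating noisy recruitment map producing rich activation at
the map centre and sparse/zero activation at the fringes.

## Worked example

```r
library(mepfield)

# a small phantom mapping session: 16³ volumes, 49-point grid × 4 intensities
cfg  <- phantom_config("test", seed = 1)
raw  <- generate_dataset(cfg)
prep <- preprocess_dataset(raw)   # zero-MEP filter, <10 mV/m filter, min-max scaling
d    <- prep$dataset
d
#> <stim_dataset> 152 stimulations, 16x16x16 volume @ 4 mm, 15 muscles
#>   intensities: 110, 120, 130, 140 %RMT
#>   E-fields scaled, MEPs scaled

folds <- stratified_kfold(d, k = 3, seed = 1)
train <- subset_by_id(d, folds[[1]]$train_ids)
test  <- subset_by_id(d, folds[[1]]$test_ids)

fit <- mepfield_fit(train, variant = "direct_variational",
                    control = training_config(max_epochs = 200, seed = 11))

pred <- predict(fit, test, type = "matrix")
rec  <- evaluate_records(pred, test, fold = 0, model = "e")
median(rec$nrmse)   # 0.584  — reconstruction error of the best variant
mean(rec$r2)        # 0.476  — fidelity within the cortical mask
mean(rec$cog_error) # 0.68   — centre-of-gravity shift, voxels

# the null model every useful inverse map must beat
base <- evaluate_records(baseline_mean_volume(train$X, nrow(test$X)),
                         test, fold = 0, model = "baseline")
median(base$nrmse)  # 0.886
```

The reconstruction halves the error of the mean-volume baseline; records with
many active muscles reconstruct best, while sparse or silent responses sit
near the null space of the cortico-motor map and reconstruct poorly — the
same qualitative pattern seen on real recordings.

The full five-variant comparison over stratified folds is one call:

```r
res <- run_experiment(experiment_config("test", variants = c("a","b","c","d","e")))
res            # per-variant NRMSE / R² table, mean ± 95% SEM across folds
compare_variants(res$report)$ranking
```

See `vignettes/inverse-mapping.Rmd` for the model details, the phantom's
design, and all numerical choices.

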