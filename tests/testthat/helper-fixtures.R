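# Small programmatic fixtures shared across the suite.

# A planted dataset with full control over field maxima and MEP patterns.
# Fields are constant-inside-mask volumes with chosen masked maxima; MEP rows
# are given directly.
make_planted_dataset <- function(maxima, meps, shape = 8L,
                                 intensities = NULL) {
  n <- length(maxima)
  stopifnot(nrow(meps) == n)
  dim3 <- rep(shape, 3L)
  V <- prod(dim3)
  g <- array(0L, dim3)
  g[2:4, 2:6, 2:4] <- 1L # small box mask
  mask <- cortex_mask(g)
  inside <- which(g != 0)
  X <- matrix(0, n, V)
  for (i in seq_len(n)) {
    X[i, inside] <- maxima[i] * seq(0.5, 1, length.out = length(inside))
  }
  intens <- intensities %||% rep(c(110, 120, 130, 140), length.out = n)
  coil <- data.frame(id = seq_len(n), x = 0, y = 0, z = 0,
                     orientation_deg = 45, intensity_pct_rmt = intens)
  stim_dataset(X, dim3, meps, coil, mask, voxel_size = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny preprocessed phantom dataset for training tests (8-cube, fast).
tiny_training_dataset <- function(seed = 7L, shape = 8L) {
  cfg <- phantom_config("test", shape = shape, seed = seed)
  prep <- preprocess_dataset(generate_dataset(cfg))
  prep$dataset
}

random_volume <- function(shape = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(shape^3), rep(shape, 3L))
}
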