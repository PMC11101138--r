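# Domain types, filtering, scaling, masking, stratified folds and I/O.

test_that("zero-MEP stimulations are removed, others retained in order", {
  meps <- matrix(0, 20, 15)
  nonzero <- c(2, 3, 5, 7, 8, 10, 12, 13, 15, 16, 18, 19, 20)
  for (i in nonzero) meps[i, sample(15, 3)] <- runif(3, 0.1, 1)
  ds <- make_planted_dataset(rep(0.05, 20), meps)
  out <- filter_zero_mep(ds)
  # independent oracle: loop-count rows with any nonzero entry
  expected <- sum(vapply(seq_len(20), function(i) any(meps[i, ] != 0), logical(1)))
  expect_equal(nrow(out$X), expected)
  expect_equal(nrow(out$X), 13)
  expect_equal(out$coil$id, nonzero)
  expect_equal(out$removed[["zero_mep"]], 7)
  # single all-zero row removed; single nonzero entry retained
  ds2 <- make_planted_dataset(c(0.05, 0.05),
                              rbind(rep(0, 15), c(rep(0, 14), 0.3)))
  expect_equal(filter_zero_mep(ds2)$coil$id, 2L)
  # idempotence
  expect_equal(filter_zero_mep(out)$coil$id, out$coil$id)
})

test_that("low E-field outlier removal is strictly below threshold", {
  maxima <- c(0.005, 0.009, 0.010, 0.011, 0.200)
  ds <- make_planted_dataset(maxima, matrix(1, 5, 15))
  out <- filter_low_efield(ds, 0.010)
  # brute-force oracle over the planted maxima
  expect_equal(nrow(out$X), sum(maxima >= 0.010))
  expect_equal(out$coil$id, c(3L, 4L, 5L)) # the 10 mV/m record survives
  expect_equal(out$removed[["low_efield"]], 2)
  expect_equal(filter_low_efield(out, 0.010)$coil$id, out$coil$id) # idempotent
  expect_error(filter_low_efield(ds, 0), "positive")
  expect_error(filter_low_efield(ds, -1), "positive")
})

test_that("filters reject an empty dataset", {
  ds <- make_planted_dataset(0.05, matrix(1, 1, 15))
  empty <- mepfield:::subset_records(ds, FALSE)
  expect_error(filter_zero_mep(empty), "empty")
  expect_error(filter_low_efield(empty), "empty")
})

test_that("E-field scaling divides by the global max and zeros outside mask", {
  set.seed(1)
  n <- 6
  ds <- make_planted_dataset(runif(n, 0.02, 0.2), matrix(1, n, 15))
  # plant a value outside the mask and a known global max
  outside <- which(ds$mask$grid == 0)[10]
  ds$X[2, outside] <- 0.15
  res <- scale_efields(ds)
  d2 <- res$dataset
  expect_equal(d2$X[2, outside], 0)
  expect_equal(max(d2$X), 1)
  expect_equal(sum(d2$X == 1), 1) # exactly one voxel attains 1
  expect_true(all(d2$X >= 0 & d2$X <= 1))
  # elementwise oracle: scaled == raw / global max inside the mask
  inside <- which(ds$mask$grid != 0)
  gmax <- max(ds$X[, inside])
  expect_equal(res$scaling$efield_global_max, gmax)
  for (i in seq_len(n))
    expect_equal(d2$X[i, inside], ds$X[i, inside] / gmax, tolerance = 1e-12)
  # all-zero dataset is degenerate
  dz <- make_planted_dataset(rep(0, 2), matrix(1, 2, 15))
  expect_error(scale_efields(dz), "degenerate")
})

test_that("MEP scaling is columnwise max division", {
  set.seed(2)
  meps <- matrix(runif(20 * 15, 0, 800), 20, 15)
  ds <- make_planted_dataset(rep(0.05, 20), meps)
  res <- scale_meps(ds)
  # columnwise brute-force oracle
  expect_equal(res$dataset$meps, sweep(meps, 2, apply(meps, 2, max), "/"),
               ignore_attr = TRUE)
  expect_true(all(abs(apply(res$dataset$meps, 2, max) - 1) < 1e-12))
  # half the muscle max scales to one half
  j <- which.max(meps[, 1])
  expect_equal(unname(res$dataset$meps[j, 1]), 1)
  # a never-active muscle maps to zeros with a warning
  meps2 <- meps
  meps2[, 4] <- 0
  ds2 <- make_planted_dataset(rep(0.05, 20), meps2)
  expect_warning(res2 <- scale_meps(ds2), "never active")
  expect_true(all(res2$dataset$meps[, 4] == 0))
  expect_equal(ncol(res2$dataset$meps), 15) # channel kept, m fixed
})

test_that("scaling is invertible on retained records", {
  set.seed(3)
  ds0 <- make_planted_dataset(runif(8, 0.02, 0.2),
                              matrix(runif(8 * 15, 0, 500), 8, 15))
  ds <- scale_efields(ds0)$dataset
  ds <- scale_meps(ds)$dataset
  back <- unscale_dataset(ds)
  inside <- which(ds0$mask$grid != 0)
  expect_equal(back$X[, inside], ds0$X[, inside], tolerance = 1e-6)
  expect_equal(back$meps, ds0$meps, tolerance = 1e-6, ignore_attr = TRUE)
  expect_false(back$efield_scaled)
  expect_false(back$mep_scaled)
})

test_that("apply_mask is an elementwise product, idempotent, never increases", {
  set.seed(4)
  g <- random_volume(6)
  mg <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
  vol <- efield_volume(g)
  msk <- cortex_mask(mg)
  out <- apply_mask(vol, msk)
  # elementwise loop oracle
  expected <- array(0, dim(g))
  for (i in seq_along(g)) expected[i] <- g[i] * mg[i]
  expect_equal(out$grid, expected)
  expect_true(all(out$grid <= g))
  expect_equal(apply_mask(out, msk)$grid, out$grid)
  expect_equal(apply_mask(vol, cortex_mask(array(1, dim(g))))$grid, g)
  expect_true(all(apply_mask(vol, cortex_mask(array(0, dim(g))))$grid == 0))
  expect_error(apply_mask(vol, cortex_mask(array(1, c(4, 4, 4)))), "shape")
})

test_that("stratified folds preserve per-intensity counts within one", {
  # perfectly divisible case: 40 records, 10 per intensity, k = 10
  ds <- make_planted_dataset(rep(0.05, 40), matrix(1, 40, 15),
                             intensities = rep(c(110, 120, 130, 140), each = 10))
  folds <- stratified_kfold(ds, 10, seed = 5)
  for (f in folds) {
    sub <- ds$coil$intensity_pct_rmt[ds$coil$id %in% f$test_ids]
    expect_equal(unname(table(sub)), rep(1L, 4), ignore_attr = TRUE)
  }
  # partition: every id in exactly one test fold
  all_test <- sort(unlist(lapply(folds, `[[`, "test_ids")))
  expect_equal(all_test, ds$coil$id)
  # determinism
  folds2 <- stratified_kfold(ds, 10, seed = 5)
  expect_identical(folds, folds2)
  # uneven strata: counts per fold within {1, 2}, stratum totals preserved
  ds2 <- make_planted_dataset(rep(0.05, 43), matrix(1, 43, 15),
                              intensities = rep(c(110, 120, 130, 140),
                                                c(11, 11, 11, 10)))
  folds2 <- stratified_kfold(ds2, 10, seed = 6)
  counts <- sapply(folds2, function(f)
    table(factor(ds2$coil$intensity_pct_rmt[ds2$coil$id %in% f$test_ids],
                 levels = c(110, 120, 130, 140))))
  expect_true(all(counts %in% c(1L, 2L)))
  expect_equal(unname(rowSums(counts)), c(11, 11, 11, 10))
  # stratum smaller than k errors, naming the stratum
  expect_error(stratified_kfold(ds2, 12), "110")
})

test_that("train and test ids are disjoint and complete in every fold", {
  ds <- make_planted_dataset(rep(0.05, 30), matrix(1, 30, 15))
  for (f in stratified_kfold(ds, 5, seed = 1)) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), ds$coil$id)
  }
})

test_that("NIfTI volumes round-trip losslessly at float32 with their affine", {
  vol <- efield_volume(random_volume(6, seed = 8), voxel_size = 2)
  # anisotropic affine
  aff <- diag(c(2, 1.5, 3, 1))
  aff[1:3, 4] <- c(-10, 5, 2)
  attr(vol, "affine") <- aff
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$grid, vol$grid, tolerance = 1e-7) # float32 round-trip
  expect_equal(unclass(attr(back, "affine")), aff, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_error(read_volume(tempfile(fileext = ".nii")), "no such")
})

test_that("MEP CSV tables round-trip with muscle labels", {
  meps <- matrix(runif(45, 0, 600), 3, 15,
                 dimnames = list(NULL, default_muscles(15)))
  path <- tempfile(fileext = ".csv")
  write_mep_table(meps, path)
  back <- read_mep_table(path)
  expect_length(back, 3)
  expect_equal(names(back[[1]]), default_muscles(15))
  for (i in 1:3) expect_equal(as.numeric(back[[i]]), unname(meps[i, ]),
                              tolerance = 1e-12)
})

test_that("domain type invariants are enforced", {
  expect_error(efield_volume(matrix(1, 2, 2)), "3D")
  expect_error(efield_volume(array(-1, c(2, 2, 2))), "nonnegative")
  expect_error(mep_vector(c(-1, 2)), "nonnegative")
  expect_error(mep_vector(1:3, c("a", "b")), "muscle names")
  v <- mep_vector(c(0.5, 1), c("FDI", "ADM"))
  expect_named(v, c("FDI", "ADM"))
})
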