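# The synthetic phantom: mask geometry, field kernel, recruitment map and
# dataset assembly.

test_that("phantom mask hits its target fraction, connected, deterministic", {
  m <- make_phantom_mask(16, 0.05, seed = 3)
  frac <- mean(m$grid)
  expect_gt(frac, 0.05 * 0.75)
  expect_lt(frac, 0.05 * 1.25)
  expect_true(mepfield:::mask_connected(m))
  m2 <- make_phantom_mask(16, 0.05, seed = 3)
  expect_identical(m$grid, m2$grid)
  m3 <- make_phantom_mask(16, 0.05, seed = 4)
  expect_false(identical(m$grid, m3$grid))
  expect_error(make_phantom_mask(16, 0), "in \\(0, 0.2\\)")
  expect_error(make_phantom_mask(16, 0.5), "in \\(0, 0.2\\)")
})

test_that("full-scale mask occupies about 2% of the 64-cube", {
  m <- make_phantom_mask(64, 0.02, seed = 1)
  n <- sum(m$grid)
  expect_gt(n, 0.015 * 64^3)
  expect_lt(n, 0.025 * 64^3)
})

test_that("simulated field is masked, unimodal, peaked under the coil", {
  cfg <- phantom_config("test", seed = 5)
  mask <- make_phantom_mask(cfg$shape, cfg$mask_fraction, cfg$seed)
  co <- mepfield:::voxel_coords_mm(dim(mask$grid), mask$voxel_size)
  centroid <- colMeans(co[mask$inside, ])
  coil <- c(centroid[1], centroid[2], 70)
  vol <- simulate_efield(coil, 45, 140, mask, cfg)
  expect_true(all(vol$grid >= 0))
  expect_true(all(vol$grid[mask$grid == 0] == 0))
  # peak voxel is the mask voxel nearest the coil's in-plane projection
  dxy <- sqrt((co[mask$inside, 1] - coil[1])^2 + (co[mask$inside, 2] - coil[2])^2)
  expect_equal(which.max(vol$grid), mask$inside[which.min(dxy)])
  # single connected superlevel set at half peak (unimodality)
  half <- cortex_mask(array(as.integer(vol$grid >= max(vol$grid) / 2),
                            dim(vol$grid)))
  expect_true(mepfield:::mask_connected(half))
  # intensity response is monotone
  v110 <- simulate_efield(coil, 45, 110, mask, cfg)
  expect_gt(max(vol$grid), max(v110$grid))
})

test_that("field values match the closed-form kernel at probe voxels", {
  cfg <- phantom_config("test", seed = 6)
  mask <- make_phantom_mask(cfg$shape, cfg$mask_fraction, cfg$seed)
  co <- mepfield:::voxel_coords_mm(dim(mask$grid), mask$voxel_size)
  centroid <- colMeans(co[mask$inside, ])
  coil <- c(centroid[1] + 5, centroid[2] - 3, 70)
  orient <- 30
  vol <- simulate_efield(coil, orient, 120, mask, cfg)
  # independent scalar implementation of the kernel
  dxy <- sqrt((co[mask$inside, 1] - coil[1])^2 + (co[mask$inside, 2] - coil[2])^2)
  peak <- which.min(dxy)
  pstar <- co[mask$inside[peak], ]
  u <- c(cos(orient * pi / 180), sin(orient * pi / 180), 0)
  ofac <- 1 + cfg$orient_gain * sum(u * mask$tangent[peak, ])
  g <- exp(-min(dxy)^2 / (2 * cfg$coil_sigma^2))
  s <- 1.2^2
  for (probe in mask$inside[c(1, 11, 51, 101, length(mask$inside))]) {
    d2 <- sum((co[probe, ] - pstar)^2)
    expected <- cfg$field_amp * s * g * ofac * exp(-d2 / (2 * cfg$field_sigma^2))
    expect_equal(vol$grid[probe], expected, tolerance = 1e-12)
  }
})

test_that("a coil far from the mask yields an all-zero flagged field", {
  cfg <- phantom_config("test", seed = 7)
  mask <- make_phantom_mask(cfg$shape, cfg$mask_fraction, cfg$seed)
  vol <- simulate_efield(c(-500, -500, 70), 45, 140, mask, cfg)
  expect_true(all(vol$grid == 0))
  expect_true(attr(vol, "fringe"))
})

test_that("muscle weight maps are normalized blobs at distinct centres", {
  mask <- make_phantom_mask(16, 0.05, seed = 8)
  maps <- make_muscle_weight_maps(15, mask, seed = 8, sigma = 6)
  expect_length(maps, 15)
  for (mp in maps) {
    expect_equal(sum(mp$w), 1, tolerance = 1e-6)
    expect_true(all(mp$w[mask$grid == 0] == 0)) # support within the mask
    expect_true(all(mp$w >= 0))
  }
  centers <- do.call(rbind, lapply(maps, `[[`, "center"))
  dists <- as.matrix(dist(centers))
  diag(dists) <- Inf
  expect_gt(min(dists), 0) # pairwise distinct
  # determinism
  maps2 <- make_muscle_weight_maps(15, mask, seed = 8, sigma = 6)
  expect_identical(lapply(maps, `[[`, "w"), lapply(maps2, `[[`, "w"))
})

test_that("recruitment map matches its closed form and rectifies to zero", {
  mask <- make_phantom_mask(16, 0.05, seed = 9)
  maps <- make_muscle_weight_maps(4, mask, seed = 9)
  recr <- list(gain = c(500, 1000, 1500, 2000),
               threshold = c(0.01, 0.02, 0.03, 0.04),
               slope = rep(0.008, 4))
  # all-zero field with no noise gives an all-zero MEP
  zero <- efield_volume(array(0, dim(mask$grid)), mask$voxel_size)
  mep0 <- simulate_mep(zero, maps, recr, noise_sd = 0, rectify_floor = 0.02)
  expect_true(all(mep0 == 0))
  # noiseless response equals the scalar sigmoid formula
  cfg <- phantom_config("test", seed = 9)
  co <- mepfield:::voxel_coords_mm(dim(mask$grid), mask$voxel_size)
  centroid <- colMeans(co[mask$inside, ])
  vol <- simulate_efield(c(centroid[1], centroid[2], 70), 45, 140, mask, cfg)
  mep <- simulate_mep(vol, maps, recr, noise_sd = 0, rectify_floor = 0.02)
  for (k in 1:4) {
    drive <- sum(maps[[k]]$w * as.numeric(vol$grid))
    expected <- max(0, recr$gain[k] *
                      (1 / (1 + exp(-(drive - recr$threshold[k]) / recr$slope[k])) -
                       1 / (1 + exp(recr$threshold[k] / recr$slope[k])) - 0.02))
    expect_equal(unname(mep[k]), expected, tolerance = 1e-10)
  }
  # a strong central field activates more muscles than a weak fringe one
  weak <- efield_volume(array(0.02 * (mask$grid > 0) *
                                as.numeric(vol$grid > 0.8 * max(vol$grid)),
                              dim(mask$grid)), mask$voxel_size)
  expect_gte(sum(mep > 0), sum(simulate_mep(weak, maps, recr, 0, 0.02) > 0))
  expect_error(simulate_mep(vol, maps, list(gain = 1, threshold = 1), 0),
               "do not match")
})

test_that("dataset generation matches the session design and is reproducible", {
  cfg <- phantom_config("test", n_jitter = 0, seed = 10)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$X), 196) # 49 grid points x 4 intensities
  expect_equal(unname(table(ds$coil$intensity_pct_rmt)), rep(49L, 4),
               ignore_attr = TRUE)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$meps, ds2$meps)
  cfg2 <- phantom_config("test", n_jitter = 3, seed = 10)
  expect_equal(nrow(generate_dataset(cfg2)$X), 4 * 52)
})

test_that("MEP mean and variance increase with stimulation intensity", {
  ds <- generate_dataset(phantom_config("test", seed = 11))
  mep_mean <- tapply(rowMeans(ds$meps), ds$coil$intensity_pct_rmt, mean)
  mep_var <- tapply(apply(ds$meps, 1, var), ds$coil$intensity_pct_rmt, mean)
  expect_true(all(diff(mep_mean) > 0))
  expect_true(all(diff(mep_var) > 0))
})

test_that("lower intensities produce more silent stimulations", {
  lo <- generate_dataset(phantom_config("test", intensities = 110, seed = 12))
  hi <- generate_dataset(phantom_config("test", intensities = 140, seed = 12))
  n_zero <- function(d) sum(rowSums(d$meps != 0) == 0)
  expect_gte(n_zero(lo), n_zero(hi))
})

test_that("phantom field maxima straddle the 10 mV/m outlier threshold", {
  ds <- generate_dataset(phantom_config("test", seed = 13))
  inside <- as.logical(ds$mask$grid)
  mx <- apply(ds$X[, inside], 1, max)
  expect_gt(sum(mx < 0.010), 0)
  expect_gt(sum(mx >= 0.010), 0)
})
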