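# Metric definitions against brute-force loop oracles (helper-oracles.R),
# and aggregation.

test_that("NRMSE matches its definition and edge cases", {
  g <- random_volume(6, seed = 41)
  expect_equal(nrmse(g, g), 0)
  expect_equal(nrmse(array(0, dim(g)), g), 1) # all-zero prediction
  p <- random_volume(6)
  expect_equal(nrmse(p, g), loop_nrmse(as.numeric(p), as.numeric(g)),
               tolerance = 1e-12)
  expect_equal(nrmse(p, g, squared = TRUE), nrmse(p, g)^2)
  expect_error(nrmse(p, array(0, dim(g))), "all zero")
})

test_that("NRMSE is invariant to common positive rescaling", {
  p <- random_volume(5, seed = 42)
  g <- random_volume(5)
  for (a in c(0.1, 3, 1000))
    expect_equal(nrmse(a * p, a * g), nrmse(p, g), tolerance = 1e-12)
})

test_that("R-squared matches its definition within the mask", {
  set.seed(43)
  d <- c(6, 6, 6)
  g <- random_volume(6)
  p <- random_volume(6)
  mg <- array(rbinom(216, 1, 0.4), d)
  msk <- cortex_mask(mg)
  inside <- which(mg != 0)
  expect_equal(r_squared(p, g, msk), loop_r2(as.numeric(p), as.numeric(g), inside),
               tolerance = 1e-12)
  expect_equal(r_squared(g, g, msk), 1)
  # predicting the mask mean everywhere gives exactly 0
  pm <- array(mean(g[inside]), d)
  expect_equal(r_squared(pm, g, msk), 0)
  # constant ground truth in the mask is undefined
  gc <- array(0.5, d)
  expect_error(r_squared(p, gc, msk), "constant")
})

test_that("centre of gravity matches hand values and a loop oracle", {
  d <- c(8, 8, 8)
  v <- array(0, d)
  v[4, 5, 6] <- 2.5 # 0-based (3, 4, 5)
  expect_equal(center_of_gravity(v), c(3, 4, 5))
  v2 <- array(0, d)
  v2[1, 1, 1] <- 1
  v2[3, 5, 7] <- 1 # equal weights at (0,0,0) and (2,4,6) -> midpoint
  expect_equal(center_of_gravity(v2), c(1, 2, 3))
  set.seed(44)
  v3 <- random_volume(8)
  mg <- array(rbinom(512, 1, 0.3), d)
  msk <- cortex_mask(mg)
  expect_equal(center_of_gravity(v3, msk),
               loop_cog(as.numeric(v3), which(mg != 0), d), tolerance = 1e-12)
  expect_error(center_of_gravity(array(0, d)), "zero total intensity")
})

test_that("CoG error is a Euclidean distance, symmetric, zero at identity", {
  d <- c(8, 8, 8)
  a <- array(0, d); a[1, 1, 1] <- 1           # CoG (0, 0, 0)
  b <- array(0, d); b[4, 5, 1] <- 1           # CoG (3, 4, 0)
  expect_equal(cog_error(a, b), 5)            # 3-4-5 triangle
  expect_equal(cog_error(b, a), cog_error(a, b))
  v <- random_volume(8, seed = 45)
  expect_equal(cog_error(v, v), 0)
  w <- random_volume(8)
  expect_equal(cog_error(v, w),
               sqrt(sum((center_of_gravity(v) - center_of_gravity(w))^2)),
               tolerance = 1e-12)
})

test_that("metrics equal naive-loop oracles on many random volume pairs", {
  set.seed(46)
  d <- c(8, 8, 8)
  mg <- array(0L, d); mg[2:6, 3:7, 2:5] <- 1L
  msk <- cortex_mask(mg)
  inside <- which(mg != 0)
  for (i in 1:50) {
    gt <- array(runif(512), d)
    pred <- array(runif(512), d)
    expect_equal(nrmse(pred, gt), loop_nrmse(as.numeric(pred), as.numeric(gt)),
                 tolerance = 1e-10)
    expect_equal(r_squared(pred, gt, msk),
                 loop_r2(as.numeric(pred), as.numeric(gt), inside),
                 tolerance = 1e-10)
    expect_equal(center_of_gravity(gt, msk), loop_cog(as.numeric(gt), inside, d),
                 tolerance = 1e-10)
  }
})

test_that("evaluation records carry metrics and stratifiers per stimulation", {
  set.seed(47)
  meps <- matrix(runif(60, 0, 1), 4, 15)
  meps[1, ] <- 0
  meps[1, 3] <- 0.5 # one active muscle
  ds <- make_planted_dataset(runif(4, 0.05, 0.2), meps)
  ds <- scale_efields(ds)$dataset
  ds <- scale_meps(ds)$dataset
  pred <- ds$X * 0.9
  rec <- evaluate_records(pred, ds, fold = 2, model = "e")
  expect_equal(nrow(rec), 4)
  expect_equal(rec$n_active[1], 1)
  expect_equal(rec$n_active[2], sum(ds$meps[2, ] > 0))
  expect_equal(rec$nrmse[3], nrmse(pred[3, ], ds$X[3, ]))
  expect_equal(rec$fold, rep(2, 4))
  # a flat prediction yields NA r2/cog flags rather than errors
  ds$X[4, ] <- 0
  rec2 <- evaluate_records(pred, ds)
  expect_true(is.na(rec2$nrmse[4]))
})

test_that("aggregation takes fold means then mean and 95% SEM", {
  rec <- data.frame(model = "e",
                    fold = rep(0:9, each = 2),
                    nrmse = rep(seq(0.1, 1.0, by = 0.1), each = 2),
                    r2 = 1 - rep(seq(0.1, 1.0, by = 0.1), each = 2))
  agg <- aggregate_metrics(rec, "model")
  fm <- seq(0.1, 1.0, by = 0.1)
  expect_equal(agg$mean[agg$metric == "nrmse"], mean(fm))
  expect_equal(agg$sem_95[agg$metric == "nrmse"],
               1.96 * sd(fm) / sqrt(10), tolerance = 1e-12)
  expect_equal(agg$n_folds[1], 10)
  # identical fold means give zero SEM
  rec2 <- transform(rec, nrmse = 0.3, r2 = 0.5)
  agg2 <- aggregate_metrics(rec2, "model")
  expect_equal(agg2$sem_95, c(0, 0))
  # single-fold group is degenerate with SEM 0
  rec3 <- rec[rec$fold == 0, ]
  agg3 <- aggregate_metrics(rec3, "model")
  expect_true(all(agg3$degenerate))
  expect_equal(agg3$sem_95, c(0, 0))
})

test_that("intensity stratification groups per %RMT", {
  rec <- expand.grid(fold = 0:4, intensity_pct_rmt = c(110, 120, 130, 140))
  rec$model <- "e"
  rec$nrmse <- rec$intensity_pct_rmt / 1000 + rec$fold * 1e-3
  rec$r2 <- 1 - rec$nrmse
  tab <- stratify_by_intensity(rec)
  expect_equal(nrow(tab), 8) # 4 intensities x 2 metrics
  nr <- tab[tab$metric == "nrmse", ]
  expect_equal(nr$mean, c(110, 120, 130, 140) / 1000 + 0.002, tolerance = 1e-12)
})

test_that("MEP profile analysis bins by active muscles and omits empty bins", {
  rec <- data.frame(id = 1:9, model = "e", fold = 0,
                    n_active = c(1, 1, 2, 2, 4, 4, 8, 8, 8),
                    mep_mean = runif(9), mep_variance = runif(9))
  rec$nrmse <- 1 / rec$n_active # construction: median decreases with n_active
  prof <- mep_profile_analysis(rec)
  expect_equal(prof$by_n_active$n_active, c(1, 2, 4, 8)) # bin 3 etc. omitted
  expect_true(all(diff(prof$by_n_active$median) < 0))
  # n_active column equals a loop count of positive entries
  meps <- matrix(runif(30, 0, 1) * rbinom(30, 1, 0.5), 2, 15)
  ds <- make_planted_dataset(c(0.05, 0.06), meps)
  # some columns may be all zero by construction; the warning is expected
  ds <- suppressWarnings(scale_meps(scale_efields(ds)$dataset)$dataset)
  r <- evaluate_records(ds$X, ds)
  for (i in 1:2) {
    cnt <- 0
    for (j in 1:15) if (ds$meps[i, j] > 0) cnt <- cnt + 1
    expect_equal(r$n_active[i], cnt)
  }
})

test_that("variant comparison ranks by NRMSE with documented tie-breaks", {
  rep <- data.frame(model = rep(c("ae_decoder", "direct_variational",
                                  "vae_decoder"), each = 2),
                    metric = rep(c("nrmse", "r2"), 3),
                    mean = c(0.3, 0.8, 0.2, 0.85, 0.2, 0.9))
  cmp <- compare_variants(rep)
  # tie on NRMSE between e and c broken by higher R2 (c wins)
  expect_equal(cmp$ranking$model,
               c("vae_decoder", "direct_variational", "ae_decoder"))
  expect_true(cmp$wins["vae_decoder", "ae_decoder"])
  expect_false(cmp$wins["ae_decoder", "vae_decoder"])
})
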