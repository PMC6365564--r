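test_that("band-pass keeps the passband and kills stopband and DC", {
  tr <- 2.2
  t <- (0:295) * tr
  in_band <- sin(2 * pi * 0.04 * t)
  out_band <- sin(2 * pi * 0.2 * t)
  amp <- function(x) sqrt(mean(x^2))
  expect_lt(abs(amp(bandpass(in_band, tr)) / amp(in_band) - 1), 0.05)
  expect_lt(amp(bandpass(out_band, tr)) / amp(out_band), 0.10)
  expect_lt(amp(bandpass(rep(5, 296), tr)), 1e-10)
  expect_error(bandpass(in_band, tr, low = 0.01, high = 0.3), "Nyquist")
  expect_error(bandpass(in_band, -1), "positive")
})

test_that("nuisance regression removes linear and squared confound structure", {
  set.seed(44)
  Tn <- 200
  motion <- apply(matrix(rnorm(Tn * 6, sd = 0.05), Tn, 6), 2, cumsum)
  tissue <- matrix(rnorm(Tn * 3), Tn, 3)
  grid <- list(dim = c(3L, 1L, 1L), spacing = 3, origin = c(0, 0, 0))
  signal <- rnorm(Tn)
  m1s <- scale(motion[, 1])
  vox <- cbind(motion[, 1],                       # pure motion
               signal,                            # clean signal
               signal + 0.7 * m1s^2)              # squared contamination
  ts <- timeseries_bundle(vox, 2.2, motion, tissue, grid)
  clean <- nuisance_regress(ts)
  expect_lt(sd(clean$voxels[, 1]), 0.05 * sd(vox[, 1]))
  expect_gt(cor(clean$voxels[, 2], signal - mean(signal)), 0.9)
  # squared term gone after cleanup; would remain under a linear-only model
  expect_lt(abs(cor(clean$voxels[, 3], m1s^2)), 0.1)
  lin_only <- qr.resid(qr(cbind(1, motion, rbind(0, diff(motion)), tissue)),
                       vox[, 3])
  expect_gt(abs(cor(lin_only, m1s^2)), 0.3)
})

test_that("eigenvariate extraction follows the rank-1 SVD oracle", {
  set.seed(3)
  Tn <- 120
  s <- rnorm(Tn)
  # identical series in every voxel
  X <- matrix(rep(s, 4), Tn, 4)
  e <- extract_eigenvariate(X)
  expect_equal(abs(cor(e, s)), 1, tolerance = 1e-10)
  expect_gt(cor(e, rowMeans(X)), 0)
  # single voxel: the (centered) series itself up to scale
  e1 <- extract_eigenvariate(X[, 1, drop = FALSE])
  expect_equal(cor(e1, s), 1, tolerance = 1e-10)
  # two anti-correlated populations of unequal variance: dominant wins
  a <- rnorm(Tn)
  X2 <- cbind(3 * a, 3 * a, 3 * a, -a)
  e2 <- extract_eigenvariate(X2)
  expect_gt(cor(e2, a)^2, 0.99)
  expect_gt(cor(e2, rowMeans(X2)), 0)
  expect_error(extract_eigenvariate(matrix(0, 10, 0)), "empty")
})

test_that("spherical VOIs match brute-force voxel enumeration", {
  grid <- list(dim = c(7L, 7L, 7L), spacing = 1, origin = c(0, 0, 0))
  center <- c(3, 3, 3)
  expect_length(voi_from_sphere(center, 0, grid)$voxels, 1L)
  expect_length(voi_from_sphere(center, 1, grid)$voxels, 7L)
  set.seed(10)
  for (r in 1:20) {
    ctr <- runif(3, 1, 5)
    rad <- runif(1, 0.5, 3)
    voi <- voi_from_sphere(ctr, rad, grid)
    # brute force over all voxel centers
    cnt <- 0L
    for (k in 1:7) for (j in 1:7) for (i in 1:7) {
      if (sum((c(i, j, k) - 1 - ctr)^2) <= rad^2 + 1e-9) cnt <- cnt + 1L
    }
    expect_equal(length(voi$voxels), cnt)
  }
  expect_error(voi_from_sphere(c(100, 0, 0), 5, grid), "outside")
})

test_that("seed correlation maps apply the Fisher transform with masking", {
  set.seed(5)
  s <- rnorm(100)
  X <- cbind(s, rnorm(100), rep(1, 100), -s)
  fc <- seed_fc(s, X)
  expect_equal(fc$r[1], 1)
  expect_equal(fc$z[1], atanh(1 - 1e-7))   # clipped, finite
  expect_equal(fc$z[4], -fc$z[1])          # odd symmetry
  expect_true(is.na(fc$r[3]))
  expect_equal(fc$masked, 3L)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  r0 <- seed_fc(s, matrix(rnorm(100), ncol = 1))
  expect_lt(abs(r0$z[1]), 0.5)
})

test_that("second level detects a noiseless single-voxel effect", {
  set.seed(66)
  n <- 20
  score <- rnorm(n)
  grid <- list(dim = c(4L, 4L, 2L), spacing = 3, origin = c(0, 0, 0))
  zmaps <- matrix(0, n, 32)
  zmaps[, 10] <- 0.3 * score
  zmaps <- zmaps + matrix(rnorm(n * 32, sd = 1e-6), n, 32)
  fc <- fc_second_level(zmaps, score, NULL, grid, n_perm = 99, seed = 2)
  hit <- vapply(fc$clusters, function(cl) 10L %in% cl$voxels, logical(1))
  expect_true(any(hit))
  expect_equal(fc$clusters[[which(hit)[1]]]$n_voxels, 1L)
})

test_that("second-level permutation p-values are valid under the null", {
  # the max-cluster statistic is discrete at this scale, so uniformity is
  # checked through rejection rates at two levels rather than a KS test
  grid <- list(dim = c(4L, 4L, 2L), spacing = 3, origin = c(0, 0, 0))
  n <- 24
  pvals <- vapply(1:40, function(r) {
    set.seed(900 + r)
    score <- rnorm(n)
    zmaps <- matrix(rnorm(n * 32, sd = 0.3), n, 32)
    fc <- fc_second_level(zmaps, score, NULL, grid, cluster_forming_p = 0.2,
                          n_perm = 99, seed = 950 + r)
    obs <- if (length(fc$clusters))
      max(vapply(fc$clusters, `[[`, numeric(1), "n_voxels")) else 0
    (1 + sum(fc$null_max_sizes >= obs)) / 100
  }, numeric(1))
  # binomial 3 SD bands around the nominal levels (40 replicates)
  expect_lt(abs(mean(pvals <= 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 40) + 0.025)
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40) + 0.025)
})

test_that("the processing order of the pipeline is load-bearing", {
  set.seed(8)
  ts_set <- generate_timeseries(c(-1, 1), n_timepoints = 100, seed = 77)
  b <- ts_set$bundles[[1]]
  voi <- voi_from_sphere(ts_set$seed_center, 5, ts_set$grid)
  standard <- rsfc_pipeline(b, voi)
  # swapped order: band-pass before nuisance regression
  keep <- -(1:4)
  alt <- timeseries_bundle(b$voxels[keep, ], b$tr, b$motion[keep, ],
                           b$tissue[keep, ], b$grid)
  alt$voxels <- bandpass(alt$voxels, alt$tr)
  alt <- nuisance_regress(alt)
  alt_seed <- extract_eigenvariate(alt$voxels[, voi$voxels, drop = FALSE])
  swapped <- seed_fc(alt_seed, alt$voxels, voi$voxels)
  expect_gt(max(abs(standard$z - swapped$z), na.rm = TRUE), 1e-4)
})

test_that("planted connectivity slope is recovered by the full chain", {
  set.seed(13)
  n <- 40
  x <- rnorm(n, 0, 2)
  ts_set <- generate_timeseries(x, n_timepoints = 200, seed = 14)
  voi <- voi_from_sphere(ts_set$seed_center, 5, ts_set$grid)
  ztar <- vapply(ts_set$bundles, function(b) {
    fcm <- rsfc_pipeline(b, voi)
    mean(fcm$z[ts_set$target_voxels])
  }, numeric(1))
  fit <- summary(lm(ztar ~ x))$coefficients
  expect_lt(abs(fit["x", 1] - ts_set$slope), 3 * fit["x", 2])
  expect_lt(fit["x", 4], 0.01)
})
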