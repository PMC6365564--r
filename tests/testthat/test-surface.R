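test_that("vertex-wise GLM recovers noiseless planted slopes exactly", {
  mesh <- grid_mesh(4, 4)
  n <- 12
  set.seed(7)
  score <- rnorm(n)
  fields <- matrix(1, n, 16)
  fields[, 5] <- 2 * score
  fit <- fit_vertexwise_glm(fields, score)
  expect_equal(fit$slope[5], 2, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals[, 5])), 1e-10)
  expect_equal(fit$F, fit$t^2, tolerance = 1e-8)
  expect_equal(fit$dof, n - 2L)
})

test_that("rank-deficient designs are rejected with a message", {
  n <- 10
  fields <- matrix(rnorm(n * 4), n, 4)
  expect_error(fit_vertexwise_glm(fields, rep(1, n)), "rank deficient|collinear")
  covs <- data.frame(age = 1:n, gender = rep(0, n))  # constant gender column
  expect_error(fit_vertexwise_glm(fields, 1:n, covs), "rank deficient|collinear")
})

test_that("GLM t statistics agree with lm() as an independent oracle", {
  set.seed(19)
  n <- 25
  fields <- matrix(rnorm(n * 6), n, 6)
  score <- rnorm(n)
  covs <- data.frame(age = rnorm(n, 67, 6), gender = rbinom(n, 1, 0.5))
  fit <- fit_vertexwise_glm(fields, score, covs)
  for (v in 1:6) {
    ref <- summary(lm(fields[, v] ~ score + I(covs$age - mean(covs$age)) +
                        covs$gender))
    expect_equal(fit$slope[v], ref$coefficients["score", 1], tolerance = 1e-8)
    expect_equal(fit$t[v], ref$coefficients["score", 3], tolerance = 1e-8)
  }
  # sampling behaviour: planted slope recovered within 3 SE
  beta <- 0.8
  set.seed(20)
  y <- outer(score, rep(beta, 3)) + matrix(rnorm(n * 3, sd = 0.5), n, 3)
  fit2 <- fit_vertexwise_glm(y, score, covs)
  se <- fit2$slope / fit2$t
  expect_true(all(abs(fit2$slope - beta) < 3 * se))
})

test_that("cluster formation matches the flood-fill oracle and edge cases", {
  skip_if_not_installed("igraph")
  mesh <- grid_mesh(6, 5)
  # nothing supra-threshold
  expect_length(form_clusters(rep(0.1, 30), mesh, dof = 20)$clusters, 0L)
  # two isolated vertices -> two clusters
  tm <- rep(0, 30); tm[c(1, 30)] <- 10
  expect_length(form_clusters(tm, mesh, dof = 20)$clusters, 2L)
  # random maps vs igraph components on small random meshes
  set.seed(33)
  for (r in 1:50) {
    m <- random_grid_mesh(7)
    nv <- nrow(m$vertices)
    tm <- rnorm(nv, sd = 2)
    cl <- form_clusters(tm, m, dof = 15, cluster_forming_p = 0.1)
    oracle <- igraph_components_oracle(tm, m, cl$cutoff)
    expect_equal(cluster_vertex_sets(cl), oracle)
  }
})

test_that("smoothness estimation recovers the FWHM of Gaussian-ACF fields", {
  mesh <- grid_mesh(40, 40)
  n <- nrow(mesh$vertices)
  set.seed(6)
  # white noise: estimate at or below the vertex spacing
  white <- matrix(rnorm(4 * n), 4, n)
  expect_lt(estimate_smoothness(white, mesh), 1.05)
  # oracle: white noise convolved with a separable Gaussian kernel of SD
  # sigma has exactly Gaussian autocorrelation with s = sigma * sqrt(2)
  gauss_field <- function(nx, ny, sigma, nmaps) {
    r <- ceiling(4 * sigma)
    kx <- dnorm(-r:r, sd = sigma)
    t(vapply(seq_len(nmaps), function(m) {
      pad <- matrix(rnorm((nx + 2 * r) * (ny + 2 * r)), nx + 2 * r)
      tmp <- apply(pad, 2, function(col) stats::filter(col, kx, sides = 2))
      tmp <- t(apply(tmp, 1, function(row) stats::filter(row, kx, sides = 2)))
      as.vector(tmp[(r + 1):(r + nx), (r + 1):(r + ny)])
    }, numeric(nx * ny)))
  }
  for (sigma in c(0.8, 1.6)) {
    R <- gauss_field(40, 40, sigma, 8)
    true_fwhm <- sqrt(8 * log(2)) * sigma * sqrt(2)
    expect_lt(abs(estimate_smoothness(R, mesh) - true_fwhm) / true_fwhm, 0.2)
  }
  expect_error(estimate_smoothness(matrix(1, 2, n), mesh), "zero-variance")
})

test_that("Monte-Carlo null behaves at its boundaries", {
  mesh <- grid_mesh(10, 10)
  # nothing survives an extreme cluster-forming threshold
  nm <- suppressWarnings(monte_carlo_null(mesh, fwhm = 1, cluster_forming_p = 1e-12,
                                          n_iter = 50, seed = 2))
  expect_true(all(nm == 0))
  expect_warning(monte_carlo_null(mesh, 1, 0.05, n_iter = 50, seed = 2),
                 "unstable")
  # cwp estimator bounds and monotonicity
  nm2 <- monte_carlo_null(mesh, 1, 0.05, n_iter = 199, seed = 3)
  tm <- rep(0, 100); tm[c(44, 45, 55)] <- 5
  cl <- form_clusters(tm, mesh, dof = 30)
  cl <- cluster_pvalues(cl, nm2)
  expect_true(all(cl$cwp >= 1 / 200 & cl$cwp <= 1))
  big <- cluster_pvalues(form_clusters(tm * 10, mesh, dof = 30), nm2)
  expect_true(all(big$cwp <= cl$cwp + 1e-12))
  # an observed size of zero has cwp 1
  expect_equal((1 + sum(nm2 >= 0)) / (length(nm2) + 1), 1)
})

test_that("permutation null flags a planted effect as extreme", {
  mesh <- grid_mesh(15, 15)
  n <- 30
  set.seed(14)
  score <- rnorm(n, 0, 2)
  cl_idx <- mesh_disk(mesh, 113, 3)
  eff <- planted_effects(cluster_vertices = cl_idx)
  fields <- generate_surface_data(mesh, score, eff, seed = 15)
  covs <- data.frame(age = rnorm(n, 67, 6), gender = rbinom(n, 1, 0.5))
  expect_error(permutation_null(fields, score, covs, mesh, n_iter = 0), ">= 1")
  nm <- permutation_null(fields, score, covs, mesh, n_iter = 199, seed = 5)
  fit <- fit_vertexwise_glm(fields, score, covs)
  obs <- form_clusters(fit$t, mesh, fit$dof)
  expect_gt(max(vapply(obs$clusters, `[[`, numeric(1), "area_mm2")),
            quantile(nm, 0.99))
})

test_that("permutation p-values are valid and non-degenerate under the null", {
  # exchangeability makes the test exact up to the discreteness of the
  # max-cluster-area statistic, so rejection rates (not a KS test) are checked
  mesh <- grid_mesh(8, 8)
  n <- 24
  pvals <- vapply(1:40, function(r) {
    set.seed(700 + r)
    score <- rnorm(n)
    fields <- matrix(rnorm(n * 64), n, 64)
    nm <- permutation_null(fields, score, NULL, mesh, n_iter = 99,
                           seed = 800 + r)
    fit <- fit_vertexwise_glm(fields, score)
    obs <- form_clusters(fit$t, mesh, fit$dof)
    obs_max <- if (length(obs$clusters))
      max(vapply(obs$clusters, `[[`, numeric(1), "area_mm2")) else 0
    (1 + sum(nm >= obs_max)) / 100
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40) + 0.025)
  expect_lte(mean(pvals <= 0.25), 0.25 + 3 * sqrt(0.25 * 0.75 / 40) + 0.025)
  expect_gte(mean(pvals <= 0.25), 0.025)  # not hopelessly conservative
})

test_that("peak-vertex extraction is exact and validated", {
  fields <- matrix(1:20, 4, 5)
  expect_equal(extract_cluster_values(fields, 3), fields[, 3])
  expect_error(extract_cluster_values(fields, -1), "out of range")
  expect_error(extract_cluster_values(fields, 6), "out of range")
})

test_that("remove-method regression ranks the generating variable first", {
  set.seed(77)
  n <- 400
  P <- data.frame(ACT = rnorm(n), ALC = rnorm(n), SOC = rnorm(n), SMO = rnorm(n))
  covs <- data.frame(age = rnorm(n, 67, 6), gender = rbinom(n, 1, 0.5))
  y <- 0.5 * P$SOC + rnorm(n)
  rm_fit <- remove_method_regression(y, P[c("SOC", "ACT", "ALC", "SMO")], covs)
  expect_equal(names(which.max(abs(rm_fit$beta_std))), "SOC")
  # removing the true predictor costs R^2; removing null predictors ~ nothing
  expect_gt(rm_fit$steps$R2_change[1], 0.1)
  expect_lt(max(rm_fit$steps$R2_change[-1]), 0.03)
  # model R^2 non-increasing across steps
  expect_true(all(diff(rm_fit$steps$model_R2) <= 1e-12))
  # perfect fit: removing the only real variable produces a huge F change
  y2 <- P$ACT
  rm2 <- suppressWarnings(remove_method_regression(y2, P[c("ACT", "ALC")], NULL))
  expect_gt(rm2$steps$F_change[1], 1e10)
})
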