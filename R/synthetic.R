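#' @title Synthetic cohort and data generation
#' @description Generates a complete synthetic dataset with the statistical
#'   structure the analysis pipeline assumes: zero-inflated right-skewed
#'   lifestyle exposures calibrated to the published descriptive statistics,
#'   smooth Gaussian surface noise with an optional planted score-related
#'   cluster, BOLD-like time series with a planted seed-target connectivity
#'   slope, subcortical volumes with a planted partial correlation, and
#'   Hardy-Weinberg genotype dosages. All generators are reproducible under a
#'   fixed seed.
#' @name synthetic-cohort
NULL

#' Cohort specification
#'
#' Defaults emulate the published study conditions: 715 available participants
#' of whom 2 are excluded for incidental findings, 70 for unusable imaging, 63
#' for missing behavioural data and 31 as score outliers, leaving 549; mean
#' age 67.4 y in 55-85; 216/549 alcohol abstainers and 255/549 never-smokers;
#' exposure means/SDs matched to the published table (SD = SE * sqrt(n)).
#'
#' @param n_participants cohort size before exclusions.
#' @param frac_female proportion of women.
#' @param age_range,age_mean years.
#' @param zero_fraction_alcohol,zero_fraction_smoking structural-zero
#'   proportions among scoreable participants.
#' @param exposure_targets list of per-variable `c(mean, sd)` for
#'   `alcohol` (g/week), `smoking` (cigarette-years), `social` (index),
#'   `met` (MET h/week).
#' @param exclusions list with counts `incidental`, `imaging`,
#'   `missing_behavior`, `outliers` (planted extreme-exposure participants).
#' @param seed integer RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 715L,
                        frac_female = 248 / 549,
                        age_range = c(55, 85),
                        age_mean = 67.4,
                        zero_fraction_alcohol = 216 / 549,
                        zero_fraction_smoking = 255 / 549,
                        exposure_targets = list(
                          alcohol = c(mean = 70.00, sd = 4.41 * sqrt(549)),
                          smoking = c(mean = 12.77, sd = 0.80 * sqrt(549)),
                          social  = c(mean = 12.72, sd = 0.25 * sqrt(549)),
                          met     = c(mean = 40.75, sd = 1.71 * sqrt(549))),
                        exclusions = list(incidental = 2L, imaging = 70L,
                                          missing_behavior = 63L, outliers = 31L),
                        seed = 1L) {
  if (n_participants <= 0) stop("'n_participants' must be > 0")
  props <- c(frac_female, zero_fraction_alcohol, zero_fraction_smoking)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (age_range[1L] >= age_range[2L]) stop("age_range must be (min, max) with min < max")
  total_excl <- sum(unlist(exclusions))
  if (total_excl >= n_participants) stop("exclusions exceed cohort size")
  structure(list(n_participants = as.integer(n_participants),
                 frac_female = frac_female, age_range = age_range,
                 age_mean = age_mean,
                 zero_fraction_alcohol = zero_fraction_alcohol,
                 zero_fraction_smoking = zero_fraction_smoking,
                 exposure_targets = exposure_targets,
                 exclusions = exclusions, seed = as.integer(seed)),
            class = "cohort_spec")
}

# gamma parameters of the positive part of a zero-inflated variable whose
# overall mean/sd are given
zi_gamma_params <- function(mean, sd, zero_fraction) {
  pnz <- 1 - zero_fraction
  m_pos <- mean / pnz
  v_pos <- (sd^2 + mean^2) / pnz - m_pos^2
  if (v_pos <= 0) v_pos <- m_pos^2  # fall back to exponential-like skew
  list(shape = m_pos^2 / v_pos, scale = v_pos / m_pos)
}

#' Generate a synthetic cohort table
#'
#' Produces a wide per-participant table of raw questionnaire items
#' (beverages with pure-alcohol grams and drinking frequencies, smoking years
#' and cigarettes per day, social-index components, activity list with MET
#' values and hours), demographics (age, gender coded 1 = female), BDI-II and
#' ISCED, and quality-control flags. Alcohol and smoking are zero-inflated
#' with gamma-distributed positive parts whose moments match the exposure
#' targets. Planted outliers receive exposures orders of magnitude beyond the
#' published maxima so a +/-3 SD score rule flags exactly those participants.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per participant; planted flags in columns
#'   `excl_incidental`, `excl_imaging`, `planted_outlier`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  tg <- spec$exposure_targets

  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, 6.6),
                   spec$age_range[1L]), spec$age_range[2L])
  gender <- stats::rbinom(n, 1L, spec$frac_female)

  # alcohol: zero-inflated gamma, represented as up to 3 beverage slots
  gp_alc <- zi_gamma_params(tg$alcohol[["mean"]], tg$alcohol[["sd"]],
                            spec$zero_fraction_alcohol)
  drinks <- stats::rbinom(n, 1L, 1 - spec$zero_fraction_alcohol) == 1L
  alc_total <- ifelse(drinks,
                      stats::rgamma(n, shape = gp_alc$shape, scale = gp_alc$scale), 0)
  bev_g <- matrix(0, n, 5L)
  bev_f <- matrix(0, n, 5L)
  n_bev <- ifelse(drinks, sample(1:3, n, replace = TRUE), 0L)
  for (i in which(drinks)) {
    k <- n_bev[i]
    share <- as.numeric(stats::rmultinom(1L, 100L, rep(1, k))) / 100
    freq <- sample(1:12, k, replace = TRUE)
    bev_f[i, seq_len(k)] <- freq
    bev_g[i, seq_len(k)] <- alc_total[i] * share / freq
  }

  # smoking: zero-inflated cigarette-years split into years x CPD
  gp_smo <- zi_gamma_params(tg$smoking[["mean"]], tg$smoking[["sd"]],
                            spec$zero_fraction_smoking)
  smokes <- stats::rbinom(n, 1L, 1 - spec$zero_fraction_smoking) == 1L
  cigyears <- ifelse(smokes,
                     stats::rgamma(n, shape = gp_smo$shape, scale = gp_smo$scale), 0)
  smoking_years <- ifelse(smokes, pmin(round(stats::runif(n, 5, 40)), age - 18), 0)
  cigarettes_per_day <- ifelse(smokes, cigyears / pmax(smoking_years, 1), 0)

  # social integration components (Berkman-style index ~ mean 12.7, SD ~ 5.7)
  married <- stats::rbinom(n, 1L, 0.62)
  n_children <- stats::rnbinom(n, size = 2, mu = 2)
  n_close_relatives <- stats::rnbinom(n, size = 2, mu = 4)
  n_friends <- stats::rnbinom(n, size = 2, mu = 4.3)
  n_memberships <- stats::rpois(n, 1.1)

  # physical activity: mostly active, gamma total MET.h split over activities
  gp_met <- zi_gamma_params(tg$met[["mean"]], tg$met[["sd"]], 0.05)
  active <- stats::rbinom(n, 1L, 0.95) == 1L
  met_total <- ifelse(active,
                      stats::rgamma(n, shape = gp_met$shape, scale = gp_met$scale), 0)
  act_m <- matrix(0, n, 8L)
  act_h <- matrix(0, n, 8L)
  n_act <- ifelse(active, sample(1:4, n, replace = TRUE), 0L)
  met_values <- c(3, 3.5, 4, 5, 6, 7, 8)
  for (i in which(active)) {
    k <- n_act[i]
    share <- as.numeric(stats::rmultinom(1L, 100L, rep(1, k))) / 100
    mv <- sample(met_values, k, replace = TRUE)
    act_m[i, seq_len(k)] <- mv
    act_h[i, seq_len(k)] <- met_total[i] * share / mv
  }

  bdi <- stats::rnbinom(n, size = 2, mu = 6)
  isced <- sample(3:8, n, replace = TRUE, prob = c(0.1, 0.25, 0.15, 0.25, 0.15, 0.1))

  cohort <- data.frame(id = sprintf("P%04d", seq_len(n)), age = age,
                       gender = gender, bdi = bdi, isced = isced,
                       smoking_years = smoking_years,
                       cigarettes_per_day = cigarettes_per_day,
                       married = married, n_children = n_children,
                       n_close_relatives = n_close_relatives,
                       n_friends = n_friends, n_memberships = n_memberships)
  colnames(bev_g) <- sprintf("beverage_%d_grams", 1:5)
  colnames(bev_f) <- sprintf("beverage_%d_freq", 1:5)
  colnames(act_m) <- sprintf("activity_%d_met", 1:8)
  colnames(act_h) <- sprintf("activity_%d_hours", 1:8)
  cohort <- cbind(cohort, bev_g, bev_f, act_m, act_h)

  # planted exclusions: disjoint sets, drawn in the ledger's order
  ex <- spec$exclusions
  pool <- sample(seq_len(n))
  take <- function(k) {
    out <- utils::head(pool, k)
    pool <<- utils::tail(pool, length(pool) - k)
    out
  }
  cohort$excl_incidental <- FALSE
  cohort$excl_imaging <- FALSE
  cohort$planted_outlier <- FALSE
  cohort$excl_incidental[take(ex$incidental %||% 0L)] <- TRUE
  cohort$excl_imaging[take(ex$imaging %||% 0L)] <- TRUE
  miss <- take(ex$missing_behavior %||% 0L)
  cohort$smoking_years[miss] <- NA
  out_idx <- take(ex$outliers %||% 0L)
  if (length(out_idx)) {
    cohort$planted_outlier[out_idx] <- TRUE
    # risk exposures far beyond the published maxima, protective behaviours at
    # the sample minimum: the planted score is pinned at the sample maximum,
    # well past mean + 3 SD, while all natural scores are compressed inside
    cohort$beverage_1_grams[out_idx] <- 3000
    cohort$beverage_1_freq[out_idx] <- 10
    cohort[out_idx, sprintf("beverage_%d_grams", 2:5)] <- 0
    cohort[out_idx, sprintf("beverage_%d_freq", 2:5)] <- 0
    cohort$smoking_years[out_idx] <- 50
    cohort$cigarettes_per_day[out_idx] <- 40
    cohort$married[out_idx] <- 0L
    cohort$n_children[out_idx] <- 0L
    cohort$n_close_relatives[out_idx] <- 0L
    cohort$n_friends[out_idx] <- 0L
    cohort$n_memberships[out_idx] <- 0L
    cohort[out_idx, sprintf("activity_%d_met", 1:8)] <- 0
    cohort[out_idx, sprintf("activity_%d_hours", 1:8)] <- 0
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planted effect configuration for the generators
#'
#' Magnitudes are chosen once to emulate weak but detectable population-level
#' effects of the kind the analysis targets: a surface cluster where the field
#' decreases by `surface_slope` per score unit, a subcortical structure with a
#' target partial correlation of 0.15, and a seed-target connectivity slope of
#' 0.05 Fisher-z units per predictor unit.
#'
#' @param cluster_vertices vertex indices of the planted surface cluster
#'   (connected on the mesh), or NULL for a null dataset.
#' @param surface_slope field change per score unit inside the cluster.
#' @param noise_sd,noise_fwhm surface noise SD and smoothness (mm).
#' @param subcortical_structure,subcortical_rho structure label and target
#'   partial correlation.
#' @param connectivity_slope Fisher-z change per predictor unit.
#' @param baseline mean field level (local gyrification index scale).
#' @return List of class `planted_effects`.
#' @export
planted_effects <- function(cluster_vertices = NULL, surface_slope = -0.5,
                            noise_sd = 1, noise_fwhm = 3,
                            subcortical_structure = "hippocampus_left",
                            subcortical_rho = 0.15,
                            connectivity_slope = 0.05,
                            baseline = 2.5) {
  if (abs(subcortical_rho) >= 1) stop("|target partial correlation| must be < 1")
  structure(list(cluster_vertices = cluster_vertices,
                 surface_slope = surface_slope, noise_sd = noise_sd,
                 noise_fwhm = noise_fwhm,
                 subcortical_structure = subcortical_structure,
                 subcortical_rho = subcortical_rho,
                 connectivity_slope = connectivity_slope,
                 baseline = baseline),
            class = "planted_effects")
}

#' Connected vertex disk on a mesh
#'
#' Grows a connected patch from a center vertex by breadth-first adjacency,
#' restricted to vertices within `radius` mm of the center; a convenient way
#' to define a planted cluster that is guaranteed edge-connected.
#'
#' @param mesh a [triangle_mesh()].
#' @param center_vertex 1-based vertex index.
#' @param radius mm.
#' @return Integer vertex indices (includes the center).
#' @export
mesh_disk <- function(mesh, center_vertex, radius) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- nrow(mesh$vertices)
  if (center_vertex < 1L || center_vertex > n) stop("center vertex out of range")
  c0 <- mesh$vertices[center_vertex, ]
  d2 <- rowSums(sweep(mesh$vertices, 2L, c0)^2)
  ok <- d2 <= radius^2 + 1e-9
  visited <- logical(n)
  queue <- center_vertex
  visited[center_vertex] <- TRUE
  acc <- integer(0)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    acc <- c(acc, u)
    nb <- mesh$adjacency[[u]]
    nb <- nb[ok[nb] & !visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sort(acc)
}

#' Generate per-participant surface fields with a planted cluster
#'
#' Each participant's field is `baseline + slope * score * 1(cluster)` plus
#' spatially smoothed Gaussian noise (iterated neighbour averaging to the
#' target FWHM, rescaled so each map's noise SD equals `noise_sd`), noise
#' independent across participants.
#'
#' @param mesh a [triangle_mesh()].
#' @param scores numeric vector, one score per participant.
#' @param effects a [planted_effects()]; `cluster_vertices = NULL` gives pure
#'   noise fields.
#' @param seed RNG seed.
#' @return Matrix, participants x vertices.
#' @export
generate_surface_data <- function(mesh, scores, effects = planted_effects(),
                                  seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(effects, "planted_effects"))
  nv <- nrow(mesh$vertices)
  cl <- effects$cluster_vertices
  if (!is.null(cl) && (any(cl < 1L) || any(cl > nv)))
    stop("cluster vertices outside the mesh")
  k <- if (effects$noise_fwhm > 0)
    smoothing_iterations(mesh, effects$noise_fwhm, seed = seed) else 0L
  set.seed(seed)
  n <- length(scores)
  noise <- matrix(stats::rnorm(nv * n), nrow = nv)
  if (k > 0L) noise <- mesh_smooth(mesh, noise, k)
  if (effects$noise_sd > 0) {
    sds <- apply(noise, 2L, stats::sd)
    noise <- sweep(noise, 2L, sds / effects$noise_sd, `/`)
  } else {
    noise[] <- 0
  }
  fields <- matrix(effects$baseline, n, nv) + t(noise)
  if (!is.null(cl) && effects$surface_slope != 0)
    fields[, cl] <- fields[, cl] + effects$surface_slope * scores
  fields
}

#' Generate subcortical volume tables with a planted association
#'
#' Volumes for the default 20-structure roster (10 per hemisphere:
#' hippocampus, amygdala, thalamus, putamen, globus pallidus, caudate,
#' accumbens and three cingulate segments) are built from structure-specific
#' baselines, additive age/gender/TIV components and Gaussian noise. One
#' structure optionally carries a planted partial correlation with the
#' supplied score after the covariates are controlled.
#'
#' @param scores numeric score vector.
#' @param covariates data.frame with `age`, `gender` and `tiv`.
#' @param effects a [planted_effects()] (uses `subcortical_structure` and
#'   `subcortical_rho`); NULL plants nothing.
#' @param structures character roster of structure labels (default 20).
#' @param seed RNG seed.
#' @return data.frame, participants x structures (mm^3).
#' @export
generate_volumes <- function(scores, covariates, effects = planted_effects(),
                             structures = default_structures(), seed = 1L) {
  n <- length(scores)
  stopifnot(nrow(covariates) == n)
  set.seed(seed)
  base <- stats::setNames(stats::runif(length(structures), 1500, 8000), structures)
  out <- data.frame(row.names = seq_len(n))
  agec <- scale(covariates$age)
  tivc <- scale(covariates$tiv)
  zs <- scale(scores)
  for (st in structures) {
    noise <- stats::rnorm(n)
    signal <- noise
    if (!is.null(effects) && identical(st, effects$subcortical_structure)) {
      rho <- effects$subcortical_rho
      signal <- rho * drop(zs) + sqrt(1 - rho^2) * noise
    }
    out[[st]] <- base[[st]] * (1 - 0.02 * drop(agec)) +
      150 * covariates$gender + 0.002 * base[[st]] * drop(tivc) * 100 +
      0.08 * base[[st]] * signal
  }
  out
}

#' @rdname generate_volumes
#' @export
default_structures <- function() {
  kinds <- c("hippocampus", "amygdala", "thalamus", "putamen",
             "globus_pallidus", "caudate", "accumbens",
             "cingulate_anterior", "cingulate_mid_anterior",
             "cingulate_posterior")
  as.vector(outer(kinds, c("left", "right"), paste, sep = "_"))
}

#' Generate BOLD-like time series with a planted connectivity slope
#'
#' For each participant, seed-region voxels share a latent signal; a target
#' region's voxels correlate with that latent signal at
#' `tanh(z0 + slope * predictor)`, so the participant's seed-target Fisher-z
#' connectivity increases linearly in the predictor. Remaining voxels are
#' noise. Six random-walk motion parameters and three tissue mean signals
#' contaminate all voxels and are returned as confounds.
#'
#' @param predictor per-participant predictor (risk score or pack years).
#' @param effects a [planted_effects()] (uses `connectivity_slope`).
#' @param n_timepoints frames per run (>= 50; default 300).
#' @param tr_seconds repetition time (default 2.2).
#' @param grid voxel grid (default 6 x 6 x 3 at 5 mm spacing).
#' @param z0 baseline Fisher-z connectivity (default 0.3).
#' @param seed RNG seed.
#' @return List of class `timeseries_set`: `bundles` (one
#'   [timeseries_bundle()] per participant), `seed_center` (mm), `seed_voxels`,
#'   `target_voxels`, `predictor`, `z0`, `slope`.
#' @export
generate_timeseries <- function(predictor, effects = planted_effects(),
                                n_timepoints = 300L, tr_seconds = 2.2,
                                grid = list(dim = c(6L, 6L, 3L), spacing = 5,
                                            origin = c(0, 0, 0)),
                                z0 = 0.3, seed = 1L) {
  if (n_timepoints < 50L) stop("'n_timepoints' must be >= 50")
  if (tr_seconds <= 0) stop("'tr_seconds' must be positive")
  set.seed(seed)
  nvox <- prod(grid$dim)
  seed_center <- grid$origin + c(1, 1, 1) * grid$spacing
  voi <- voi_from_sphere(seed_center, radius = grid$spacing, grid = grid)
  seed_vox <- voi$voxels
  # target region: a compact block in the opposite grid corner
  target_center <- grid$origin + (grid$dim - 2L) * grid$spacing
  target_vox <- voi_from_sphere(target_center, radius = grid$spacing, grid = grid)$voxels
  target_vox <- setdiff(target_vox, seed_vox)
  slope <- effects$connectivity_slope
  n <- length(predictor)
  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    Tn <- n_timepoints
    latent <- stats::rnorm(Tn)
    r_i <- tanh(z0 + slope * predictor[i])
    r_i <- pmax(pmin(r_i, 0.99), -0.99)
    X <- matrix(stats::rnorm(Tn * nvox), Tn, nvox)
    X[, seed_vox] <- latent + 0.1 * X[, seed_vox]
    X[, target_vox] <- r_i * latent + sqrt(1 - r_i^2) * X[, target_vox]
    motion <- apply(matrix(stats::rnorm(Tn * 6L, sd = 0.02), Tn, 6L), 2L, cumsum)
    tissue <- matrix(stats::rnorm(Tn * 3L, sd = 0.5), Tn, 3L)
    X <- X + motion %*% matrix(stats::runif(6L * nvox, -0.2, 0.2), 6L, nvox) +
      tissue %*% matrix(stats::runif(3L * nvox, -0.1, 0.1), 3L, nvox)
    bundles[[i]] <- timeseries_bundle(X, tr_seconds, motion, tissue, grid)
  }
  structure(list(bundles = bundles, seed_center = seed_center,
                 seed_voxels = seed_vox, target_voxels = target_vox,
                 predictor = predictor, z0 = z0, slope = slope, grid = grid),
            class = "timeseries_set")
}

#' Generate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages in \{0, 1, 2\} of the effect allele are drawn as binomial(2, maf)
#' per SNP, i.e. under Hardy-Weinberg proportions.
#'
#' @param panel SNP panel data.frame (needs `rsid`; `maf_cohort` used as the
#'   default allele frequency when `mafs` is NULL).
#' @param n number of participants.
#' @param mafs per-SNP minor-allele frequencies in (0, 0.5], recycled; NULL
#'   uses `panel$maf_cohort` or 0.3.
#' @param seed RNG seed.
#' @return Integer matrix, participants x SNPs, rsids as column names.
#' @export
generate_genotypes <- function(panel, n, mafs = NULL, seed = 1L) {
  rsids <- panel$rsid
  if (is.null(mafs)) {
    mafs <- if (!is.null(panel$maf_cohort)) panel$maf_cohort else rep(0.3, length(rsids))
  }
  mafs <- rep(mafs, length.out = length(rsids))
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  set.seed(seed)
  D <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1L) D <- matrix(D, nrow = 1L)
  colnames(D) <- rsids
  D
}
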