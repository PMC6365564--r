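#' @title Seed-based resting-state functional connectivity
#' @description Per-participant pipeline (frame discard, nuisance regression
#'   with first- and second-order confound terms, band-pass filtering, seed
#'   eigenvariate extraction, voxel-wise Fisher-z maps) and second-level
#'   cluster-corrected regression of connectivity on a lifestyle risk score.
#' @name rsfc
NULL

#' Bundle of voxel time series with acquisition metadata
#'
#' @param voxels numeric matrix, timepoints x voxels (BOLD-like signal).
#' @param tr repetition time in seconds (> 0).
#' @param motion timepoints x 6 realignment parameters.
#' @param tissue timepoints x 3 mean tissue signals (GM, WM, CSF).
#' @param grid voxel grid geometry: list with `dim` (3 integers), `spacing`
#'   (mm, scalar or length 3) and `origin` (mm coordinate of voxel (1,1,1)).
#' @return Object of class `timeseries_bundle`.
#' @export
timeseries_bundle <- function(voxels, tr, motion, tissue, grid) {
  voxels <- as.matrix(voxels)
  if (tr <= 0) stop("'tr' must be positive")
  if (nrow(voxels) < 50L) stop("need at least 50 timepoints")
  motion <- as.matrix(motion)
  tissue <- as.matrix(tissue)
  if (nrow(motion) != nrow(voxels) || ncol(motion) != 6L)
    stop("'motion' must be timepoints x 6")
  if (nrow(tissue) != nrow(voxels) || ncol(tissue) != 3L)
    stop("'tissue' must be timepoints x 3 (GM, WM, CSF)")
  grid$spacing <- rep(grid$spacing, length.out = 3L)
  if (prod(grid$dim) != ncol(voxels))
    stop("grid dim does not match voxel count")
  structure(list(voxels = voxels, tr = tr, motion = motion, tissue = tissue,
                 grid = grid),
            class = "timeseries_bundle")
}

#' @export
print.timeseries_bundle <- function(x, ...) {
  cat(sprintf("timeseries_bundle: %d timepoints x %d voxels, TR %.2f s, grid %s\n",
              nrow(x$voxels), ncol(x$voxels), x$tr,
              paste(x$grid$dim, collapse = "x")))
  invisible(x)
}

#' Nuisance regression with first- and second-order confound terms
#'
#' Builds the confound set: the six motion parameters, their first derivatives
#' (backward differences, zero-padded at the first frame), and the three mean
#' tissue signals. Each confound is standardized, then entered both linearly
#' and squared (second-order terms computed after standardization), plus an
#' intercept. Per-voxel OLS residuals are returned.
#'
#' @param ts a [timeseries_bundle()].
#' @return The bundle with `voxels` replaced by the residual series.
#' @export
nuisance_regress <- function(ts) {
  stopifnot(inherits(ts, "timeseries_bundle"))
  deriv <- rbind(0, diff(ts$motion))
  base <- cbind(ts$motion, deriv, ts$tissue)
  keep <- apply(base, 2L, stats::sd) > 0
  base <- scale(base[, keep, drop = FALSE])
  X <- cbind(1, base, base^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # drop linearly dependent confound columns rather than failing the run
    pivot_drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("rank-deficient confound design; dropping ",
            length(pivot_drop), " column(s)")
    X <- X[, -pivot_drop, drop = FALSE]
    qrX <- qr(X)
  }
  ts$voxels <- qr.resid(qrX, ts$voxels)
  ts
}

#' Band-pass filter for BOLD series
#'
#' Zero-phase ideal (frequency-domain) band-pass: the series are demeaned,
#' Fourier transformed, components outside `[low, high]` Hz are set to zero,
#' and the series reconstructed. Passband gain is exactly 1 and stopband
#' attenuation complete up to spectral leakage; there is no phase distortion.
#'
#' @param series numeric vector or timepoints x voxels matrix.
#' @param tr repetition time in seconds.
#' @param low,high passband edges in Hz (defaults 0.01 and 0.08); `high` must
#'   be below the Nyquist frequency 1/(2 TR).
#' @return Filtered series, same shape.
#' @export
bandpass <- function(series, tr, low = 0.01, high = 0.08) {
  if (tr <= 0) stop("'tr' must be positive")
  nyquist <- 1 / (2 * tr)
  if (low < 0 || high <= low) stop("need 0 <= low < high")
  if (high > nyquist) stop(sprintf("'high' exceeds Nyquist (%.3f Hz)", nyquist))
  vec <- is.null(dim(series))
  X <- if (vec) matrix(series, ncol = 1L) else as.matrix(series)
  Tn <- nrow(X)
  X <- sweep(X, 2L, colMeans(X))
  freqs <- (seq_len(Tn) - 1L) / (Tn * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum
  keep <- freqs >= low & freqs <= high
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0
  out <- Re(stats::mvfft(Xf, inverse = TRUE)) / Tn
  if (vec) drop(out) else out
}

#' Spherical seed volume of interest
#'
#' Selects all voxels whose center lies within `radius` mm (Euclidean) of the
#' given center coordinate.
#'
#' @param center mm coordinate (length 3), e.g. an MNI peak.
#' @param radius sphere radius in mm (default 5).
#' @param grid voxel grid geometry (see [timeseries_bundle()]).
#' @return Object of class `seed_voi`: list with `center`, `radius`, `voxels`
#'   (linear indices, column-major) and `coords` (member voxel centers, mm).
#' @export
voi_from_sphere <- function(center, radius = 5, grid) {
  if (radius < 0) stop("'radius' must be >= 0")
  spacing <- rep(grid$spacing, length.out = 3L)
  dims <- grid$dim
  lo <- grid$origin
  hi <- grid$origin + (dims - 1L) * spacing
  if (any(center < lo - spacing / 2) || any(center > hi + spacing / 2))
    stop("seed center outside the voxel grid")
  idx <- as.matrix(expand.grid(i = seq_len(dims[1L]), j = seq_len(dims[2L]),
                               k = seq_len(dims[3L])))
  coords <- sweep(sweep(idx - 1, 2L, spacing, `*`), 2L, lo, `+`)
  d2 <- rowSums(sweep(coords, 2L, center)^2)
  members <- which(d2 <= radius^2 + 1e-9)
  if (!length(members)) stop("no voxel center within the sphere")
  structure(list(center = center, radius = radius, voxels = members,
                 coords = coords[members, , drop = FALSE]),
            class = "seed_voi")
}

#' First eigenvariate of a voxel set
#'
#' The representative time course of a seed region: the leading left singular
#' vector of the centered member-voxel matrix, scaled by the leading singular
#' value over the square root of the voxel count, with the sign chosen to
#' correlate positively with the mean series of the region.
#'
#' @param voxel_series timepoints x member-voxels matrix (>= 1 column).
#' @return Numeric time series of length timepoints.
#' @export
extract_eigenvariate <- function(voxel_series) {
  X <- as.matrix(voxel_series)
  if (ncol(X) < 1L) stop("empty VOI")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 1L, nv = 0L)
  e <- sv$u[, 1L] * sv$d[1L] / sqrt(ncol(X))
  mref <- rowMeans(Xc)
  if (sum(e * mref) < 0) e <- -e
  e
}

#' Seed-to-voxel functional connectivity map
#'
#' Pearson correlation between the seed series and every voxel series, with
#' Fisher z = arctanh(r). Correlations of exactly +/-1 are clipped to
#' +/-(1 - 1e-7) before the transform; zero-variance voxels are masked (NA)
#' and their indices recorded.
#'
#' @param seed_series seed time course (e.g. from [extract_eigenvariate()]).
#' @param voxel_series timepoints x voxels matrix.
#' @param seed_voxels optional indices of seed-member voxels, flagged in the
#'   output.
#' @return Object of class `fc_map`: list with `r`, `z`, `masked` (indices of
#'   zero-variance voxels) and `seed_voxels`.
#' @export
seed_fc <- function(seed_series, voxel_series, seed_voxels = integer(0)) {
  X <- as.matrix(voxel_series)
  if (length(seed_series) != nrow(X)) stop("time dimensions differ")
  sdv <- apply(X, 2L, stats::sd)
  r <- rep(NA_real_, ncol(X))
  ok <- sdv > 0 & stats::sd(seed_series) > 0
  if (any(ok)) r[ok] <- drop(stats::cor(seed_series, X[, ok, drop = FALSE]))
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
  structure(list(r = r, z = z, masked = as.integer(which(!ok)),
                 seed_voxels = as.integer(seed_voxels)),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("fc_map: %d voxels, mean z = %.3f, %d masked\n",
              length(x$z), mean(x$z, na.rm = TRUE), length(x$masked)))
  invisible(x)
}

# neighbour offsets for voxel-lattice connectivity
lattice_offsets <- function(connectivity = 18L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# connected components of a voxel index set on a dims lattice
lattice_components <- function(members, dims, connectivity = 18L) {
  if (!length(members)) return(list())
  offs <- lattice_offsets(connectivity)
  nxy <- dims[1L] * dims[2L]
  inset <- logical(prod(dims))
  inset[members] <- TRUE
  visited <- logical(prod(dims))
  to_ijk <- function(v) {
    v0 <- v - 1L
    cbind(v0 %% dims[1L] + 1L, (v0 %/% dims[1L]) %% dims[2L] + 1L,
          v0 %/% nxy + 1L)
  }
  comps <- list()
  for (v in members) {
    if (visited[v]) next
    queue <- v; visited[v] <- TRUE
    acc <- integer(0)
    while (length(queue)) {
      u <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      acc <- c(acc, u)
      ijk <- to_ijk(u)
      nb <- sweep(offs, 2L, as.numeric(ijk), `+`)
      okn <- nb[, 1L] >= 1 & nb[, 1L] <= dims[1L] &
             nb[, 2L] >= 1 & nb[, 2L] <= dims[2L] &
             nb[, 3L] >= 1 & nb[, 3L] <= dims[3L]
      nb <- nb[okn, , drop = FALSE]
      lin <- (nb[, 3L] - 1L) * nxy + (nb[, 2L] - 1L) * dims[1L] + nb[, 1L]
      lin <- lin[inset[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
    comps[[length(comps) + 1L]] <- sort(acc)
  }
  comps
}

#' Second-level regression of Fisher-z maps with cluster FWE correction
#'
#' Per-voxel OLS of participants' Fisher-z connectivity maps on the predictor
#' plus covariates; supra-threshold voxels (two-sided cluster-forming p,
#' default 0.001) are grouped into clusters by lattice connectivity (default
#' 18-neighbourhood), and cluster-level familywise p-values are computed from
#' a permutation max-cluster-size null (predictor permuted, covariates fixed;
#' positive and negative effects clustered separately, one pooled null).
#'
#' @param zmaps matrix, participants x voxels, of Fisher-z values.
#' @param predictor per-participant explanatory variable (risk score or single
#'   lifestyle variable).
#' @param covariates data.frame of covariates (age, gender, optionally PRS).
#' @param grid voxel grid geometry (see [timeseries_bundle()]).
#' @param cluster_forming_p two-sided voxel threshold (default 0.001).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param connectivity 6, 18 or 26 (default 18).
#' @return Object of class `fc_cluster_result`: `clusters` (each with `voxels`,
#'   `n_voxels`, `volume_mm3`, `peak_voxel`, `peak_t`, `sign`), `cwp`, `t`
#'   (voxel map), `slope`, `dof`, `null_max_sizes`.
#' @export
fc_second_level <- function(zmaps, predictor, covariates = NULL, grid,
                            cluster_forming_p = 0.001, n_perm = 1000L,
                            seed = 1L, connectivity = 18L) {
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  Y <- as.matrix(zmaps)
  n <- nrow(Y)
  Z <- if (is.null(covariates)) NULL else {
    Z <- as.matrix(as.data.frame(covariates))
    if ("age" %in% colnames(Z)) Z[, "age"] <- Z[, "age"] - mean(Z[, "age"])
    Z
  }
  if (n < (2L + if (is.null(Z)) 0L else ncol(Z)) + 2L)
    stop("too few participants for the second-level design")
  ft <- vertexwise_t(Y, predictor, Z)
  cutoff <- stats::qt(1 - cluster_forming_p / 2, df = ft$dof)
  dims <- grid$dim
  voxvol <- prod(rep(grid$spacing, length.out = 3L))
  collect <- function(tt) {
    members <- which(abs(tt) > cutoff)
    cl <- list()
    for (sgn in c(1, -1)) {
      ms <- members[sgn * tt[members] > 0]
      if (!length(ms)) next
      for (vs in lattice_components(ms, dims, connectivity)) {
        pk <- vs[which.max(abs(tt[vs]))]
        cl[[length(cl) + 1L]] <- list(voxels = vs, n_voxels = length(vs),
                                      volume_mm3 = length(vs) * voxvol,
                                      peak_voxel = pk, peak_t = tt[pk],
                                      sign = sgn)
      }
    }
    cl
  }
  clusters <- collect(ft$t)

  qrZ <- ft$qrZ
  Yres <- ft$Yres
  syy <- colSums(Yres^2)
  set.seed(seed)
  nullmax <- vapply(seq_len(n_perm), function(i) {
    xp <- sample(predictor)
    xres <- qr.resid(qrZ, xp)
    sxx <- sum(xres^2)
    sxy <- drop(crossprod(xres, Yres))
    rss <- pmax(syy - sxy^2 / sxx, 0)
    se <- sqrt(rss / ft$dof / sxx)
    tt <- ifelse(se > 0, (sxy / sxx) / se, 0)
    members <- which(abs(tt) > cutoff)
    if (!length(members)) return(0)
    best <- 0
    for (sgn in c(1, -1)) {
      ms <- members[sgn * tt[members] > 0]
      if (!length(ms)) next
      comps <- lattice_components(ms, dims, connectivity)
      best <- max(best, max(lengths(comps)))
    }
    best
  }, numeric(1))

  cwp <- vapply(clusters, function(cl) {
    (1 + sum(nullmax >= cl$n_voxels)) / (n_perm + 1)
  }, numeric(1))
  structure(list(clusters = clusters, cwp = cwp, t = ft$t, slope = ft$slope,
                 dof = ft$dof, cutoff = cutoff, null_max_sizes = nullmax,
                 connectivity = connectivity),
            class = "fc_cluster_result")
}

#' @export
print.fc_cluster_result <- function(x, ...) {
  cat(sprintf("fc_cluster_result: %d cluster(s), |t| cutoff %.2f, %d-connectivity\n",
              length(x$clusters), x$cutoff, x$connectivity))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %s%d voxels, peak t %.2f, cwp %.4g\n",
                if (cl$sign > 0) "+" else "-", cl$n_voxels, cl$peak_t, x$cwp[i]))
  }
  invisible(x)
}

#' Per-participant RSFC pipeline
#'
#' Fixed processing order: discard initial frames, nuisance regression,
#' band-pass filtering, seed eigenvariate extraction, seed-to-voxel
#' correlation, Fisher z.
#'
#' @param ts a [timeseries_bundle()].
#' @param voi a [voi_from_sphere()] seed.
#' @param n_discard initial frames to discard (default 4).
#' @param low,high band-pass edges in Hz.
#' @return An `fc_map` for this participant.
#' @export
rsfc_pipeline <- function(ts, voi, n_discard = 4L, low = 0.01, high = 0.08) {
  stopifnot(inherits(ts, "timeseries_bundle"), inherits(voi, "seed_voi"))
  if (n_discard > 0L) {
    keep <- -seq_len(n_discard)
    ts <- timeseries_bundle(ts$voxels[keep, , drop = FALSE], ts$tr,
                            ts$motion[keep, , drop = FALSE],
                            ts$tissue[keep, , drop = FALSE], ts$grid)
  }
  ts <- nuisance_regress(ts)
  ts$voxels <- bandpass(ts$voxels, ts$tr, low, high)
  seed_series <- extract_eigenvariate(ts$voxels[, voi$voxels, drop = FALSE])
  seed_fc(seed_series, ts$voxels, seed_voxels = voi$voxels)
}
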