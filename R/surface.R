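#' @title Vertex-wise surface inference
#' @description Mass-univariate GLM of per-vertex surface fields (local
#'   gyrification index, cortical thickness) on a lifestyle risk score with
#'   covariates, followed by cluster formation on the mesh and cluster-wise
#'   correction against a max-cluster-size null distribution obtained either by
#'   Monte-Carlo simulation of smooth Gaussian fields or by permutation of the
#'   predictor.
#' @name surface-inference
NULL

# Fast per-vertex t statistics for one predictor given fixed covariates.
# Y: n x V field matrix; x: predictor; Z: covariate matrix (without intercept).
# The predictor t in the multiple regression equals the t of the correlation
# between covariate-residualized x and covariate-residualized Y.
vertexwise_t <- function(Y, x, Z = NULL, Yres = NULL, qrZ = NULL) {
  n <- length(x)
  Zfull <- cbind(`(Intercept)` = rep(1, n), Z)
  if (is.null(qrZ)) qrZ <- qr(Zfull)
  if (qrZ$rank < ncol(Zfull)) stop("covariate design is rank deficient")
  if (is.null(Yres)) Yres <- qr.resid(qrZ, Y)
  xres <- qr.resid(qrZ, x)
  sxx <- sum(xres^2)
  if (sxx < .Machine$double.eps * n)
    stop("predictor is collinear with the covariates (zero residual variance)")
  sxy <- drop(crossprod(xres, Yres))
  slope <- sxy / sxx
  dof <- n - ncol(Zfull) - 1L
  syy <- colSums(Yres^2)
  rss <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(rss / dof / sxx)
  tt <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  list(slope = slope, t = tt, dof = dof, xres = xres, Yres = Yres,
       qrZ = qrZ, rss = rss)
}

#' Vertex-wise general linear model
#'
#' Ordinary least squares of each vertex's field values on
#' `[intercept, predictor, covariates]`. The signed t statistic of the
#' predictor is retained per vertex (the two-sided F test on the predictor is
#' `t^2` with 1 numerator df); residual maps are kept for spatial smoothness
#' estimation. Age is centered and gender should be coded 0/1 before entry.
#'
#' @param fields numeric matrix, participants x vertices.
#' @param predictor numeric vector (e.g. a combined risk score), one per
#'   participant.
#' @param covariates data.frame or matrix of nuisance covariates (age, gender,
#'   optionally PRS, BDI-II, ISCED), or NULL.
#' @return Object of class `vertex_glm`: `slope`, `t`, `F` (= t^2), `dof`,
#'   `residuals` (participants x vertices), plus the design pieces needed by
#'   [permutation_null()].
#' @export
fit_vertexwise_glm <- function(fields, predictor, covariates = NULL) {
  Y <- as.matrix(fields)
  n <- nrow(Y)
  if (length(predictor) != n) stop("one predictor value per participant required")
  Z <- if (is.null(covariates)) NULL else {
    Z <- as.matrix(as.data.frame(covariates))
    if ("age" %in% colnames(Z)) Z[, "age"] <- Z[, "age"] - mean(Z[, "age"])
    Z
  }
  p <- 2L + if (is.null(Z)) 0L else ncol(Z)
  if (n < p + 2L) stop("need at least p + 2 participants")
  X <- cbind(1, predictor, Z)
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank deficient; check predictor/covariates: ",
         paste(c("predictor", colnames(Z)), collapse = ", "))
  }
  ft <- vertexwise_t(Y, predictor, Z)
  residuals <- ft$Yres - outer(ft$xres, ft$slope)
  structure(list(slope = ft$slope, t = ft$t, F = ft$t^2, dof = ft$dof,
                 residuals = residuals, predictor = predictor, covariates = Z,
                 n = n),
            class = "vertex_glm")
}

#' @export
print.vertex_glm <- function(x, ...) {
  cat(sprintf("vertex_glm: %d participants, %d vertices, dof = %d, max |t| = %.2f\n",
              x$n, length(x$t), x$dof, max(abs(x$t))))
  invisible(x)
}

# connected components among a set of vertices, edge adjacency, BFS on a
# CSR-style adjacency index (fast enough for permutation loops)
components_in_set <- function(members, adjidx, n_vertices) {
  inset <- logical(n_vertices)
  inset[members] <- TRUE
  comp <- integer(0)
  labels <- vector("list", 0L)
  visited <- logical(n_vertices)
  nbr <- adjidx$nbr; ptr <- adjidx$ptr
  for (v in members) {
    if (visited[v]) next
    queue <- v
    visited[v] <- TRUE
    acc <- integer(0)
    while (length(queue)) {
      u <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      acc <- c(acc, u)
      nb <- nbr[(ptr[u] + 1L):ptr[u + 1L]]
      if (ptr[u + 1L] == ptr[u]) nb <- integer(0)
      nb <- nb[inset[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    labels[[length(labels) + 1L]] <- acc
  }
  labels
}

#' Form supra-threshold clusters on a mesh
#'
#' Thresholds a t map at the |t| cutoff corresponding to a two-sided
#' cluster-forming p-value at the model's residual degrees of freedom, then
#' finds edge-connected components separately within the positive and negative
#' supra-threshold sets. Cluster size is the sum of member vertex areas (mm^2).
#'
#' @param tmap signed statistic per vertex.
#' @param mesh a [triangle_mesh()].
#' @param dof residual degrees of freedom of the model behind `tmap`.
#' @param cluster_forming_p two-sided p-value threshold (default 0.05).
#' @param adjidx optional precomputed adjacency index (internal reuse).
#' @return Object of class `cluster_result`: list with `clusters` (each a list
#'   with `vertices`, `area_mm2`, `peak_vertex`, `peak_t`, `sign`), the |t|
#'   `cutoff` used, and (after [cluster_pvalues()]) `cwp` and `null_max_sizes`.
#' @export
form_clusters <- function(tmap, mesh, dof, cluster_forming_p = 0.05,
                          adjidx = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- nrow(mesh$vertices)
  if (length(tmap) != n) stop("'tmap' length must equal vertex count")
  if (is.null(adjidx)) adjidx <- mesh_adjacency_index(mesh)
  cutoff <- stats::qt(1 - cluster_forming_p / 2, df = dof)
  clusters <- list()
  for (sgn in c(1, -1)) {
    members <- which(sgn * tmap > cutoff)
    if (!length(members)) next
    comps <- components_in_set(members, adjidx, n)
    for (vs in comps) {
      pk <- vs[which.max(abs(tmap[vs]))]
      clusters[[length(clusters) + 1L]] <-
        list(vertices = sort(vs), area_mm2 = sum(mesh$vertex_area[vs]),
             peak_vertex = pk, peak_t = tmap[pk], sign = sgn)
    }
  }
  structure(list(clusters = clusters, cutoff = cutoff,
                 cluster_forming_p = cluster_forming_p, dof = dof),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), |t| cutoff %.3f\n",
              length(x$clusters), x$cutoff))
  if (length(x$clusters)) {
    sizes <- vapply(x$clusters, `[[`, numeric(1), "area_mm2")
    cwp <- if (!is.null(x$cwp)) sprintf(", cwp %s", format(x$cwp, digits = 3)) else ""
    for (i in order(-sizes)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  peak v%d  %s%.1f mm^2  peak t %.2f%s\n", cl$peak_vertex,
                  if (cl$sign > 0) "+" else "-", cl$area_mm2, cl$peak_t,
                  if (!is.null(x$cwp)) sprintf("  cwp %.4g", x$cwp[i]) else ""))
    }
  }
  invisible(x)
}

#' Spatial smoothness (FWHM) of residual maps
#'
#' Global FWHM estimate from the variance of residual differences across mesh
#' edges relative to the residual variance, using the Gaussian autocorrelation
#' relation rho(h) = exp(-h^2 / (2 s^2)) and FWHM = s * sqrt(8 log 2).
#' Edge statistics are pooled over participants.
#'
#' @param residuals matrix, participants x vertices (residual maps of a
#'   [fit_vertexwise_glm()]), or a single map as a vector.
#' @param mesh a [triangle_mesh()].
#' @return Estimated FWHM in mm.
#' @export
estimate_smoothness <- function(residuals, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  R <- if (is.null(dim(residuals))) matrix(residuals, nrow = 1L) else as.matrix(residuals)
  if (ncol(R) != nrow(mesh$vertices)) stop("residual maps must match vertex count")
  v <- apply(R, 1L, stats::var)
  if (any(v <= .Machine$double.eps)) stop("zero-variance residual map")
  e1 <- mesh$edges[, 1L]; e2 <- mesh$edges[, 2L]
  h2 <- rowSums((mesh$vertices[e1, , drop = FALSE] -
                 mesh$vertices[e2, , drop = FALSE])^2)
  d2 <- (R[, e1, drop = FALSE] - R[, e2, drop = FALSE])^2
  # pooled edge-variance ratio across maps: mean squared edge difference
  # relative to twice the mean map variance
  ratio <- mean(d2) / (2 * mean(v))
  rho <- min(max(1 - ratio, 1e-8), 1 - 1e-8)
  s2 <- -mean(h2) / (2 * log(rho))
  sqrt(8 * log(2)) * sqrt(s2)
}

#' Smoothing iterations matching a target FWHM
#'
#' Empirically calibrates how many neighbour-averaging passes on this mesh
#' produce white noise whose estimated FWHM is closest to the target; used by
#' the Monte-Carlo null so that simulated fields match the smoothness estimated
#' from the observed residuals.
#'
#' @param mesh a [triangle_mesh()].
#' @param fwhm target FWHM in mm (>= 0).
#' @param max_iter maximum passes explored.
#' @param n_fields white-noise fields averaged for the calibration.
#' @param seed RNG seed for the calibration fields.
#' @return Integer number of passes (0 for FWHM at or below the white-noise
#'   floor).
#' @export
smoothing_iterations <- function(mesh, fwhm, max_iter = 40L, n_fields = 6L,
                                 seed = 1L) {
  if (fwhm < 0) stop("'fwhm' must be >= 0")
  n <- nrow(mesh$vertices)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_fields), nrow = n)
  est <- numeric(max_iter + 1L)
  est[1L] <- estimate_smoothness(t(X), mesh)
  for (k in seq_len(max_iter)) {
    X <- mesh_smooth(mesh, X, 1L)
    est[k + 1L] <- estimate_smoothness(t(X), mesh)
    if (est[k + 1L] > fwhm) break
  }
  est <- est[seq_len(k + 1L)]
  which.min(abs(est - fwhm)) - 1L
}

#' Monte-Carlo null distribution of maximum cluster size
#'
#' Each iteration synthesizes a Gaussian random field on the mesh, smooths it
#' to the requested FWHM by iterated neighbour averaging, standardizes it,
#' thresholds at the two-sided cluster-forming cutoff, and records the maximum
#' cluster area in mm^2 (0 if nothing survives). Positive and negative
#' supra-threshold components are pooled into one null, matching a two-sided
#' test.
#'
#' @param mesh a [triangle_mesh()].
#' @param fwhm field smoothness in mm (e.g. from [estimate_smoothness()]).
#' @param cluster_forming_p two-sided cluster-forming p-value.
#' @param n_iter iterations; fewer than 100 triggers a tail-instability
#'   warning.
#' @param seed RNG seed.
#' @return Numeric vector of `n_iter` maximum cluster areas.
#' @export
monte_carlo_null <- function(mesh, fwhm, cluster_forming_p = 0.05,
                             n_iter = 10000L, seed = 1L) {
  if (fwhm < 0) stop("'fwhm' must be >= 0")
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  if (n_iter < 100L) warning("n_iter < 100: unstable null tail")
  k <- smoothing_iterations(mesh, fwhm, seed = seed)
  n <- nrow(mesh$vertices)
  adjidx <- mesh_adjacency_index(mesh)
  cutoff <- stats::qnorm(1 - cluster_forming_p / 2)
  set.seed(seed)
  vapply(seq_len(n_iter), function(i) {
    f <- stats::rnorm(n)
    if (k > 0) f <- mesh_smooth(mesh, f, k)
    f <- (f - mean(f)) / stats::sd(f)
    members <- which(abs(f) > cutoff)
    if (!length(members)) return(0)
    best <- 0
    for (sgn in c(1, -1)) {
      ms <- members[sgn * f[members] > 0]
      if (!length(ms)) next
      comps <- components_in_set(ms, adjidx, n)
      best <- max(best, vapply(comps, function(vs) sum(mesh$vertex_area[vs]),
                               numeric(1)))
    }
    best
  }, numeric(1))
}

#' Permutation null distribution of maximum cluster size
#'
#' Permutes the predictor across participants (covariates fixed), refits the
#' vertex-wise GLM, re-forms clusters at the same cluster-forming threshold,
#' and records the maximum cluster area per iteration (pooled over signs).
#'
#' @inheritParams fit_vertexwise_glm
#' @param mesh a [triangle_mesh()].
#' @param cluster_forming_p two-sided cluster-forming p-value.
#' @param n_iter number of permutations (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of `n_iter` maximum cluster areas.
#' @export
permutation_null <- function(fields, predictor, covariates = NULL, mesh,
                             cluster_forming_p = 0.05, n_iter = 10000L,
                             seed = 1L) {
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  Y <- as.matrix(fields)
  n <- nrow(Y)
  Z <- if (is.null(covariates)) NULL else {
    Z <- as.matrix(as.data.frame(covariates))
    if ("age" %in% colnames(Z)) Z[, "age"] <- Z[, "age"] - mean(Z[, "age"])
    Z
  }
  Zfull <- cbind(rep(1, n), Z)
  qrZ <- qr(Zfull)
  Yres <- qr.resid(qrZ, Y)
  dof <- n - ncol(Zfull) - 1L
  cutoff <- stats::qt(1 - cluster_forming_p / 2, df = dof)
  adjidx <- mesh_adjacency_index(mesh)
  nv <- ncol(Y)
  area <- mesh$vertex_area
  syy <- colSums(Yres^2)
  set.seed(seed)
  vapply(seq_len(n_iter), function(i) {
    xp <- sample(predictor)
    xres <- qr.resid(qrZ, xp)
    sxx <- sum(xres^2)
    sxy <- drop(crossprod(xres, Yres))
    rss <- pmax(syy - sxy^2 / sxx, 0)
    se <- sqrt(rss / dof / sxx)
    tt <- ifelse(se > 0, (sxy / sxx) / se, 0)
    members <- which(abs(tt) > cutoff)
    if (!length(members)) return(0)
    best <- 0
    for (sgn in c(1, -1)) {
      ms <- members[sgn * tt[members] > 0]
      if (!length(ms)) next
      comps <- components_in_set(ms, adjidx, nv)
      best <- max(best, vapply(comps, function(vs) sum(area[vs]), numeric(1)))
    }
    best
  }, numeric(1))
}

#' Cluster-wise p-values from a max-size null distribution
#'
#' For each observed cluster, cwp = (1 + #\{null maxima >= observed size\}) /
#' (n_iter + 1), the standard add-one permutation estimator, bounded below by
#' 1 / (n_iter + 1).
#'
#' @param observed a [form_clusters()] result.
#' @param null_max_sizes numeric vector of null maximum cluster sizes.
#' @return The `cluster_result` with `cwp` (per cluster) and `null_max_sizes`
#'   attached.
#' @export
cluster_pvalues <- function(observed, null_max_sizes) {
  stopifnot(inherits(observed, "cluster_result"))
  if (!length(null_max_sizes)) stop("empty null distribution")
  m <- length(null_max_sizes)
  observed$cwp <- vapply(observed$clusters, function(cl) {
    (1 + sum(null_max_sizes >= cl$area_mm2)) / (m + 1)
  }, numeric(1))
  observed$null_max_sizes <- null_max_sizes
  observed
}

#' Extract per-participant field values at a peak vertex
#'
#' @param fields matrix, participants x vertices.
#' @param vertex 1-based vertex index (e.g. a cluster's `peak_vertex`).
#' @return Numeric vector, one value per participant.
#' @export
extract_cluster_values <- function(fields, vertex) {
  Y <- as.matrix(fields)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > ncol(Y))
    stop("'vertex' out of range")
  Y[, vertex]
}

#' Post-hoc multiple regression with stepwise removal
#'
#' Fits the full model of `y` on all listed lifestyle predictors plus
#' covariates, then removes the predictors one at a time in the stated order,
#' recording at each step the F change and R^2 change relative to the model
#' before the removal. Mirrors the "remove method" used to rank single
#' lifestyle variables as explanations of extracted cluster values.
#'
#' @param y response (e.g. extracted gyrification values at a peak vertex).
#' @param predictors data.frame of lifestyle predictors, columns in removal
#'   order.
#' @param covariates data.frame of covariates kept in every model (age,
#'   gender), or NULL.
#' @return Object of class `remove_method`: data.frame `steps` with columns
#'   `removed`, `F_change`, `p_change`, `R2_change`, `model_R2`, plus
#'   `full_model` (the initial `lm` fit) and standardized coefficients
#'   `beta_std` of the full model's predictors.
#' @export
remove_method_regression <- function(y, predictors, covariates = NULL) {
  P <- as.data.frame(predictors)
  C <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  dat <- if (is.null(C)) cbind(y = y, P) else cbind(y = y, P, C)
  rhs_all <- c(names(P), names(C))
  fit_with <- function(vars) {
    fml <- stats::reformulate(if (length(vars)) vars else "1", response = "y")
    stats::lm(fml, data = dat)
  }
  full <- fit_with(rhs_all)
  if (any(is.na(stats::coef(full)))) stop("full design is rank deficient")
  beta_std <- vapply(names(P), function(v) {
    stats::coef(full)[[v]] * stats::sd(dat[[v]]) / stats::sd(y)
  }, numeric(1))

  prev <- full
  remaining <- rhs_all
  steps <- data.frame(removed = character(0), F_change = numeric(0),
                      p_change = numeric(0), R2_change = numeric(0),
                      model_R2 = numeric(0))
  for (v in names(P)) {
    if (!v %in% remaining) stop("removal of absent variable: ", v)
    remaining <- setdiff(remaining, v)
    red <- fit_with(remaining)
    rss_prev <- sum(stats::resid(prev)^2)
    rss_red <- sum(stats::resid(red)^2)
    df_prev <- prev$df.residual
    f_change <- ((rss_red - rss_prev) / 1) / (rss_prev / df_prev)
    p_change <- stats::pf(f_change, 1, df_prev, lower.tail = FALSE)
    r2 <- function(m) summary(m)$r.squared
    steps <- rbind(steps, data.frame(
      removed = v, F_change = f_change, p_change = p_change,
      R2_change = r2(prev) - r2(red), model_R2 = r2(red)))
    prev <- red
  }
  structure(list(steps = steps, full_model = full, beta_std = beta_std),
            class = "remove_method")
}

#' @export
print.remove_method <- function(x, ...) {
  cat("remove-method regression (F/R^2 change per removal step):\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' One-stop surface analysis with cluster-wise correction
#'
#' Convenience wrapper: fits the vertex-wise GLM, forms clusters at the
#' cluster-forming threshold, builds the requested max-cluster-size null
#' (Monte-Carlo on fields smoothed to the residual FWHM, or predictor
#' permutation) and attaches cluster-wise p-values.
#'
#' @inheritParams fit_vertexwise_glm
#' @param mesh a [triangle_mesh()].
#' @param correction `"montecarlo"` or `"permutation"`.
#' @param cluster_forming_p two-sided cluster-forming p-value (default 0.05).
#' @param n_iter null iterations.
#' @param seed RNG seed for the null.
#' @return A `cluster_result` with `cwp`, plus the `vertex_glm` fit in `$glm`
#'   and the estimated residual FWHM in `$fwhm` (Monte-Carlo only).
#' @export
surface_analysis <- function(fields, predictor, covariates = NULL, mesh,
                             correction = c("montecarlo", "permutation"),
                             cluster_forming_p = 0.05, n_iter = 1000L,
                             seed = 1L) {
  correction <- match.arg(correction)
  fit <- fit_vertexwise_glm(fields, predictor, covariates)
  cl <- form_clusters(fit$t, mesh, fit$dof, cluster_forming_p)
  if (correction == "montecarlo") {
    fwhm <- estimate_smoothness(fit$residuals, mesh)
    nullmax <- monte_carlo_null(mesh, fwhm, cluster_forming_p, n_iter, seed)
    cl <- cluster_pvalues(cl, nullmax)
    cl$fwhm <- fwhm
  } else {
    nullmax <- permutation_null(fields, predictor, covariates, mesh,
                                cluster_forming_p, n_iter, seed)
    cl <- cluster_pvalues(cl, nullmax)
  }
  cl$glm <- fit
  cl
}
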