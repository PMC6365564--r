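#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both rank
#' vectors on an intercept plus the covariates by ordinary least squares
#' (covariates entered untransformed), and returns the Pearson correlation of
#' the residuals with a t-based two-sided p-value at n - 2 - k degrees of
#' freedom. With no covariates this reduces to the plain Spearman correlation,
#' and the estimate is invariant to strictly monotone transforms of `x` or `y`.
#'
#' @param x,y numeric vectors, non-constant after listwise deletion.
#' @param covariates data.frame/matrix of covariates (e.g. age, gender coded
#'   0/1, total intracranial volume), or NULL.
#' @return List of class `partial_cor`: `rho`, `p`, `n`, `dof`, `covariates`
#'   (names).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  Z <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  keep <- stats::complete.cases(cbind(x, y, Z))
  x <- x[keep]; y <- y[keep]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2L) stop("too few complete observations (n <= covariates + 2)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("'x' and 'y' must be non-constant")
  rx <- rank(x); ry <- rank(y)
  X <- cbind(rep(1, n), Z)
  qrX <- qr(X)
  ex <- qr.resid(qrX, rx)
  ey <- qr.resid(qrX, ry)
  if (sum(ex^2) == 0 || sum(ey^2) == 0)
    stop("ranks are fully explained by the covariates")
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  dof <- n - 2L - k
  tt <- rho * sqrt(dof / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = dof, lower.tail = FALSE)
  structure(list(rho = rho, p = p, n = n, dof = dof,
                 covariates = colnames(Z)),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("partial Spearman rho = %.3f, p = %.4g (n = %d%s)\n", x$rho, x$p,
              x$n, if (length(x$covariates))
                paste0(", covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Risk-model by subcortical-structure correlation screen
#'
#' Computes partial Spearman correlations between every risk score model and
#' every subcortical structure volume, controlling for the supplied covariates
#' (age, gender, total intracranial volume). Flags nominally significant cells
#' (p < alpha) and cells surviving Bonferroni correction over the number of
#' structures (alpha / n_structures, e.g. 0.05 / 20 = 0.0025).
#'
#' @param scores named list of numeric score vectors (one per risk model), all
#'   over the same participants.
#' @param volumes data.frame of structure volumes (mm^3), one column per
#'   structure, rows aligned with the scores.
#' @param covariates data.frame of covariates, same rows.
#' @param alpha nominal level (default 0.05).
#' @return data.frame of class `subcortical_screen` in long format with columns
#'   `model`, `structure`, `rho`, `p`, `nominal` and `bonferroni`; the
#'   Bonferroni threshold is attached as attribute `bonferroni_alpha`.
#' @export
correlation_matrix <- function(scores, volumes, covariates, alpha = 0.05) {
  volumes <- as.data.frame(volumes)
  n <- nrow(volumes)
  bad <- vapply(scores, function(s) length(s) != n, logical(1))
  if (any(bad)) stop("score vectors must align with volume rows")
  thr <- bonferroni_threshold(alpha, ncol(volumes))
  rows <- list()
  for (m in names(scores)) {
    for (st in names(volumes)) {
      pc <- partial_spearman(scores[[m]], volumes[[st]], covariates)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, structure = st, rho = pc$rho, p = pc$p,
        nominal = pc$p < alpha, bonferroni = pc$p < thr)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_alpha") <- thr
  class(out) <- c("subcortical_screen", class(out))
  out
}
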