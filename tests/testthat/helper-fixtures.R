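# shared fixtures built in code

# a random small grid mesh (<= max_side^2 vertices), valid by construction
random_grid_mesh <- function(max_side = 10L) {
  grid_mesh(sample(2:max_side, 1L), sample(2:max_side, 1L))
}

# independent connected-components oracle via igraph on the supra-threshold
# subgraph (different code path from the package's BFS)
igraph_components_oracle <- function(tmap, mesh, cutoff) {
  out <- list()
  for (sgn in c(1, -1)) {
    members <- which(sgn * tmap > cutoff)
    if (!length(members)) next
    e <- mesh$edges
    keep <- e[, 1] %in% members & e[, 2] %in% members
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e[keep, 1]), to = as.character(e[keep, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(members)))
    cmp <- igraph::components(g)
    for (k in seq_len(cmp$no)) {
      vs <- sort(as.integer(names(cmp$membership)[cmp$membership == k]))
      out[[length(out) + 1L]] <- vs
    }
  }
  # canonical order for comparison
  out[order(vapply(out, min, numeric(1)))]
}

cluster_vertex_sets <- function(cl) {
  sets <- lapply(cl$clusters, `[[`, "vertices")
  sets[order(vapply(sets, min, numeric(1)))]
}

# independent partial-Spearman oracle: ranks via order statistics, normal
# equations solved explicitly, correlation from scratch
partial_spearman_oracle <- function(x, y, Z = NULL) {
  rk <- function(v) {
    # average ranks from sorting, no call to rank()
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  X <- cbind(1, Z)
  beta_x <- solve(t(X) %*% X, t(X) %*% rx)
  beta_y <- solve(t(X) %*% X, t(X) %*% ry)
  ex <- rx - X %*% beta_x
  ey <- ry - X %*% beta_y
  num <- sum(ex * ey)
  num / sqrt(sum(ex^2) * sum(ey^2))
}

# direct Hardy-Weinberg chi-square oracle
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  p <- (2 * aa + ab) / (2 * n)
  if (p %in% c(0, 1)) return(list(chisq = 0, p = 1))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(aa, ab, bb) - e)^2 / e)
  list(chisq = x2, p = stats::pchisq(x2, 1, lower.tail = FALSE))
}

pair_spec <- function(vars) {
  structure(list(included = vars, label = paste(vars, collapse = "+")),
            class = "risk_model_spec")
}
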