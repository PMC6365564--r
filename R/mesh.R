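#' Triangulated surface mesh
#'
#' Construct a triangle mesh from vertex coordinates and face indices, as used
#' for vertex-wise surface analyses (gyrification, cortical thickness). Vertex
#' areas are computed as one third of the summed areas of the incident
#' triangles, the convention used when cluster extent is reported in mm^2.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return An object of class `triangle_mesh`: a list with `vertices`, `faces`,
#'   `vertex_area` (mm^2 per vertex), `edges` (unique vertex index pairs) and
#'   `adjacency` (list of neighbouring vertex indices per vertex).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("'vertices' must be an n x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L || nrow(faces) < 1L) stop("mesh needs at least 3 vertices and 1 face")
  if (any(faces < 1L) || any(faces > n)) stop("face indices outside vertex range")

  # triangle areas via cross product
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  cc <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))

  vertex_area <- numeric(n)
  for (k in 1:3) {
    va <- tapply(tri_area, faces[, k], sum)
    idx <- as.integer(names(va))
    vertex_area[idx] <- vertex_area[idx] + va / 3
  }
  if (any(vertex_area <= 0)) stop("every vertex must have at least one incident face")

  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  adjacency <- vector("list", n)
  nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
  idx <- as.integer(names(nb))
  adjacency[idx] <- lapply(nb, function(x) sort(unique(as.integer(x))))
  for (i in seq_len(n)) if (is.null(adjacency[[i]])) adjacency[[i]] <- integer(0)

  structure(list(vertices = vertices, faces = faces, vertex_area = vertex_area,
                 edges = e, adjacency = adjacency),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, total area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$vertex_area)))
  invisible(x)
}

#' Regular triangulated grid mesh
#'
#' A planar nx x ny lattice of vertices with each grid square split into two
#' triangles. Used as a desk-scale stand-in for a cortical hemisphere mesh in
#' simulations and tests.
#'
#' @param nx,ny number of vertices along each axis.
#' @param spacing vertex spacing in mm.
#' @return A [triangle_mesh()].
#' @export
grid_mesh <- function(nx, ny, spacing = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("grid_mesh needs nx >= 2 and ny >= 2")
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  vertices <- cbind((xy$x - 1) * spacing, (xy$y - 1) * spacing, 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f1 <- cbind(id(i, j), id(i + 1L, j), id(i, j + 1L))
  f2 <- cbind(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  triangle_mesh(vertices, rbind(f1, f2))
}

#' One pass of neighbour averaging on a mesh
#'
#' Each vertex value is replaced by the mean of itself and its edge neighbours.
#' Iterating this kernel yields approximately Gaussian spatial smoothing and is
#' the mesh-native smoothing primitive used throughout the surface module.
#'
#' @param mesh a [triangle_mesh()].
#' @param values numeric vector (one per vertex) or matrix (vertices x maps).
#' @param iterations number of averaging passes.
#' @return Smoothed values, same shape as the input.
#' @export
mesh_smooth <- function(mesh, values, iterations = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  vec <- is.null(dim(values))
  x <- if (vec) matrix(values, ncol = 1L) else as.matrix(values)
  n <- nrow(mesh$vertices)
  if (nrow(x) != n) stop("'values' length must match vertex count")
  if (iterations < 0L) stop("'iterations' must be >= 0")
  e1 <- mesh$edges[, 1L]; e2 <- mesh$edges[, 2L]
  deg <- tabulate(c(e1, e2), nbins = n) + 1  # + self
  for (it in seq_len(iterations)) {
    acc <- x
    for (k in seq_len(ncol(x))) {
      xs <- x[, k]
      s <- xs
      sums <- rowsum(c(xs[e2], xs[e1]), c(e1, e2), reorder = FALSE)
      idx <- as.integer(rownames(sums))
      s[idx] <- s[idx] + sums[, 1L]
      acc[, k] <- s / deg
    }
    x <- acc
  }
  if (vec) drop(x) else x
}

# neighbour sums are used in several hot loops; precompute an index structure
# once per mesh: flat neighbour vector + pointer offsets (CSR-like).
mesh_adjacency_index <- function(mesh) {
  adj <- mesh$adjacency
  lens <- lengths(adj)
  list(nbr = unlist(adj, use.names = FALSE),
       ptr = c(0L, cumsum(lens)))
}

#' Write / read a mesh in OFF format
#'
#' Plain-text Object File Format, a minimal interchange format for
#' triangulated surfaces.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @return `read_off` returns a [triangle_mesh()]; `write_off` returns the path
#'   invisibly.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1L])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3L, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE), ncol = 4L, byrow = TRUE)
  if (any(fl[, 1L] != 3)) stop("only triangle faces supported")
  triangle_mesh(verts, fl[, 2:4] + 1L)
}
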