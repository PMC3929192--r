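#' Triangle mesh container
#'
#' A `triangle_mesh` stores vertex coordinates (in mm, world space) and
#' triangular faces as 1-based vertex index triples.  All mesh operators in
#' the package (curvature, decimation, classification) expect this class.
#' File readers/writers translate to the 0-based indexing the on-disk
#' formats use.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z
#'   in mm).
#' @param faces integer matrix, one row per triangle, three columns of 1-based
#'   vertex indices.  Faces must reference valid vertices and may not repeat a
#'   vertex.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @examples
#' m <- icosphere_mesh(radius = 1, subdivisions = 0)
#' n_vertices(m)  # 12
#' n_faces(m)     # 20
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertices must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      stop("faces with repeated vertices are not allowed")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @rdname triangle_mesh
#' @param x a `triangle_mesh`.
#' @export
n_vertices <- function(x) nrow(x$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(x) nrow(x$faces)

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces, chi = %d>\n",
              n_vertices(x), n_faces(x), euler_characteristic(x)))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer matrix with two columns, each row an edge with
#'   `min < max` vertex index, one row per distinct edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# per-edge face counts, keyed like mesh_edges(); used by manifold checks
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- edge_key(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), n_vertices(mesh))
  tab <- table(key)
  as.integer(tab)
}

# encode an (a < b) pair as a double; exact for n*b + a < 2^53
edge_key <- function(a, b, n) as.numeric(a) * (n + 1) + as.numeric(b)

#' Euler characteristic V - E + F
#'
#' @param mesh a `triangle_mesh`.
#' @return integer: 2 for a topological sphere, 0 for a torus.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

#' Mesh integrity checks
#'
#' `is_edge_manifold()` tests that every edge is shared by at most two faces;
#' `is_closed()` that every edge is shared by exactly two; and
#' `is_oriented()` that face windings are consistent (each directed half-edge
#' appears at most once).  `mesh_volume()` returns the signed enclosed volume
#' (positive when closed components are wound outward).
#'
#' @param mesh a `triangle_mesh`.
#' @return logical scalar (or numeric for `mesh_volume`).
#' @export
is_edge_manifold <- function(mesh) all(edge_face_counts(mesh) <= 2L)

#' @rdname is_edge_manifold
#' @export
is_closed <- function(mesh) all(edge_face_counts(mesh) == 2L)

#' @rdname is_edge_manifold
#' @export
is_oriented <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2), drop = FALSE],
              f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  key <- edge_key(he[, 1], he[, 2], n_vertices(mesh))  # directed: a then b
  !anyDuplicated(key)
}

#' @rdname is_edge_manifold
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # divergence theorem: sum of signed tetra volumes against the origin
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Total surface area and per-face areas
#'
#' @param mesh a `triangle_mesh`.
#' @return `face_areas()`: numeric vector, one area (mm^2) per face;
#'   `mesh_area()`: their sum.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# per-face unit normals (right-hand rule on the stored winding)
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.xmin)
}

# area-weighted per-vertex normals; rows for isolated vertices are zero
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  fa <- face_areas(mesh)
  f <- mesh$faces
  nv <- n_vertices(mesh)
  out <- matrix(0, nv, 3)
  w <- fn * fa
  for (k in 1:3) {
    out[, 1] <- out[, 1] + unname(rowsum_vec(w[, 1], f[, k], nv))
    out[, 2] <- out[, 2] + unname(rowsum_vec(w[, 2], f[, k], nv))
    out[, 3] <- out[, 3] + unname(rowsum_vec(w[, 3], f[, k], nv))
  }
  len <- sqrt(rowSums(out^2))
  out / pmax(len, .Machine$double.xmin)
}

# sum `x` into bins 1..n given by `idx`; dense, zero-filled
rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Connected components of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer vector of component labels (1-based), one per vertex.
#'   Isolated vertices get their own component.
#' @export
mesh_components <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Drop small connected components
#'
#' Isosurface extraction of a noisy segmentation typically yields one large
#' surface plus disconnected debris; this keeps only components with at least
#' `min_vertices` vertices (or only the single largest one).
#'
#' @param mesh a `triangle_mesh`.
#' @param min_vertices minimum component size (vertices) to retain.
#' @return a `triangle_mesh` with vertex indices compacted.
#' @export
remove_small_components <- function(mesh, min_vertices = 1L) {
  if (min_vertices < 1L) stop("min_vertices must be >= 1")
  comp <- mesh_components(mesh)
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_vertices)
  if (length(keep_comp) == 0L)
    stop("remove_small_components: no component has >= ", min_vertices,
         " vertices")
  subset_mesh(mesh, comp %in% keep_comp)
}

#' @rdname remove_small_components
#' @export
keep_largest_component <- function(mesh) {
  comp <- mesh_components(mesh)
  sizes <- tabulate(comp)
  subset_mesh(mesh, comp == which.max(sizes))
}

# keep vertices where `keep` is TRUE plus the faces entirely inside the set
subset_mesh <- function(mesh, keep) {
  new_idx <- cumsum(keep)
  f <- mesh$faces
  fk <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(new_idx[f[fk, , drop = FALSE]], ncol = 3))
}

# one-ring vertex neighbourhoods as a list of integer vectors
vertex_rings <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  split(c(e[, 2], e[, 1]),
        factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
}

#' Shrinkage-limited mesh smoothing
#'
#' Two-factor (Taubin-style) smoothing: each iteration moves every vertex
#' toward the mean of its one-ring by `shrink_factor`, then away by
#' `inflate_factor` (negative), which removes voxelization staircase
#' artifacts while keeping the enclosed volume nearly constant.  Only vertex
#' positions change; connectivity is untouched.
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of shrink/inflate passes (0 = identity).
#' @param shrink_factor positive step toward the neighbourhood mean.
#' @param inflate_factor negative step; its magnitude slightly above
#'   `shrink_factor` compensates shrinkage.
#' @return the smoothed `triangle_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 10L, shrink_factor = 0.5,
                        inflate_factor = -0.53) {
  if (iterations < 0L) stop("iterations must be >= 0")
  if (iterations == 0L || n_faces(mesh) == 0L) return(mesh)
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, nbins = nv)
  v <- mesh$vertices
  step <- function(v, lambda) {
    mean_nb <- cbind(rowsum_vec(v[dst, 1], src, nv),
                     rowsum_vec(v[dst, 2], src, nv),
                     rowsum_vec(v[dst, 3], src, nv)) / pmax(deg, 1L)
    moved <- v + lambda * (mean_nb - v)
    moved[deg == 0L, ] <- v[deg == 0L, , drop = FALSE]
    moved
  }
  for (i in seq_len(iterations)) {
    v <- step(v, shrink_factor)
    v <- step(v, inflate_factor)
  }
  triangle_mesh(v, mesh$faces)
}

#' Rigidly transform or scale a mesh
#'
#' Convenience helpers used mainly to test invariance of the curvature
#' descriptors: `transform_mesh` applies `x -> x R^T + t`, `scale_mesh`
#' multiplies all coordinates by a scalar.
#'
#' @param mesh a `triangle_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @param s positive scalar.
#' @return transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  triangle_mesh(sweep(mesh$vertices %*% t(rotation), 2, translation, "+"),
                mesh$faces)
}

#' @rdname transform_mesh
#' @export
scale_mesh <- function(mesh, s) {
  if (s <= 0) stop("s must be positive")
  triangle_mesh(mesh$vertices * s, mesh$faces)
}
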