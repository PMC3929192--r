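#' Discrete differential-geometry operators
#'
#' Per-vertex curvature estimation on a triangle mesh using the classical
#' one-ring averaging-region operators: the cotangent formula for the mean
#' curvature normal, the angle deficit over the mixed area for Gaussian
#' curvature, principal curvatures from the two, and the Koenderink shape
#' index.  [vertex_differentials()] computes everything at once and returns
#' a tibble (one row per vertex); the individual operators are exported for
#' targeted use and testing.
#'
#' Sign convention: a convex closed surface with outward normals (a gyral
#' crest seen from outside the brain) has *negative* signed mean curvature
#' and shape index +1; concave (sulcal) regions have positive signed mean
#' curvature and shape index -1.  This is the one convention under which the
#' shape-index formula's leading minus sign, the classification table and
#' "negative values represent concave surface" agree.
#'
#' @name curvature-operators
NULL

# Per-face geometry shared by all operators: corner angles, cotangents,
# areas, obtuse flags.  Angles via atan2(|cross|, dot) for robustness on
# needle triangles; sin is floored at 1e-12 before the cotangent so
# degenerate corners give a huge but finite weight.
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  ang <- function(a, b) {            # angle between edge vectors a, b
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    atan2(sqrt(rowSums(cr^2)), rowSums(a * b))
  }
  a1 <- ang(p2 - p1, p3 - p1)
  a2 <- ang(p3 - p2, p1 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  area <- face_areas(mesh)
  if (any(area == 0))
    stop("degenerate zero-area face(s): ",
         paste(utils::head(which(area == 0), 5), collapse = ", "))
  len2 <- cbind(rowSums((p3 - p2)^2),   # edge opposite corner 1
                rowSums((p1 - p3)^2),   # opposite corner 2
                rowSums((p2 - p1)^2))   # opposite corner 3
  # aspect ratio = longest edge / triangle height over it = l^2 / (2 area)
  aspect <- pmax(len2[, 1], len2[, 2], len2[, 3]) / (2 * area)
  if (any(aspect > 1e5))
    warning("needle triangle(s) with aspect ratio > 1e5; curvature ",
            "estimates may be unreliable there")
  angles <- cbind(a1, a2, a3)
  cots <- cos(angles) / pmax(sin(angles), 1e-12)
  list(angles = angles, cots = cots, area = area, len2 = len2,
       obtuse = angles > pi / 2)
}

#' Mixed (Voronoi-corrected) vertex areas
#'
#' The per-vertex averaging region: for non-obtuse incident triangles the
#' Voronoi (circumcentric) corner area, for an obtuse triangle half its area
#' at the obtuse corner and a quarter at the others.  Mixed areas tile the
#' surface: they sum exactly to the total mesh area.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex optional single vertex index; default returns all vertices.
#' @return numeric vector of areas (mm^2), length `n_vertices(mesh)` (or 1).
#' @export
mixed_area <- function(mesh, vertex = NULL) {
  fg <- face_geometry(mesh)
  f <- mesh$faces
  nv <- n_vertices(mesh)
  contrib <- matrix(0, nrow(f), 3)
  any_obtuse <- rowSums(fg$obtuse) > 0L
  # Voronoi corner area at corner k: (1/8) (|e_j|^2 cot(theta_j) summed over
  # the two adjacent corners' opposite edges)
  for (k in 1:3) {
    o1 <- (k %% 3) + 1L
    o2 <- ((k + 1L) %% 3) + 1L
    vor <- (fg$len2[, o1] * fg$cots[, o1] + fg$len2[, o2] * fg$cots[, o2]) / 8
    contrib[, k] <- ifelse(any_obtuse,
                           ifelse(fg$obtuse[, k], fg$area / 2, fg$area / 4),
                           vor)
  }
  out <- numeric(nv)
  for (k in 1:3) out <- out + rowsum_vec(contrib[, k], f[, k], nv)
  if (!is.null(vertex)) {
    if (length(vertex) != 1L) stop("vertex must be a single index")
    if (out[vertex] == 0) stop("vertex ", vertex, " has no incident face")
    return(out[vertex])
  }
  out
}

# vertices lying on a boundary (an edge with exactly one incident face)
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- edge_key(a, b, n_vertices(mesh))
  cnt <- table(key)
  bkey <- as.numeric(names(cnt)[cnt == 1L])
  flag <- logical(n_vertices(mesh))
  if (length(bkey)) {
    bb <- bkey %% (n_vertices(mesh) + 1)
    aa <- (bkey - bb) / (n_vertices(mesh) + 1)
    flag[c(aa, bb)] <- TRUE
  }
  flag
}

#' Mean curvature from the cotangent one-ring operator
#'
#' The discrete mean-curvature normal at vertex i is
#' `(1 / (2 A_M)) * sum_j (cot a_ij + cot b_ij) (x_i - x_j)` over the
#' one-ring, where `a_ij`, `b_ij` are the two angles opposite edge (i, j);
#' its half-norm is the unsigned mean curvature.  The sign is fixed by
#' projecting the vector on the outward vertex normal so that convex regions
#' come out negative (see [curvature-operators]).
#'
#' @param mesh a closed, consistently oriented `triangle_mesh`.
#' @return list with numeric per-vertex vectors `magnitude` (`|K_H|`, 1/mm),
#'   `signed` (`K_H`), and logical `boundary` flagging vertices where the
#'   operator is undefined (open-mesh boundaries; values there are `NA`).
#' @export
mean_curvature <- function(mesh) {
  fg <- face_geometry(mesh)
  f <- mesh$faces
  nv <- n_vertices(mesh)
  v <- mesh$vertices
  am <- mixed_area(mesh)
  vec <- matrix(0, nv, 3)
  # corner k's cotangent weights the edge opposite it, pulling both of that
  # edge's endpoints
  for (k in 1:3) {
    i1 <- f[, (k %% 3) + 1L]
    i2 <- f[, ((k + 1L) %% 3) + 1L]
    w <- fg$cots[, k]
    d <- v[i1, , drop = FALSE] - v[i2, , drop = FALSE]
    for (c3 in 1:3) {
      vec[, c3] <- vec[, c3] + rowsum_vec(w * d[, c3], i1, nv)
      vec[, c3] <- vec[, c3] - rowsum_vec(w * d[, c3], i2, nv)
    }
  }
  vec <- vec / (2 * pmax(am, .Machine$double.xmin))
  mag <- 0.5 * sqrt(rowSums(vec^2))
  nrm <- vertex_normals(mesh)
  sgn <- sign(rowSums(vec * nrm))
  signed <- -sgn * mag
  signed[sgn == 0] <- 0
  bnd <- boundary_vertices(mesh)
  mag[bnd] <- NA_real_
  signed[bnd] <- NA_real_
  list(magnitude = mag, signed = signed, boundary = bnd)
}

#' Gaussian curvature from the angle deficit
#'
#' `K_G(x_i) = (2 pi - sum_j theta_j) / A_M(x_i)` with `theta_j` the angles
#' of the incident faces at the vertex.  Summed against the mixed areas this
#' telescopes to the discrete Gauss-Bonnet identity
#' `sum_i K_G A_M = 2 pi chi`.
#'
#' @param mesh a closed `triangle_mesh`.
#' @return list with numeric `k_g` (1/mm^2), numeric `deficit` (radians) and
#'   logical `boundary` (values `NA` on open boundaries).
#' @export
gaussian_curvature <- function(mesh) {
  fg <- face_geometry(mesh)
  f <- mesh$faces
  nv <- n_vertices(mesh)
  angsum <- numeric(nv)
  for (k in 1:3) angsum <- angsum + rowsum_vec(fg$angles[, k], f[, k], nv)
  deficit <- 2 * pi - angsum
  am <- mixed_area(mesh)
  kg <- deficit / pmax(am, .Machine$double.xmin)
  bnd <- boundary_vertices(mesh)
  kg[bnd] <- NA_real_
  deficit[bnd] <- NA_real_
  list(k_g = kg, deficit = deficit, boundary = bnd)
}

#' Principal curvatures from mean and Gaussian curvature
#'
#' `k_max = K_H + D`, `k_min = K_H - D` with
#' `D = sqrt(max(K_H^2 - K_G, 0))`; the clamp handles the discrete case
#' where `K_H^2 < K_G` (then both principal curvatures are set to `K_H`).
#' `printed_delta = TRUE` switches to the unclamped-root variant
#' `D = max(K_H^2 - K_G^2, 0)` found in some published write-ups; it is
#' dimensionally inconsistent and kept only for comparability.
#'
#' @param k_h_signed signed mean curvature (1/mm).
#' @param k_g Gaussian curvature (1/mm^2).
#' @param printed_delta use the legacy (dimensionally inconsistent) delta.
#' @return list of numeric vectors `k_max`, `k_min`, `delta` with
#'   `k_max >= k_min`.
#' @export
principal_curvatures <- function(k_h_signed, k_g, printed_delta = FALSE) {
  if (printed_delta) {
    delta <- pmax(k_h_signed^2 - k_g^2, 0)
  } else {
    delta <- sqrt(pmax(k_h_signed^2 - k_g, 0))
  }
  list(k_max = k_h_signed + delta, k_min = k_h_signed - delta, delta = delta)
}

#' Koenderink shape index
#'
#' `SI = -(2/pi) * atan((k_max + k_min) / (k_max - k_min))`, a
#' translation-, rotation- and scale-invariant descriptor in `[-1, 1]`.
#' Under the package sign convention SI is +1 on convex umbilics (domes seen
#' from outside), -1 on concave umbilics (cups), 0 on symmetric saddles.
#' At umbilics (`k_max == k_min != 0`) the limit `-sign(k_max)` is used;
#' flat points (both curvatures ~ 0) return `NA`.
#'
#' @param k_max,k_min principal curvatures with `k_max >= k_min` (1/mm).
#' @return numeric vector of shape indices in `[-1, 1]`, `NA` at flat points.
#' @export
shape_index <- function(k_max, k_min) {
  k_max <- as.numeric(k_max)
  k_min <- as.numeric(k_min)
  scale <- pmax(abs(k_max), abs(k_min))
  flat <- scale == 0 | !is.finite(scale)
  umbilic <- !flat & (k_max - k_min) <= 1e-12 * scale
  si <- -(2 / pi) * atan((k_max + k_min) / (k_max - k_min))
  si[umbilic] <- -sign(k_max[umbilic])
  si[flat] <- NA_real_
  si
}

#' All per-vertex differential quantities as a tibble
#'
#' Runs the full operator stack and returns one row per vertex with the
#' mixed area, signed and unsigned mean curvature, Gaussian curvature,
#' principal curvatures, delta term and shape index, plus `boundary` and
#' `flat` flags.  Boundary vertices of open meshes carry `NA` differentials.
#'
#' @param mesh a `triangle_mesh` (closed for meaningful values everywhere).
#' @param printed_delta see [principal_curvatures()].
#' @param flat_tol curvature magnitude (1/mm) below which a vertex is
#'   treated as flat (shape index undefined).  Default `1e-10 / h` with `h`
#'   the mean edge length, i.e. effectively exact-zero detection, scale
#'   aware.
#' @return a tibble with columns `vertex`, `a_m`, `k_h_mag`, `k_h_signed`,
#'   `k_g`, `k_max`, `k_min`, `delta`, `si`, `boundary`, `flat`.
#' @export
vertex_differentials <- function(mesh, printed_delta = FALSE,
                                 flat_tol = NULL) {
  if (is.null(flat_tol)) flat_tol <- 1e-10 / mean_edge_length(mesh)
  am <- mixed_area(mesh)
  mh <- mean_curvature(mesh)
  gg <- gaussian_curvature(mesh)
  pc <- principal_curvatures(mh$signed, gg$k_g, printed_delta = printed_delta)
  flat <- !is.na(pc$k_max) & abs(pc$k_max) < flat_tol &
    abs(pc$k_min) < flat_tol
  si <- shape_index(pc$k_max, pc$k_min)
  si[flat] <- NA_real_
  tibble::tibble(
    vertex = seq_len(n_vertices(mesh)),
    a_m = am,
    k_h_mag = mh$magnitude,
    k_h_signed = mh$signed,
    k_g = gg$k_g,
    k_max = pc$k_max,
    k_min = pc$k_min,
    delta = pc$delta,
    si = si,
    boundary = mh$boundary,
    flat = flat)
}

# mean edge length of a mesh, mm
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2)))
}
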