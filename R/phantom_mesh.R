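#' Icosphere mesh with analytically known curvature
#'
#' Repeated midpoint subdivision of an icosahedron, each new vertex projected
#' back to the sphere.  The exact sphere is the reference surface for the
#' discrete curvature operators: mean curvature 1/R, Gaussian curvature
#' 1/R^2, shape index +1 under the package's sign convention (convex
#' negative mean curvature).
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of subdivision rounds (0 = icosahedron; at most
#'   7).
#' @return a closed, outward-oriented `triangle_mesh` with `10 * 4^s + 2`
#'   vertices and `20 * 4^s` faces at subdivision level `s`.
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 0L) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0L || subdivisions > 7L)
    stop("subdivisions must be in 0..7")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_midpoint(v, f)
    v <- sub$v / sqrt(rowSums(sub$v^2))
    f <- sub$f
  }
  triangle_mesh(v * radius, f)
}

# one round of loop-style midpoint subdivision (no smoothing), shared
# midpoints deduplicated; returns unnormalized vertices
subdivide_midpoint <- function(v, f) {
  nv <- nrow(v)
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  a <- pmin(ea[, 1], ea[, 2])
  b <- pmax(ea[, 1], ea[, 2])
  key <- edge_key(a, b, nv)
  uk <- unique(key)
  mid_id <- nv + match(key, uk)                 # per half-edge midpoint index
  first <- match(uk, key)
  mids <- (v[a[first], , drop = FALSE] + v[b[first], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = f2)
}

#' Torus mesh (mixed-sign Gaussian curvature fixture)
#'
#' Regular parametric torus: circle of radius `minor_r` swept around a
#' circle of radius `major_R` in the xy-plane.  Outer-equator vertices have
#' positive Gaussian curvature, inner-equator vertices negative, which makes
#' the torus the standard oracle for hyperbolic/elliptic discrimination and
#' for the genus-1 Gauss-Bonnet identity (total curvature 0).
#'
#' @param major_R,minor_r ring and tube radii in mm (`major_R > minor_r > 0`).
#' @param n_u,n_v number of segments around the ring and the tube (>= 3).
#' @return a closed `triangle_mesh` of genus 1 with `2 * n_u * n_v` faces.
#' @export
torus_mesh <- function(major_R = 2, minor_r = 1, n_u = 16L, n_v = 16L) {
  if (!(major_R > minor_r && minor_r > 0))
    stop("need major_R > minor_r > 0 (got ", major_R, ", ", minor_r, ")")
  if (n_u < 3L || n_v < 3L) stop("n_u and n_v must be >= 3")
  u <- 2 * pi * (seq_len(n_u) - 1) / n_u  # around the ring
  vv <- 2 * pi * (seq_len(n_v) - 1) / n_v # around the tube
  g <- expand.grid(iv = seq_len(n_v), iu = seq_len(n_u))
  U <- u[g$iu]
  V <- vv[g$iv]
  verts <- cbind((major_R + minor_r * cos(V)) * cos(U),
                 (major_R + minor_r * cos(V)) * sin(U),
                 minor_r * sin(V))
  id <- function(iu, iv) (iu - 1L) * n_v + iv  # both wrapped to 1..n
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  g2 <- expand.grid(iv = seq_len(n_v), iu = seq_len(n_u))
  i00 <- id(g2$iu, g2$iv)
  i10 <- id(wrap(g2$iu + 1L, n_u), g2$iv)
  i01 <- id(g2$iu, wrap(g2$iv + 1L, n_v))
  i11 <- id(wrap(g2$iu + 1L, n_u), wrap(g2$iv + 1L, n_v))
  f <- rbind(cbind(i00, i10, i11), cbind(i00, i11, i01))
  m <- triangle_mesh(verts, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Folded "cortex-like" phantom mesh with ground-truth landmarks
#'
#' A sphere with a doubly periodic radial displacement
#' `r(theta, phi) = R + A * sin(f * theta) * sin(f * phi)`, giving regularly
#' alternating convex bumps (gyral crests) and concave dimples (sulcal
#' fundi) whose locations are known analytically.  Vertices where the
#' displacement exceeds `+0.8 A` (falls below `-0.8 A`) are returned as the
#' crest (fundus) landmark sets used to score classification accuracy.
#' With `fold_amplitude = 0` the result is bit-identical to
#' [icosphere_mesh()].
#'
#' @param base_radius sphere radius R in mm.
#' @param fold_frequency integer angular frequency f of the folds.
#' @param fold_amplitude fold height A in mm; must be below `base_radius / 2`
#'   to avoid self-intersection.
#' @param subdivisions icosphere subdivision level of the support mesh.
#' @return a closed `triangle_mesh` with integer-vector attributes
#'   `crest_vertices`, `fundus_vertices` and numeric attribute
#'   `displacement` (the analytic radial offset per vertex).
#' @export
folded_phantom_mesh <- function(base_radius = 10, fold_frequency = 6L,
                                fold_amplitude = 2, subdivisions = 4L) {
  if (fold_amplitude < 0) stop("fold_amplitude must be >= 0")
  if (fold_amplitude >= base_radius / 2)
    stop("fold_amplitude ", fold_amplitude, " >= base_radius/2 would ",
         "self-intersect the phantom")
  m <- icosphere_mesh(radius = base_radius, subdivisions = subdivisions)
  if (fold_amplitude == 0) {
    attr(m, "crest_vertices") <- integer(0)
    attr(m, "fundus_vertices") <- integer(0)
    attr(m, "displacement") <- numeric(n_vertices(m))
    return(m)
  }
  dirs <- m$vertices / base_radius
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))    # polar angle
  phi <- atan2(dirs[, 2], dirs[, 1])             # azimuth
  disp <- fold_amplitude * sin(fold_frequency * theta) * sin(fold_frequency * phi)
  out <- triangle_mesh(dirs * (base_radius + disp), m$faces)
  attr(out, "crest_vertices") <- which(disp > 0.8 * fold_amplitude)
  attr(out, "fundus_vertices") <- which(disp < -0.8 * fold_amplitude)
  attr(out, "displacement") <- disp
  out
}
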