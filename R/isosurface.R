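#' Extract a triangulated isosurface from a volume
#'
#' Table-driven isosurface triangulation of the voxel grid: each cell is
#' split into six conforming tetrahedra (Kuhn decomposition, so triangulated
#' faces of neighbouring cells match exactly) and each tetrahedron crossed
#' by the isovalue contributes one or two triangles with vertices linearly
#' interpolated along the crossing edges.  The result is watertight and
#' consistently oriented by construction, with normals pointing from the
#' above-isovalue region (interior) to the below-isovalue region — for a
#' level-set field (positive inside) extracted at 0 this is the outward
#' orientation.
#'
#' Vertex coordinates are world-space mm: `origin + index0 * spacing` with
#' grid vertices at voxel centres (0-based index).
#'
#' @param x an `intensity_volume`, a `level_set_state`, or a bare 3D array.
#' @param isovalue iso level; defaults to 0 for level-set states and to
#'   midway between min and max otherwise.  Must lie strictly inside the
#'   field's range.
#' @param spacing,origin used only when `x` is a bare array.
#' @return a `triangle_mesh`.
#' @export
extract_isosurface <- function(x, isovalue = NULL, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (inherits(x, "level_set_state")) {
    vals <- x$psi; spacing <- x$spacing; origin <- x$origin
    if (is.null(isovalue)) isovalue <- 0
  } else if (inherits(x, "intensity_volume")) {
    vals <- x$data; spacing <- x$spacing; origin <- x$origin
  } else {
    vals <- x
  }
  storage.mode(vals) <- "double"
  spacing <- rep(as.numeric(spacing), length.out = 3)
  rng <- range(vals)
  if (is.null(isovalue)) isovalue <- mean(rng)
  if (isovalue <= rng[1] || isovalue >= rng[2])
    stop("empty isosurface: isovalue ", isovalue,
         " outside the open field range (", rng[1], ", ", rng[2], ")")
  marching_tetrahedra(vals, isovalue, spacing, origin)
}

# the 6 Kuhn tetrahedra of the unit cell as 0/1 corner offsets; every tet
# contains the main diagonal (0,0,0)-(1,1,1) so the decomposition conforms
# across neighbouring cells
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(6), function(p) {
    e <- diag(3)[perms[p, ], , drop = FALSE]
    rbind(c(0, 0, 0), e[1, ], e[1, ] + e[2, ], c(1, 1, 1))
  })
}

marching_tetrahedra <- function(vals, isovalue, spacing, origin) {
  d <- dim(vals)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ntot <- nx * ny * nz
  # nudge grid values off the isovalue so no crossing sits on a grid vertex
  tiny <- 1e-9 * max(max(vals) - min(vals), 1)
  vals[abs(vals - isovalue) < tiny] <- isovalue + tiny
  # linear (1-based) indices of the base corner of every cell
  base <- as.vector(outer(outer(seq_len(nx - 1),
                                (seq_len(ny - 1) - 1) * nx, "+"),
                          (seq_len(nz - 1) - 1) * nx * ny, "+"))
  off_lin <- function(o) o[1] + o[2] * nx + o[3] * nx * ny

  face_keys <- list()   # each: n x 3 matrix of corner keys (oriented)
  key_pos <- list()     # each: m x 4 matrix (key, x, y, z)
  acc <- 1L

  world_of <- function(lin, frac_to, tval) {
    # world position along grid edge lin -> frac_to at parameter tval
    a <- lin_to_idx0(lin, nx, ny)
    b <- lin_to_idx0(frac_to, nx, ny)
    grid_to_world(a + tval * (b - a), spacing, origin)
  }

  for (tt in kuhn_tets()) {
    corner_lin <- vapply(1:4, function(k) base + off_lin(tt[k, ]),
                         numeric(length(base)))
    vmat <- matrix(vals[corner_lin], ncol = 4)
    inside <- vmat > isovalue
    pat <- as.vector(inside %*% 2L^(0:3))
    for (p in setdiff(unique(pat), c(0L, 15L))) {
      rows <- which(pat == p)
      ins <- which(bitwAnd(p, 2L^(0:3)) > 0)
      outs <- setdiff(1:4, ins)
      cl <- corner_lin[rows, , drop = FALSE]
      vm <- vmat[rows, , drop = FALSE]
      cross_pt <- function(a, b) {   # a inside corner, b outside corner
        la <- cl[, a]; lb <- cl[, b]
        tval <- (isovalue - vm[, a]) / (vm[, b] - vm[, a])
        list(key = edge_key(pmin(la, lb), pmax(la, lb), ntot),
             pos = world_of(la, lb, tval))
      }
      # world direction from inside-corner centroid to outside-corner
      # centroid, used to orient triangles
      centroid <- function(which_corners) {
        s <- matrix(0, length(rows), 3)
        for (k in which_corners)
          s <- s + grid_to_world(lin_to_idx0(cl[, k], nx, ny), spacing, origin)
        s / length(which_corners)
      }
      dir <- centroid(outs) - centroid(ins)
      emit <- function(p1, p2, p3) {
        nrm <- cross3(p2$pos - p1$pos, p3$pos - p1$pos)
        flip <- rowSums(nrm * dir) < 0
        k2 <- ifelse(flip, p3$key, p2$key)
        k3 <- ifelse(flip, p2$key, p3$key)
        face_keys[[acc]] <<- cbind(p1$key, k2, k3)
        key_pos[[acc]] <<- rbind(cbind(p1$key, p1$pos),
                                 cbind(p2$key, p2$pos),
                                 cbind(p3$key, p3$pos))
        acc <<- acc + 1L
      }
      if (length(ins) == 1L) {
        cp <- lapply(outs, function(o) cross_pt(ins, o))
        emit(cp[[1]], cp[[2]], cp[[3]])
      } else if (length(ins) == 3L) {
        cp <- lapply(ins, function(i) cross_pt(i, outs))
        emit(cp[[1]], cp[[2]], cp[[3]])
      } else {
        p11 <- cross_pt(ins[1], outs[1]); p12 <- cross_pt(ins[1], outs[2])
        p22 <- cross_pt(ins[2], outs[2]); p21 <- cross_pt(ins[2], outs[1])
        emit(p11, p12, p22)
        emit(p11, p22, p21)
      }
    }
  }
  if (length(face_keys) == 0L) stop("empty isosurface at isovalue ", isovalue)
  fk <- do.call(rbind, face_keys)
  kp <- do.call(rbind, key_pos)
  first <- !duplicated(kp[, 1])
  uk <- kp[first, 1]
  verts <- kp[first, 2:4, drop = FALSE]
  faces <- matrix(match(fk, uk), nrow = nrow(fk), ncol = 3)
  triangle_mesh(verts, faces)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

lin_to_idx0 <- function(lin, nx, ny) {
  lin0 <- lin - 1
  i <- lin0 %% nx
  j <- (lin0 %/% nx) %% ny
  k <- lin0 %/% (nx * ny)
  cbind(i, j, k)
}
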