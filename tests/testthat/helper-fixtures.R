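# Mesh fixtures built in code, shared across test files.

# closed unit cube, 12 triangles, outward winding
cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (z = 0)
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front (y = 0)
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left (x = 0)
             c(2, 3, 7), c(2, 7, 6))   # right
  triangle_mesh(v, f)
}

# open flat n x n grid patch in the z = 0 plane, unit spacing
flat_patch <- function(n = 5) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      f <- rbind(f,
                 c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  triangle_mesh(v, f)
}

# regular tetrahedron (closed, outward)
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# independent brute-force decimator: rescans every edge of the current
# complex each step, picks the global minimum cost (ties: smallest (a, b)),
# maintains quadrics additively.  Written without the package's heap or
# adjacency machinery so it can serve as an oracle for quadric_decimate().
oracle_decimate <- function(mesh, target_reduction, preserve_topology = TRUE) {
  verts <- mesh$vertices
  faces <- mesh$faces
  nv <- nrow(verts)
  alive_f <- rep(TRUE, nrow(faces))
  alive_v <- rep(TRUE, nv)
  plane_quadric <- function(fi) {
    p <- verts[faces[fi, ], , drop = FALSE]
    n <- c(p[1, 2] * p[2, 3] - p[1, 3] * p[2, 2],
           p[1, 3] * p[2, 1] - p[1, 1] * p[2, 3],
           p[1, 1] * p[2, 2] - p[1, 2] * p[2, 1])
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    area <- sqrt(sum(n^2)) / 2
    n <- n / max(sqrt(sum(n^2)), 1e-300)
    pl <- c(n, -sum(n * p[1, ]))
    area * tcrossprod(pl)
  }
  quads <- vector("list", nv)
  for (i in seq_len(nv)) {
    inc <- which(alive_f & (faces[, 1] == i | faces[, 2] == i | faces[, 3] == i))
    quads[[i]] <- Reduce(`+`, lapply(inc, plane_quadric))
  }
  eval_q <- function(Q, x) { v <- c(x, 1); as.numeric(v %*% Q %*% v) }
  best_point <- function(Q, xa, xb) {
    A <- Q[1:3, 1:3]; b <- Q[1:3, 4]
    if (rcond(A) > 1e-10) {
      x <- tryCatch(solve(A, -b), error = function(e) NULL)
      if (!is.null(x) && all(is.finite(x)))
        return(list(p = as.numeric(x), cost = max(eval_q(Q, x), 0)))
    }
    cand <- rbind(xa, xb, (xa + xb) / 2)
    cs <- apply(cand, 1, function(x) eval_q(Q, x))
    k <- which.min(cs)
    list(p = cand[k, ], cost = max(cs[k], 0))
  }
  link_ok <- function(a, b) {
    fa <- which(alive_f & (faces[, 1] == a | faces[, 2] == a | faces[, 3] == a))
    fb <- which(alive_f & (faces[, 1] == b | faces[, 2] == b | faces[, 3] == b))
    shared <- intersect(fa, fb)
    if (length(shared) != 2L) return(FALSE)
    ring_a <- setdiff(unique(as.vector(faces[fa, ])), a)
    ring_b <- setdiff(unique(as.vector(faces[fb, ])), b)
    common <- intersect(ring_a, ring_b)
    opp <- setdiff(unique(as.vector(faces[shared, ])), c(a, b))
    if (!(length(common) == 2L && setequal(common, opp))) return(FALSE)
    has_cd <- function(fs) {
      fs <- setdiff(fs, shared)
      if (!length(fs)) return(FALSE)
      any(apply(faces[fs, , drop = FALSE], 1, function(r) sum(r %in% opp) >= 2))
    }
    !(has_cd(fa) && has_cd(fb))
  }
  n_alive <- sum(alive_f)
  target <- ceiling((1 - target_reduction) * n_alive)
  log <- NULL
  while (n_alive > target) {
    ef <- faces[alive_f, , drop = FALSE]
    e <- unique(cbind(pmin(rbind(ef[, 1:2], ef[, 2:3], ef[, c(3, 1)])[, 1],
                           rbind(ef[, 1:2], ef[, 2:3], ef[, c(3, 1)])[, 2]),
                      pmax(rbind(ef[, 1:2], ef[, 2:3], ef[, c(3, 1)])[, 1],
                           rbind(ef[, 1:2], ef[, 2:3], ef[, c(3, 1)])[, 2])))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    best <- NULL
    for (r in seq_len(nrow(e))) {
      a <- e[r, 1]; b <- e[r, 2]
      if (preserve_topology && !link_ok(a, b)) next
      bp <- best_point(quads[[a]] + quads[[b]], verts[a, ], verts[b, ])
      if (is.null(best) || bp$cost < best$cost - 1e-300 ||
            (bp$cost == best$cost && (a < best$a ||
                                        (a == best$a && b < best$b)))) {
        best <- list(a = a, b = b, cost = bp$cost, p = bp$p)
      }
    }
    if (is.null(best)) break
    a <- best$a; b <- best$b
    verts[a, ] <- best$p
    quads[[a]] <- quads[[a]] + quads[[b]]
    alive_v[b] <- FALSE
    for (fi in which(alive_f)) {
      row <- faces[fi, ]
      if (b %in% row) {
        if (a %in% row) {
          alive_f[fi] <- FALSE
        } else {
          row[row == b] <- a
          if (anyDuplicated(row)) alive_f[fi] <- FALSE else faces[fi, ] <- row
        }
      }
    }
    n_alive <- sum(alive_f)
    log <- rbind(log, c(a = a, b = b, cost = best$cost, faces = n_alive))
  }
  fk <- faces[alive_f, , drop = FALSE]
  idx <- cumsum(alive_v)
  list(mesh = triangle_mesh(verts[alive_v, , drop = FALSE],
                            matrix(idx[fk], ncol = 3)),
       log = as.data.frame(log))
}

# voxels lying on the interface of a logical mask: some 6-neighbour differs
interface_voxels <- function(mask) {
  d <- dim(mask)
  shift <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    s <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    idx[[axis]] <- s
    do.call(`[`, c(list(a), idx))
  }
  out <- array(FALSE, d)
  for (ax in 1:3) {
    out <- out | (mask != shift(mask, ax, 1L)) | (mask != shift(mask, ax, -1L))
  }
  out
}
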