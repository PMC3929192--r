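#' Quadric error metrics
#'
#' Each face contributes the area-weighted plane quadric
#' `Q = area * p p^T`, `p = (n, -n . x)` with `n` the unit face normal; a
#' vertex quadric is the sum over its incident faces and measures the
#' squared distance (mm^2-weighted) of a candidate point to all those
#' planes.  After an edge collapse the merged vertex inherits the sum of
#' the endpoint quadrics (the additive rule), so quadrics are never
#' re-accumulated from the simplified geometry.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex a single vertex index with at least one incident face.
#' @return `vertex_quadric()`: a symmetric 4x4 matrix, positive
#'   semidefinite in its 3x3 block.
#' @export
vertex_quadric <- function(mesh, vertex) {
  f <- mesh$faces
  inc <- which(f[, 1] == vertex | f[, 2] == vertex | f[, 3] == vertex)
  if (length(inc) == 0L) stop("vertex ", vertex, " has no incident face")
  qs <- face_quadrics(mesh, inc)
  Reduce(`+`, qs)
}

# list of 4x4 area-weighted plane quadrics for the given faces
face_quadrics <- function(mesh, face_idx = seq_len(n_faces(mesh))) {
  v <- mesh$vertices
  f <- mesh$faces[face_idx, , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cross3(e1, e2)
  len <- sqrt(rowSums(nrm^2))
  area <- len / 2
  nrm <- nrm / pmax(len, .Machine$double.xmin)
  d <- -rowSums(nrm * v[f[, 1], , drop = FALSE])
  lapply(seq_along(face_idx), function(i) {
    p <- c(nrm[i, ], d[i])
    area[i] * tcrossprod(p)
  })
}

# evaluate quadric at a 3-point
quadric_eval <- function(Q, x) {
  v <- c(x, 1)
  as.numeric(v %*% Q %*% v)
}

# optimal collapse point and cost for combined quadric Q; falls back to the
# best of the endpoints and midpoint when the 3x3 system is ill-conditioned
quadric_optimum <- function(Q, xa, xb) {
  A <- Q[1:3, 1:3]
  b <- Q[1:3, 4]
  opt <- NULL
  if (rcond(A) > 1e-10) {
    opt <- tryCatch(solve(A, -b), error = function(e) NULL)
  }
  if (is.null(opt) || !all(is.finite(opt))) {
    cand <- rbind(xa, xb, (xa + xb) / 2)
    costs <- apply(cand, 1, function(x) quadric_eval(Q, x))
    k <- which.min(costs)
    return(list(point = cand[k, ], cost = max(costs[k], 0)))
  }
  list(point = as.numeric(opt), cost = max(quadric_eval(Q, opt), 0))
}

#' Cost of collapsing an edge
#'
#' Combines the endpoint quadrics and minimizes the resulting error over
#' the collapse point.  Standalone variant of what the decimator maintains
#' incrementally; useful for inspection and testing.
#'
#' @param mesh a `triangle_mesh`.
#' @param edge length-2 integer vector of vertex indices.
#' @return a `collapse_candidate`: list with `edge` (sorted), `cost` (>= 0,
#'   mm^2-weighted quadric error) and `optimal_point`.
#' @export
edge_collapse_cost <- function(mesh, edge) {
  edge <- sort(as.integer(edge))
  Q <- vertex_quadric(mesh, edge[1]) + vertex_quadric(mesh, edge[2])
  opt <- quadric_optimum(Q, mesh$vertices[edge[1], ], mesh$vertices[edge[2], ])
  structure(list(edge = edge, cost = opt$cost, optimal_point = opt$point),
            class = "collapse_candidate")
}

#' Link condition for topology-preserving collapse
#'
#' An edge (a, b) of a closed 2-manifold may be collapsed without changing
#' the topology iff the one-ring neighbourhoods of a and b intersect in
#' exactly the two vertices opposite the edge, and those two vertices do
#' not form a face with both a and b beyond the two faces sharing the edge
#' (which rules out tetrahedron-like pockets).
#'
#' @param mesh a manifold `triangle_mesh`.
#' @param edge length-2 integer vector.
#' @return logical.
#' @export
link_condition <- function(mesh, edge) {
  a <- edge[1]; b <- edge[2]
  f <- mesh$faces
  fa <- which(f[, 1] == a | f[, 2] == a | f[, 3] == a)
  fb <- which(f[, 1] == b | f[, 2] == b | f[, 3] == b)
  link_condition_faces(f, fa, fb, a, b)
}

# core link test given the incident face index sets of both endpoints
link_condition_faces <- function(f, fa, fb, a, b) {
  shared <- intersect(fa, fb)
  if (length(shared) != 2L) return(FALSE)   # boundary or non-manifold edge
  ring_a <- setdiff(unique(as.vector(f[fa, ])), a)
  ring_b <- setdiff(unique(as.vector(f[fb, ])), b)
  common <- intersect(ring_a, ring_b)
  opposite <- setdiff(unique(as.vector(f[shared, ])), c(a, b))
  if (!(length(common) == 2L && setequal(common, opposite))) return(FALSE)
  # reject if both opposite vertices already span faces with a and with b
  # outside the shared pair (closed pocket, e.g. a tetrahedron)
  third_a <- setdiff(fa, shared)
  third_b <- setdiff(fb, shared)
  has_cd <- function(fs) {
    if (length(fs) == 0L) return(FALSE)
    sub <- f[fs, , drop = FALSE]
    any(rowSums(matrix(sub %in% opposite, nrow(sub), 3)) >= 2L)
  }
  !(has_cd(third_a) && has_cd(third_b))
}

#' Quadric edge-collapse decimation
#'
#' Greedy simplification: all edges enter a priority queue keyed by quadric
#' collapse cost (ties broken by vertex index pair for reproducibility);
#' the cheapest valid edge is collapsed into its optimal point, the merged
#' vertex inherits the summed quadric, and the costs of the edges around it
#' are refreshed (lazy deletion via per-vertex version counters).  With
#' `preserve_topology` every collapse must pass the [link_condition()], so
#' the Euler characteristic and component count never change; without it
#' collapses proceed regardless, which can pinch or merge topology in
#' exchange for hitting the target reduction.
#'
#' @param mesh a manifold `triangle_mesh`.
#' @param target_reduction fraction of faces to remove, strictly in (0, 1).
#' @param preserve_topology require the link condition (default TRUE).
#' @return the decimated `triangle_mesh`, with attributes `collapse_log`
#'   (tibble: `step`, `kept`, `removed`, `cost`, `x`, `y`, `z`,
#'   `faces_after`), `blocked` (number of pops rejected by the link
#'   condition), `target_faces`, and `vertex_reduction` (fraction of
#'   vertices removed, for comparison with the face-based target).
#' @export
quadric_decimate <- function(mesh, target_reduction, preserve_topology = TRUE) {
  if (!is.numeric(target_reduction) || length(target_reduction) != 1L ||
        target_reduction <= 0 || target_reduction >= 1)
    stop("target_reduction must be strictly between 0 and 1")
  nv <- n_vertices(mesh)
  nf0 <- n_faces(mesh)
  target_faces <- ceiling((1 - target_reduction) * nf0)

  verts <- mesh$vertices
  faces <- mesh$faces
  face_alive <- rep(TRUE, nf0)
  vert_alive <- rep(TRUE, nv)
  version <- integer(nv)
  # incident alive-face lists
  vf <- vector("list", nv)
  for (k in 1:3) {
    sp <- split(seq_len(nf0), faces[, k])
    idx <- as.integer(names(sp))
    for (i in seq_along(sp)) vf[[idx[i]]] <- c(vf[[idx[i]]], sp[[i]])
  }
  quad <- vector("list", nv)
  fq <- face_quadrics(mesh)
  for (i in seq_len(nv)) {
    quad[[i]] <- Reduce(`+`, fq[vf[[i]]])
    if (is.null(quad[[i]])) stop("isolated vertex ", i)
  }

  # --- binary min-heap ordered by (cost, a, b) ---
  cap <- 4096L
  h_cost <- numeric(cap); h_a <- integer(cap); h_b <- integer(cap)
  h_px <- numeric(cap); h_py <- numeric(cap); h_pz <- numeric(cap)
  h_va <- integer(cap); h_vb <- integer(cap)
  h_n <- 0L
  less <- function(i, j) {
    if (h_cost[i] != h_cost[j]) return(h_cost[i] < h_cost[j])
    if (h_a[i] != h_a[j]) return(h_a[i] < h_a[j])
    h_b[i] < h_b[j]
  }
  swap <- function(i, j) {
    tmp <- c(h_cost[i], h_px[i], h_py[i], h_pz[i])
    h_cost[i] <<- h_cost[j]; h_px[i] <<- h_px[j]; h_py[i] <<- h_py[j]; h_pz[i] <<- h_pz[j]
    h_cost[j] <<- tmp[1]; h_px[j] <<- tmp[2]; h_py[j] <<- tmp[3]; h_pz[j] <<- tmp[4]
    tmpi <- c(h_a[i], h_b[i], h_va[i], h_vb[i])
    h_a[i] <<- h_a[j]; h_b[i] <<- h_b[j]; h_va[i] <<- h_va[j]; h_vb[i] <<- h_vb[j]
    h_a[j] <<- tmpi[1]; h_b[j] <<- tmpi[2]; h_va[j] <<- tmpi[3]; h_vb[j] <<- tmpi[4]
  }
  push <- function(cost, a, b, p) {
    if (h_n == cap) {
      cap <<- cap * 2L
      length(h_cost) <<- cap; length(h_a) <<- cap; length(h_b) <<- cap
      length(h_px) <<- cap; length(h_py) <<- cap; length(h_pz) <<- cap
      length(h_va) <<- cap; length(h_vb) <<- cap
    }
    h_n <<- h_n + 1L
    h_cost[h_n] <<- cost; h_a[h_n] <<- a; h_b[h_n] <<- b
    h_px[h_n] <<- p[1]; h_py[h_n] <<- p[2]; h_pz[h_n] <<- p[3]
    h_va[h_n] <<- version[a]; h_vb[h_n] <<- version[b]
    i <- h_n
    while (i > 1L) {
      par <- i %/% 2L
      if (less(i, par)) { swap(i, par); i <- par } else break
    }
  }
  pop <- function() {
    top <- list(cost = h_cost[1], a = h_a[1], b = h_b[1],
                p = c(h_px[1], h_py[1], h_pz[1]),
                va = h_va[1], vb = h_vb[1])
    swap(1L, h_n)
    h_n <<- h_n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      if (l > h_n) break
      m <- if (r <= h_n && less(r, l)) r else l
      if (less(m, i)) { swap(i, m); i <- m } else break
    }
    top
  }

  push_edge <- function(a, b) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    Q <- quad[[a]] + quad[[b]]
    opt <- quadric_optimum(Q, verts[a, ], verts[b, ])
    push(opt$cost, a, b, opt$point)
  }

  e0 <- mesh_edges(mesh)
  for (i in seq_len(nrow(e0))) push_edge(e0[i, 1], e0[i, 2])

  n_alive_faces <- nf0
  blocked <- 0L
  rescans <- 0L
  reseed <- function() {
    fk <- faces[face_alive, , drop = FALSE]
    if (nrow(fk) == 0L) return(invisible())
    ee <- rbind(fk[, c(1, 2), drop = FALSE], fk[, c(2, 3), drop = FALSE],
                fk[, c(3, 1), drop = FALSE])
    ee <- unique(cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2])))
    for (i in seq_len(nrow(ee))) push_edge(ee[i, 1], ee[i, 2])
  }
  log_step <- integer(0); log_kept <- integer(0); log_removed <- integer(0)
  log_cost <- numeric(0); log_pt <- NULL; log_faces <- integer(0)
  step <- 0L

  while (n_alive_faces > target_faces) {
    if (h_n == 0L) {
      # a collapse elsewhere can unblock a link-condition-rejected edge
      # without bumping its endpoints' versions; rescan a few times before
      # declaring the reduction topologically blocked
      if (rescans >= 3L) break
      rescans <- rescans + 1L
      reseed()
      if (h_n == 0L) break
    }
    cand <- pop()
    a <- cand$a; b <- cand$b
    if (!vert_alive[a] || !vert_alive[b]) next
    if (cand$va != version[a] || cand$vb != version[b]) next   # stale
    fa <- vf[[a]]; fb <- vf[[b]]
    shared <- intersect(fa, fb)
    if (length(shared) == 0L) next                             # edge gone
    if (preserve_topology &&
          !link_condition_faces(faces, fa, fb, a, b)) {
      blocked <- blocked + 1L
      next
    }
    # ---- collapse b into a at the optimal point ----
    verts[a, ] <- cand$p
    quad[[a]] <- quad[[a]] + quad[[b]]
    vert_alive[b] <- FALSE
    # faces of b: retarget to a, dropping those sharing the edge
    for (fi in setdiff(fb, shared)) {
      row <- faces[fi, ]
      row[row == b] <- a
      if (anyDuplicated(row)) { face_alive[fi] <- FALSE; n_alive_faces <- n_alive_faces - 1L }
      faces[fi, ] <- row
    }
    dead_now <- shared[face_alive[shared]]
    face_alive[dead_now] <- FALSE
    n_alive_faces <- n_alive_faces - length(dead_now)
    new_fa <- unique(c(fa, fb))
    new_fa <- new_fa[face_alive[new_fa]]
    vf[[a]] <- new_fa
    vf[[b]] <- integer(0)
    # prune dead faces from the other vertices' lists lazily: rebuild the
    # lists of the ring vertices touched by the dead faces
    touched <- setdiff(unique(as.vector(faces[c(shared, setdiff(fb, shared)), ])), c(a, b))
    for (v2 in touched) vf[[v2]] <- vf[[v2]][face_alive[vf[[v2]]]]
    for (v2 in intersect(unique(as.vector(faces[new_fa, ])), touched)) {
      vf[[v2]] <- unique(c(vf[[v2]], new_fa[rowSums(matrix(faces[new_fa, ] == v2,
                                                           length(new_fa), 3)) > 0]))
    }
    version[a] <- version[a] + 1L
    version[b] <- version[b] + 1L
    step <- step + 1L
    rescans <- 0L
    log_step <- c(log_step, step); log_kept <- c(log_kept, a)
    log_removed <- c(log_removed, b); log_cost <- c(log_cost, cand$cost)
    log_pt <- rbind(log_pt, cand$p); log_faces <- c(log_faces, n_alive_faces)
    # refresh costs of edges around a
    ring <- setdiff(unique(as.vector(faces[vf[[a]], ])), a)
    for (v2 in ring) if (vert_alive[v2]) push_edge(a, v2)
  }

  keep_v <- vert_alive
  new_idx <- cumsum(keep_v)
  fkeep <- faces[face_alive, , drop = FALSE]
  out <- triangle_mesh(verts[keep_v, , drop = FALSE],
                       matrix(new_idx[fkeep], ncol = 3))
  lg <- tibble::tibble(step = log_step, kept = log_kept, removed = log_removed,
                       cost = log_cost,
                       x = if (is.null(log_pt)) numeric(0) else log_pt[, 1],
                       y = if (is.null(log_pt)) numeric(0) else log_pt[, 2],
                       z = if (is.null(log_pt)) numeric(0) else log_pt[, 3],
                       faces_after = log_faces)
  attr(out, "collapse_log") <- lg
  attr(out, "blocked") <- blocked
  attr(out, "target_faces") <- target_faces
  attr(out, "reached_target") <- n_alive_faces <= target_faces
  attr(out, "vertex_reduction") <- 1 - sum(keep_v) / nv
  out
}
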