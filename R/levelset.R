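#' Level-set evolution parameters
#'
#' Parameters of the region + boundary speed law driving the front
#' `dpsi/dt = [alpha_r F_region + alpha_b F_boundary] |grad psi|`:
#' `m_T` is the mean intensity of the target tissue and `eps_T` the
#' intensity half-width around it, so the region speed is positive exactly
#' inside the band `(m_T - eps_T, m_T + eps_T)` and the front grows into
#' that band; the boundary speed `(c + k) / (1 + |grad I|)` slows the front
#' at image edges, with `k` the front mean curvature acting as a
#' regularizer.
#'
#' @param m_T mean intensity of the target region (intensity units).
#' @param eps_T intensity half-width of the target band (>= 0).
#' @param alpha_r,alpha_b non-negative region/boundary weights (not both 0).
#' @param c constant advection speed of the boundary term.
#' @param dt time step; default `0.1 * min(spacing)` at evolve time
#'   (CFL-admissible for speeds of order 1 after normalization, with the
#'   curvature regularizer clamped at the grid scale).
#' @param n_iter_max iteration cap.
#' @param reinit_every re-initialize psi to a signed distance every this
#'   many iterations, and test convergence there.
#' @param tol convergence tolerance: mean front movement per voxel between
#'   re-initializations (voxels).
#' @return a `level_set_params` list.
#' @export
level_set_params <- function(m_T, eps_T, alpha_r = 1, alpha_b = 0.2, c = 1,
                             dt = NULL, n_iter_max = 500L,
                             reinit_every = 5L, tol = 1e-3) {
  if (eps_T < 0) stop("eps_T must be >= 0")
  if (alpha_r < 0 || alpha_b < 0) stop("alpha_r and alpha_b must be >= 0")
  # both weights zero gives a frozen front; allowed (useful as a null case)
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  structure(list(m_T = m_T, eps_T = eps_T, alpha_r = alpha_r,
                 alpha_b = alpha_b, c = c, dt = dt,
                 n_iter_max = as.integer(n_iter_max),
                 reinit_every = as.integer(reinit_every), tol = tol),
            class = "level_set_params")
}

#' Region speed of the band model
#'
#' `F_region(I) = I - (m_T - eps_T)` for `I < m_T`, else
#' `(m_T + eps_T) - I`: a tent profile peaking at `eps_T` for `I = m_T`,
#' crossing zero exactly at `m_T +/- eps_T`, negative outside the band.
#'
#' @param intensity numeric vector/array of intensities.
#' @param m_T,eps_T band centre and half-width.
#' @return speed, same shape as `intensity`.
#' @export
region_speed <- function(intensity, m_T, eps_T) {
  if (eps_T < 0) stop("eps_T must be >= 0")
  ifelse(intensity < m_T,
         intensity - (m_T - eps_T),
         (m_T + eps_T) - intensity)
}

# forward/backward/central differences of a 3D array with replicated edges
shift3 <- function(a, axis, by) {
  idx <- rep(list(quote(expr = )), 3)
  n <- dim(a)[axis]
  s <- pmin(pmax(seq_len(n) + by, 1L), n)
  idx[[axis]] <- s
  do.call(`[`, c(list(a), idx))
}

diff_forward <- function(a, axis, h) (shift3(a, axis, 1L) - a) / h
diff_backward <- function(a, axis, h) (a - shift3(a, axis, -1L)) / h
diff_central <- function(a, axis, h) (shift3(a, axis, 1L) - shift3(a, axis, -1L)) / (2 * h)

# central-difference gradient magnitude
gradient_magnitude <- function(a, spacing) {
  sqrt(diff_central(a, 1, spacing[1])^2 +
         diff_central(a, 2, spacing[2])^2 +
         diff_central(a, 3, spacing[3])^2)
}

# mean curvature of the level sets of psi: div(grad psi / |grad psi|),
# computed with central differences
front_curvature <- function(psi, spacing) {
  gx <- diff_central(psi, 1, spacing[1])
  gy <- diff_central(psi, 2, spacing[2])
  gz <- diff_central(psi, 3, spacing[3])
  mag <- pmax(sqrt(gx^2 + gy^2 + gz^2), 1e-12)
  diff_central(gx / mag, 1, spacing[1]) +
    diff_central(gy / mag, 2, spacing[2]) +
    diff_central(gz / mag, 3, spacing[3])
}

#' Boundary speed field
#'
#' `F_boundary = sign * (c + k) / (1 + |grad I|)` with `k` the front mean
#' curvature from `psi` and the sign +1 where the region speed is negative,
#' -1 otherwise — the boundary term therefore always opposes the region
#' term's overshoot and anchors the front at image edges, where
#' `1 / (1 + |grad I|)` vanishes.
#'
#' @param psi_field current level-set array (same grid as the volume).
#' @param volume the `intensity_volume` being segmented.
#' @param region_field precomputed region-speed array (see [region_speed()]).
#' @param c constant advection speed.
#' @return speed array, same shape as `psi_field`.
#' @export
boundary_speed <- function(psi_field, volume, region_field, c = 1) {
  gmag <- gradient_magnitude(volume$data, volume$spacing)
  if (!all(is.finite(gmag))) stop("non-finite image gradient")
  k <- front_curvature(psi_field, volume$spacing)
  # clamp the curvature regularizer at the grid scale: finer detail than
  # 1/voxel is discretization noise and would break the CFL bound
  kmax <- 1 / min(volume$spacing)
  k <- pmin(pmax(k, -kmax), kmax)
  sgn <- ifelse(region_field < 0, 1, -1)
  sgn * (c + k) / (1 + gmag)
}

# a few sweeps of PDE re-initialization toward |grad psi| = 1, keeping the
# zero level set in place (Sussman-style, Godunov upwinding)
reinitialize_sdf <- function(psi, spacing, n_sweeps = 30L) {
  h <- min(spacing)
  s0 <- psi / sqrt(psi^2 + h^2)
  dtau <- 0.5 * h
  for (it in seq_len(n_sweeps)) {
    gm <- godunov_grad(psi, spacing, s0)
    psi <- psi - dtau * s0 * (gm - 1)
  }
  psi
}

# Godunov upwind |grad psi| for speed field f (entropy-satisfying)
godunov_grad <- function(psi, spacing, f) {
  ap <- function(x) pmax(x, 0)
  am <- function(x) pmin(x, 0)
  dxm <- diff_backward(psi, 1, spacing[1]); dxp <- diff_forward(psi, 1, spacing[1])
  dym <- diff_backward(psi, 2, spacing[2]); dyp <- diff_forward(psi, 2, spacing[2])
  dzm <- diff_backward(psi, 3, spacing[3]); dzp <- diff_forward(psi, 3, spacing[3])
  pos <- sqrt(pmax(ap(dxm)^2, am(dxp)^2) +
                pmax(ap(dym)^2, am(dyp)^2) +
                pmax(ap(dzm)^2, am(dzp)^2))
  neg <- sqrt(pmax(am(dxm)^2, ap(dxp)^2) +
                pmax(am(dym)^2, ap(dyp)^2) +
                pmax(am(dzm)^2, ap(dzp)^2))
  ifelse(f > 0, pos, ifelse(f < 0, neg, 0))
}

#' Evolve the level-set front
#'
#' Explicit upwind evolution of `psi` under the combined region/boundary
#' speed, starting from the signed distance transform of `init_mask`
#' (positive inside).  The field is re-initialized to a signed distance
#' every `reinit_every` iterations; evolution stops when the mean front
#' movement between re-initializations drops below `tol` voxels, or at
#' `n_iter_max`.
#'
#' @param volume an `intensity_volume`.
#' @param init_mask logical/0-1 array on the same grid, the initial interior.
#' @param params a [level_set_params()] object.
#' @return a `level_set_state`: list with `psi` (array, mm units, positive
#'   inside), `iteration`, `converged`, `spacing`, `origin`.
#' @export
evolve <- function(volume, init_mask, params) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(params, "level_set_params"))
  mask <- array(as.logical(init_mask), dim = dim(volume$data))
  if (!any(mask)) stop("init_mask is empty")
  sp <- volume$spacing
  h <- min(sp)
  dt <- if (is.null(params$dt)) 0.1 * h else params$dt
  psi <- mask_to_sdf(mask, sp)
  if (params$alpha_r == 0 && params$alpha_b == 0) {
    # zero total speed: the front is frozen, no iteration needed
    return(structure(list(psi = psi, iteration = 0L, converged = TRUE,
                          spacing = sp, origin = volume$origin),
                     class = "level_set_state"))
  }
  freg <- region_speed(volume$data, params$m_T, params$eps_T)
  # normalize the region term so speeds are O(1) regardless of intensity
  # units; the CFL check below then guards dt in mm
  fscale <- max(abs(freg), 1e-12)
  freg_n <- freg / fscale
  converged <- FALSE
  iter <- 0L
  psi_ref <- psi
  while (iter < params$n_iter_max) {
    iter <- iter + 1L
    speed <- params$alpha_r * freg_n
    if (params$alpha_b > 0) {
      speed <- speed +
        params$alpha_b * boundary_speed(psi, volume, freg, params$c)
    }
    upd <- dt * speed * godunov_grad(psi, sp, speed)
    if (max(abs(upd)) > 0.5 * h)
      stop("CFL violation: |update| ", signif(max(abs(upd)), 4),
           " mm exceeds half a voxel; reduce dt = ", dt)
    psi <- psi + upd
    if (iter %% params$reinit_every == 0L || iter == params$n_iter_max) {
      psi <- reinitialize_sdf(psi, sp, n_sweeps = 10L)
      band <- abs(psi_ref) < 2 * h | abs(psi) < 2 * h
      move <- mean(abs(psi[band] - psi_ref[band])) / h
      psi_ref <- psi
      if (move < params$tol) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(psi = psi, iteration = iter, converged = converged,
                 spacing = sp, origin = volume$origin),
            class = "level_set_state")
}

#' @export
print.level_set_state <- function(x, ...) {
  cat(sprintf("<level_set_state: %s grid, %d iterations, converged = %s>\n",
              paste(dim(x$psi), collapse = "x"), x$iteration, x$converged))
  invisible(x)
}

#' Interior mask of a level-set state
#'
#' @param state a `level_set_state` (or a bare psi array).
#' @return logical array, TRUE where `psi > 0` (interior by the package's
#'   sign convention).
#' @export
mask_from_levelset <- function(state) {
  psi <- if (inherits(state, "level_set_state")) state$psi else state
  if (!all(is.finite(psi))) stop("psi must be finite")
  psi > 0
}

#' Signed distance field of a binary mask
#'
#' Positive inside, negative outside, approximated by PDE re-initialization
#' of the +/- h/2 indicator field; accurate near the interface, which is
#' where the evolution and extraction use it.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing voxel spacing (mm).
#' @param n_sweeps re-initialization sweeps (each extends the accurate band
#'   by about half a voxel).
#' @return numeric array of signed distances (mm).
#' @export
mask_to_sdf <- function(mask, spacing = c(1, 1, 1), n_sweeps = 40L) {
  mask <- array(as.logical(mask), dim = dim(mask))
  h <- min(spacing)
  psi <- array(ifelse(mask, 0.5 * h, -0.5 * h), dim = dim(mask))
  psi <- reinitialize_sdf(psi, spacing, n_sweeps = n_sweeps)
  # the PDE sweeps may drift the zero crossing across an interface voxel;
  # pin the sign to the mask so mask -> sdf -> mask is the identity
  eps <- 1e-6 * h
  psi[mask & psi < eps] <- eps
  psi[!mask & psi > -eps] <- -eps
  psi
}

#' Intensity-band initialization mask
#'
#' Thresholds the volume to the band `[m_T - eps_T, m_T + eps_T]`, keeps the
#' largest 6-connected component, and optionally erodes it so the front
#' starts strictly inside the target tissue.
#'
#' @param volume an `intensity_volume`.
#' @param m_T,eps_T target band centre and half-width.
#' @param erode number of one-voxel erosion passes applied to the component.
#' @return logical array.
#' @export
threshold_init_mask <- function(volume, m_T, eps_T, erode = 1L) {
  band <- volume$data >= (m_T - eps_T) & volume$data <= (m_T + eps_T)
  if (!any(band)) stop("no voxels in the intensity band [",
                       m_T - eps_T, ", ", m_T + eps_T, "]")
  comp <- largest_component_3d(band)
  for (i in seq_len(erode)) comp <- erode_mask(comp)
  if (!any(comp)) stop("initialization mask empty after erosion")
  comp
}

# largest 6-connected component of a logical array, via igraph
largest_component_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  lin <- array(seq_along(mask), dim = d)
  edges <- NULL
  for (axis in 1:3) {
    nb <- shift3(lin, axis, 1L)
    both <- mask & shift3(mask, axis, 1L) & nb != lin
    edges <- rbind(edges, cbind(lin[both], nb[both]))
  }
  keep <- idx
  if (!is.null(edges) && nrow(edges) > 0L) {
    relab <- match(edges, idx)
    g <- igraph::graph_from_edgelist(matrix(relab, ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    keep <- idx[memb == which.max(tabulate(memb))]
  }
  out <- array(FALSE, dim = d)
  out[keep] <- TRUE
  out
}

# one pass of 6-neighbourhood binary erosion
erode_mask <- function(mask) {
  out <- mask
  for (axis in 1:3) {
    out <- out & shift3(mask, axis, 1L) & shift3(mask, axis, -1L)
  }
  out
}
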