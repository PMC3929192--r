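#' Regular-grid intensity volume
#'
#' Container for a 3D scalar image on a regular voxel grid: the raw array,
#' the voxel spacing along each axis (mm) and the world coordinate of the
#' centre of the first voxel.  World coordinates of voxel `(i, j, k)`
#' (1-based) are `origin + (c(i, j, k) - 1) * spacing`, so mesh vertices
#' produced downstream are in mm and curvature values in 1/mm.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing length-3 positive numeric, voxel edge lengths in mm.
#' @param origin length-3 numeric, world position of the first voxel centre.
#' @return an `intensity_volume` object.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("every grid dimension must be >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (!all(is.finite(data))) stop("data values must be finite")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume: %s voxels, spacing %s mm, range [%g, %g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Two-intensity sphere phantom volume
#'
#' Emulates a noiseless or noisy two-tissue image: voxels whose centre lies
#' inside a sphere of the given radius receive `inside_level`, all others
#' `outside_level`, optionally corrupted by additive Gaussian noise.  The
#' grid is sized to hold the sphere with at least a 2-voxel margin and the
#' sphere centre sits at the grid centre.  Ground truth (`center`, `radius`)
#' is attached as attributes for downstream accuracy checks.
#'
#' @param radius sphere radius in mm (must be at least 3 voxels).
#' @param spacing isotropic voxel size in mm (or length-3 vector).
#' @param inside_level,outside_level the two tissue intensities.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none).
#' @param seed integer seed making the noise reproducible.
#' @param margin extra margin around the sphere, in voxels.
#' @return an `intensity_volume` with attributes `center` and `radius`.
#' @export
sphere_volume <- function(radius, spacing = 1, inside_level = 100,
                          outside_level = 20, noise_sd = 0, seed = 1L,
                          margin = 2L) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (radius < 3 * max(spacing))
    stop("radius ", radius, " mm is unresolvable at spacing ",
         paste(spacing, collapse = "x"), " mm (need radius >= 3 voxels)")
  n <- ceiling(2 * (radius / spacing + margin)) + 1L
  center_idx <- (n - 1) / 2  # 0-based index of the grid centre
  ax <- lapply(1:3, function(k) (seq_len(n[k]) - 1 - center_idx[k]) * spacing[k])
  dx2 <- ax[[1]]^2
  dy2 <- ax[[2]]^2
  dz2 <- ax[[3]]^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  vol <- array(outside_level, dim = n)
  vol[r2 <= radius^2] <- inside_level
  if (noise_sd > 0) {
    vol <- vol + withr::with_seed(as.integer(seed),
                                  array(stats::rnorm(length(vol), 0, noise_sd),
                                        dim = n))
  }
  out <- intensity_volume(vol, spacing = spacing, origin = c(0, 0, 0))
  attr(out, "center") <- center_idx * spacing
  attr(out, "radius") <- radius
  out
}

#' Read and write volumes as NIfTI
#'
#' Spacing goes to/from `pixdim`; the origin is stored in the qform offset.
#' A written-then-read volume reproduces the grid exactly.
#'
#' @param path file path ending in `.nii`.
#' @param volume an `intensity_volume`.
#' @return `read_volume()`: an `intensity_volume`; `write_volume()`: `path`,
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("malformed NIfTI header: pixdim must be positive (got ",
         paste(pd, collapse = ", "), ")")
  hdr <- RNifti::niftiHeader(img)
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  intensity_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                   spacing = pd[1:3], origin = origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::qform(img) <- structure(
    rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1)),
    code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world coordinates (n x 3) of 0-based fractional grid indices
grid_to_world <- function(idx0, spacing, origin) {
  sweep(sweep(idx0, 2, spacing, "*"), 2, origin, "+")
}
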