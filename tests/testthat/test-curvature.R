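test_that("mixed areas tile the surface and match closed forms", {
  ico <- icosphere_mesh(1, 0)
  am <- mixed_area(ico)
  # every icosahedron vertex: 5 equilateral triangles, Voronoi share T/3
  t_area <- mesh_area(ico) / 20
  expect_equal(am, rep(5 * t_area / 3, 12), tolerance = 1e-12)
  for (m in list(icosphere_mesh(5, 2), torus_mesh(2, 1, 12, 12),
                 folded_phantom_mesh(10, 4, 1.5, 2))) {
    expect_equal(sum(mixed_area(m)), mesh_area(m), tolerance = 1e-9)
  }
})

test_that("obtuse triangles contribute T/2 at the obtuse corner, T/4 elsewhere", {
  # one triangle, obtuse at vertex 1
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0.2, 0), c(-1, 0.2, 0)),
                       rbind(c(1, 2, 3)))
  t_area <- mesh_area(tri)
  expect_equal(mixed_area(tri, 1), t_area / 2, tolerance = 1e-12)
  expect_equal(mixed_area(tri, 2), t_area / 4, tolerance = 1e-12)
  expect_equal(mixed_area(tri, 3), t_area / 4, tolerance = 1e-12)
})

test_that("degenerate faces and isolated vertices are rejected", {
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       rbind(c(1, 2, 3)))  # collinear: zero area
  expect_error(mixed_area(bad), "degenerate")
  lone <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                        rbind(c(1, 2, 3)))
  expect_error(vertex_quadric(lone, 4), "no incident face")
})

test_that("mean curvature recovers 1/R on spheres with a negative sign", {
  m <- icosphere_mesh(5, 3)
  mh <- mean_curvature(m)
  expect_lt(max(abs(mh$magnitude - 0.2) / 0.2), 0.02)
  expect_true(all(mh$signed < 0))  # convex surface, outward normals
  expect_equal(mh$magnitude, abs(mh$signed))
})

test_that("flat patches have zero mean-curvature vector in the interior", {
  p <- flat_patch(5)
  mh <- mean_curvature(p)
  interior <- !mh$boundary
  expect_gt(sum(interior), 0)
  expect_lt(max(abs(mh$magnitude[interior])), 1e-9)
  # boundary vertices are flagged and undefined
  expect_true(all(is.na(mh$magnitude[mh$boundary])))
})

test_that("Gaussian curvature matches the angle-deficit closed forms", {
  cube <- cube_mesh()
  gg <- gaussian_curvature(cube)
  expect_equal(gg$deficit, rep(pi / 2, 8), tolerance = 1e-12)
  expect_equal(gg$k_g, (pi / 2) / mixed_area(cube), tolerance = 1e-12)
  m <- icosphere_mesh(5, 3)
  expect_lt(max(abs(gaussian_curvature(m)$k_g - 0.04) / 0.04), 0.02)
})

test_that("discrete Gauss-Bonnet holds exactly on closed meshes", {
  for (fix in list(list(m = icosphere_mesh(5, 2), chi = 2),
                   list(m = torus_mesh(2, 1, 16, 16), chi = 0),
                   list(m = cube_mesh(), chi = 2),
                   list(m = folded_phantom_mesh(10, 6, 2, 2), chi = 2))) {
    d <- vertex_differentials(fix$m)
    total <- sum(d$k_g * d$a_m)
    expect_lt(abs(total - 2 * pi * fix$chi), 1e-8 * max(1, 2 * pi * abs(fix$chi)))
  }
})

test_that("principal curvatures follow the corrected delta with clamping", {
  pc <- principal_curvatures(-1, 1)
  expect_equal(pc$k_max, -1)      # umbilic: delta = 0
  expect_equal(pc$k_min, -1)
  pc <- principal_curvatures(0, -1)
  expect_equal(pc$k_max, 1)       # symmetric saddle
  expect_equal(pc$k_min, -1)
  pc <- principal_curvatures(0, 0.5)
  expect_equal(pc$k_max, 0)       # clamp branch: K_H^2 < K_G
  expect_equal(pc$k_min, 0)
  # k_max + k_min = 2 K_H whenever the clamp is inactive
  kh <- runif(50, -2, 2)
  kg <- kh^2 - runif(50, 0, 3)    # guarantees K_H^2 - K_G >= 0
  pc <- principal_curvatures(kh, kg)
  expect_equal(pc$k_max + pc$k_min, 2 * kh, tolerance = 1e-12)
  expect_true(all(pc$k_max >= pc$k_min))
  # legacy printed variant differs and is opt-in
  expect_false(isTRUE(all.equal(
    principal_curvatures(1, 0.5, printed_delta = TRUE)$delta,
    principal_curvatures(1, 0.5)$delta)))
})

test_that("shape index matches closed forms and stays in [-1, 1]", {
  expect_equal(shape_index(-1, -1), 1)    # convex umbilic
  expect_equal(shape_index(1, 1), -1)     # concave umbilic
  expect_equal(shape_index(1, -1), 0)     # symmetric saddle
  expect_equal(shape_index(2, 1), -(2 / pi) * atan(3), tolerance = 1e-12)
  expect_true(is.na(shape_index(0, 0)))   # flat point: undefined, no error
  ks <- seq(-10, 10, length.out = 81)
  grid <- expand.grid(k_max = ks, k_min = ks)
  grid <- grid[grid$k_max >= grid$k_min, ]
  si <- shape_index(grid$k_max, grid$k_min)
  si <- si[!is.na(si)]
  expect_true(all(si >= -1 & si <= 1))
})

test_that("curvature descriptors are rigid-motion invariant", {
  m <- folded_phantom_mesh(10, 4, 1.5, 2)
  d0 <- vertex_differentials(m)
  # a fixed arbitrary rotation (QR of a seeded random matrix)
  set.seed(11)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  mt <- transform_mesh(m, rotation = R, translation = c(3.2, -7.1, 12.5))
  d1 <- vertex_differentials(mt)
  expect_lt(max(abs(d1$k_h_mag - d0$k_h_mag)), 1e-9)
  expect_lt(max(abs(d1$k_g - d0$k_g)), 1e-9)
  expect_lt(max(abs(d1$si - d0$si)), 1e-9)
})

test_that("curvatures obey the scaling law and the shape index does not", {
  m <- folded_phantom_mesh(10, 4, 1.5, 2)
  d0 <- vertex_differentials(m)
  for (s in c(0.5, 2)) {
    ds <- vertex_differentials(scale_mesh(m, s))
    expect_equal(ds$k_h_signed, d0$k_h_signed / s, tolerance = 1e-9)
    expect_equal(ds$k_g, d0$k_g / s^2, tolerance = 1e-9)
    expect_equal(ds$si, d0$si, tolerance = 1e-9)
  }
})

test_that("curvature errors shrink monotonically with mesh refinement", {
  errs <- vapply(2:4, function(s) {
    d <- vertex_differentials(icosphere_mesh(5, s))
    c(kh = max(abs(d$k_h_mag - 0.2) / 0.2),
      kg = max(abs(d$k_g - 0.04) / 0.04))
  }, numeric(2))
  expect_true(all(diff(errs["kh", ]) < 0))
  expect_true(all(diff(errs["kg", ]) < 0))
})

test_that("vertex_differentials returns a coherent per-vertex tibble", {
  m <- icosphere_mesh(5, 2)
  d <- vertex_differentials(m)
  expect_s3_class(d, "tbl_df")
  expect_equal(nrow(d), n_vertices(m))
  expect_true(all(d$a_m > 0))
  expect_true(all(d$k_max >= d$k_min))
  expect_equal(d$k_h_mag, abs(d$k_h_signed))
  expect_true(all(abs(d$k_max + d$k_min - 2 * d$k_h_signed) < 1e-12 |
                    d$delta == 0))
  expect_false(any(d$boundary))
  expect_lt(max(abs(d$si - 1)), 0.05)  # sphere: SI ~ +1 everywhere
})
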