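test_that("region speed is the tent profile with zeros at the band edges", {
  expect_equal(region_speed(100, 100, 30), 30)     # I = m_T -> eps_T
  expect_equal(region_speed(70, 100, 30), 0)       # I = m_T - eps_T
  expect_equal(region_speed(160, 100, 30), -30)    # I = m_T + 2 eps_T
  # continuous, sign changes exactly at m_T +/- eps_T
  I <- seq(0, 200, by = 0.01)
  f <- region_speed(I, 100, 30)
  expect_lt(max(abs(diff(f))), 0.011)              # Lipschitz constant 1
  expect_true(all(f[I > 70 & I < 130] > 0))
  expect_true(all(f[I < 70 | I > 130] < 0))
  expect_error(region_speed(1, 0, -1), "eps_T")
})

test_that("boundary speed has the region-driven sign and (c+k)/(1+|gradI|) magnitude", {
  dims <- c(12, 12, 12)
  uniform <- intensity_volume(array(50, dims))
  # planar front: psi = x - 6 (zero curvature)
  psi <- array(rep(seq_len(dims[1]) - 6, times = prod(dims[2:3])), dims)
  freg_neg <- array(-1, dims)
  fb <- boundary_speed(psi, uniform, freg_neg, c = 2)
  inner <- 3:10
  expect_true(all(fb > 0))                          # F_region < 0 -> +1
  expect_equal(fb[inner, inner, inner],
               array(2, dim = rep(length(inner), 3)), tolerance = 1e-9)
  freg_pos <- array(1, dims)
  fb2 <- boundary_speed(psi, uniform, freg_pos, c = 2)
  expect_true(all(fb2 < 0))                         # otherwise -> -1
  # steep image gradient kills the magnitude
  ramp <- intensity_volume(array(rep(seq_len(dims[1]) * 1e6,
                                     times = prod(dims[2:3])), dims))
  fb3 <- boundary_speed(psi, ramp, freg_neg, c = 2)
  expect_lt(max(abs(fb3[inner, inner, inner])), 1e-4)
})

test_that("zero speed freezes the front", {
  vol <- sphere_volume(6, 1)
  mask <- vol$data == 100
  p0 <- level_set_params(100, 30, alpha_r = 0, alpha_b = 0)
  st <- evolve(vol, mask, p0)
  expect_identical(st$psi, mask_to_sdf(mask, vol$spacing))
  expect_true(st$converged)
})

test_that("level-set segmentation recovers the sphere interface", {
  vol <- sphere_volume(8, 1, inside_level = 100, outside_level = 20)
  params <- level_set_params(m_T = 100, eps_T = 30)
  init <- threshold_init_mask(vol, 100, 30, erode = 3)
  st <- evolve(vol, init, params)
  expect_true(st$converged)
  front <- extract_isosurface(st)
  r <- sqrt(rowSums(sweep(front$vertices, 2, attr(vol, "center"))^2))
  expect_lt(max(abs(r - 8)), 1)          # within one voxel of the truth
  # determinism: identical inputs, identical psi
  st2 <- evolve(vol, init, params)
  expect_identical(st$psi, st2$psi)
})

test_that("starting at the true region stays there", {
  vol <- sphere_volume(8, 1)
  truemask <- vol$data == 100
  st <- evolve(vol, truemask, level_set_params(100, 30))
  expect_true(st$converged)
  final <- mask_from_levelset(st)
  moved <- final != truemask
  # any changed voxel must sit on the interface (a 6-neighbour differs)
  if (any(moved)) {
    on_iface <- interface_voxels(truemask)
    expect_true(all(moved[!on_iface] == FALSE))
  }
  expect_lt(st$iteration, 120)  # settles much faster than a cold start
})

test_that("with the boundary term off the mask converges to the intensity band", {
  vol <- sphere_volume(8, 1, inside_level = 100, outside_level = 20)
  init <- threshold_init_mask(vol, 100, 30, erode = 2)
  st <- evolve(vol, init, level_set_params(100, 30, alpha_r = 1, alpha_b = 0))
  band <- vol$data > 70 & vol$data < 130
  differs <- mask_from_levelset(st) != band
  on_iface <- interface_voxels(band)
  expect_true(all(!differs | on_iface))  # mismatches only in a 1-voxel band
})

test_that("CFL violations are reported with the offending dt", {
  vol <- sphere_volume(8, 1)
  init <- threshold_init_mask(vol, 100, 30)
  bad <- level_set_params(100, 30, dt = 5)
  expect_error(evolve(vol, init, bad), "CFL.*dt = 5")
})

test_that("mask -> signed distance -> mask is the identity", {
  vol <- sphere_volume(8, 1)
  mask <- vol$data == 100
  expect_identical(mask_from_levelset(mask_to_sdf(mask, vol$spacing)), mask)
  # far-field distances are close to true Euclidean distance on the sphere
  sdf <- mask_to_sdf(mask, vol$spacing)
  ctr <- attr(vol, "center")
  idx <- which(abs(sdf) < 4, arr.ind = TRUE)
  true_d <- 8 - sqrt(rowSums(sweep((idx - 1), 2, ctr)^2))
  expect_lt(stats::median(abs(sdf[idx] - true_d)), 0.6)
})

test_that("mask_from_levelset follows the positive-inside convention", {
  expect_false(any(mask_from_levelset(array(-1, c(3, 3, 3)))))
  psi <- mask_to_sdf(sphere_volume(6, 1)$data == 100)
  expect_identical(mask_from_levelset(psi), psi > 0)
  expect_error(mask_from_levelset(array(c(NA, 1), c(2, 2, 2))), "finite")
})

test_that("threshold initialization keeps the largest in-band component", {
  vol <- sphere_volume(8, 1)
  # add a tiny far-away bright blob that must be discarded
  vol$data[1:2, 1:2, 1:2] <- 100
  init <- threshold_init_mask(vol, 100, 30, erode = 0)
  expect_false(any(init[1:2, 1:2, 1:2]))
  expect_gt(sum(init), 1000)
  expect_error(threshold_init_mask(vol, 1e5, 1), "no voxels")
})
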