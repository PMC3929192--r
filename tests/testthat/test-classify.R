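fake_diffs <- function(kh, kg, si) {
  tibble::tibble(k_h_signed = kh, k_g = kg, si = si,
                 boundary = FALSE, flat = FALSE)
}

test_that("strict classification follows the sign pairs and SI intervals", {
  expect_equal(as.character(classify_vertices(
    fake_diffs(-1, 1, 0.9), "strict")), "ELLIPTIC_GREEN")
  expect_equal(as.character(classify_vertices(
    fake_diffs(1, -1, -0.2), "strict")), "HYPERBOLIC_BLUE")
  expect_equal(as.character(classify_vertices(
    fake_diffs(-1, -1, 0.9), "strict")), "UNCLASSIFIED")  # SI not in [1/8,3/8]
  expect_equal(as.character(classify_vertices(
    fake_diffs(-1, -1, 0.25), "strict")), "HYPERBOLIC_CYAN")
  expect_equal(as.character(classify_vertices(
    fake_diffs(1, 1, -0.8), "strict")), "ELLIPTIC_RED")
  # the SI gaps demote to UNCLASSIFIED
  expect_equal(as.character(classify_vertices(
    fake_diffs(1, 1, -0.5), "strict")), "UNCLASSIFIED")
  expect_equal(as.character(classify_vertices(
    fake_diffs(-1, 1, 0.05), "strict")), "UNCLASSIFIED")
})

test_that("sign-only classification uses the sign pair alone", {
  d <- fake_diffs(c(-1, -1, 1, 1), c(1, -1, -1, 1), c(0.9, 0.9, -0.9, -0.9))
  expect_equal(as.character(classify_vertices(d, "sign_only")),
               c("ELLIPTIC_GREEN", "HYPERBOLIC_CYAN", "HYPERBOLIC_BLUE",
                 "ELLIPTIC_RED"))
  # near-zero curvatures are sign noise -> UNCLASSIFIED
  expect_equal(as.character(classify_vertices(
    fake_diffs(1e-12, 1, 0.9), "sign_only", zero_tol = 1e-6)), "UNCLASSIFIED")
  # undefined differentials classify silently, no exception
  nad <- fake_diffs(NA_real_, NA_real_, NA_real_)
  expect_equal(as.character(classify_vertices(nad)), "UNCLASSIFIED")
})

test_that("strict mode only ever demotes relative to sign-only", {
  m <- folded_phantom_mesh(10, 6, 2, 3)
  d <- vertex_differentials(m)
  s_only <- classify_vertices(d, "sign_only")
  strict <- classify_vertices(d, "strict")
  agree <- strict == s_only | strict == "UNCLASSIFIED"
  expect_true(all(agree))
})

test_that("labeling summarises a surface coherently", {
  m <- icosphere_mesh(5, 2)
  d <- vertex_differentials(m)
  lab <- label_surface(m, d)
  expect_s3_class(lab, "surface_labeling")
  expect_equal(sum(lab$histogram), n_vertices(m))
  expect_equal(sum(lab$area_fraction), 1, tolerance = 1e-12)
  # sphere: all convex-elliptic in sign mode, nearly all in strict mode
  expect_equal(lab$histogram[["ELLIPTIC_GREEN"]], n_vertices(m))
  strict <- label_surface(m, d, mode = "strict")
  expect_gte(strict$histogram[["ELLIPTIC_GREEN"]], 0.99 * n_vertices(m))
  # colors map 1:1 to classes
  expect_identical(lab$labels$color,
                   unname(surface_class_colors[as.character(lab$labels$class)]))
  expect_error(label_surface(m, d[-1, ]), "vertices")
})

test_that("torus rings separate into elliptic and hyperbolic classes", {
  m <- torus_mesh(2, 1, 32, 16)
  lab <- label_surface(m, vertex_differentials(m))
  rr <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  outer_cls <- lab$labels$class[rr > 2.7]
  inner_cls <- lab$labels$class[rr < 1.3]
  expect_true(all(outer_cls == "ELLIPTIC_GREEN"))
  expect_true(all(inner_cls %in% c("HYPERBOLIC_CYAN", "HYPERBOLIC_BLUE")))
})

test_that("folded-phantom landmarks get their anatomical classes", {
  m <- folded_phantom_mesh(10, 6, 2, 3)
  lab <- label_surface(m, vertex_differentials(m))
  crest_cls <- lab$labels$class[attr(m, "crest_vertices")]
  fundus_cls <- lab$labels$class[attr(m, "fundus_vertices")]
  expect_gt(mean(crest_cls == "ELLIPTIC_GREEN"), 0.5)
  expect_gt(mean(fundus_cls == "ELLIPTIC_RED"), 0.5)
})

test_that("crest curvature magnitude grows with fold amplitude", {
  kh_crest <- vapply(c(1, 2, 3), function(a) {
    m <- folded_phantom_mesh(10, 6, a, 3)
    d <- vertex_differentials(m)
    mean(abs(d$k_h_signed[attr(m, "crest_vertices")]))
  }, numeric(1))
  expect_true(all(diff(kh_crest) > 0))
})

test_that("multiresolution agreement is 1 on identical labelings", {
  m <- folded_phantom_mesh(10, 6, 2, 2)
  lab <- label_surface(m, vertex_differentials(m))
  a <- multires_label_agreement(lab, m, lab, m)
  expect_equal(a$agreement, 1)
  expect_equal(a$n_compared + a$n_unclassified_pairs, n_vertices(m))
})

test_that("agreement under label permutation matches the chance level", {
  # balanced synthetic labels -> chance agreement 1/4
  m <- icosphere_mesh(5, 3)
  nv <- n_vertices(m)
  cls <- factor(rep(c("ELLIPTIC_GREEN", "HYPERBOLIC_CYAN",
                      "HYPERBOLIC_BLUE", "ELLIPTIC_RED"),
                    length.out = nv),
                levels = names(surface_class_colors))
  lab <- label_surface(m, vertex_differentials(m))
  lab$labels$class <- cls
  perm <- lab
  set.seed(99)
  agreements <- replicate(20, {
    perm$labels$class <- sample(cls)
    multires_label_agreement(lab, m, perm, m)$agreement
  })
  expect_lt(abs(mean(agreements) - 0.25), 0.02)
})

test_that("classes survive 50% decimation on the folded phantom", {
  m <- folded_phantom_mesh(10, 6, 2, 3)
  lab <- label_surface(m, vertex_differentials(m))
  dec <- quadric_decimate(m, 0.5)
  lab_d <- label_surface(dec, vertex_differentials(dec))
  expect_gt(lab_d$histogram[["ELLIPTIC_GREEN"]], 0)
  expect_gt(lab_d$histogram[["ELLIPTIC_RED"]], 0)
  a <- multires_label_agreement(lab, m, lab_d, dec)
  expect_gt(a$agreement, 0.5)
  expect_error(multires_label_agreement(lab, m,
                                        structure(list(labels = lab$labels[0, ],
                                                       mode = "sign_only"),
                                                  class = "surface_labeling"),
                                        dec),
               "empty")
})

test_that("tidy, glance and autoplot expose the labeling", {
  m <- icosphere_mesh(5, 1)
  lab <- label_surface(m, vertex_differentials(m))
  td <- generics::tidy(lab)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("vertex", "class", "color", "si", "consistent"))
  gl <- generics::glance(lab)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_vertices, n_vertices(m))
  p <- ggplot2::autoplot(lab, m)
  expect_s3_class(p, "ggplot")
})
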