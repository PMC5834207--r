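test_that("rounded boxes are watertight with the requested extents", {
  m <- small_cube_mesh()
  expect_true(is_watertight(m))
  bb <- apply(m$vertices, 2, range)
  expect_equal(unname(bb[2, ] - bb[1, ]), c(4, 4, 4), tolerance = 1e-9)
  expect_true(all(abs(sqrt(rowSums(m$normals^2)) - 1) < 1e-9))
  # outward normals
  ctr <- colMeans(m$vertices)
  expect_true(all(rowSums(m$normals * sweep(m$vertices, 2, ctr)) > 0))
})

test_that("the standard cube has its stated extents and Minkowski area", {
  m <- cached("sharp_cube_fine", build_rounded_box(c(8.8, 8.8, 8.8), 1.3))
  bb <- apply(m$vertices, 2, range)
  expect_equal(unname(bb[2, ] - bb[1, ]), c(8.8, 8.8, 8.8), tolerance = 1e-9)
  expect_equal(sqrt(sum((bb[2, ] - bb[1, ])^2)), 8.8 * sqrt(3),
               tolerance = 1e-9)
  # rounded corners: the outermost vertex sits at |inner corner| + radius
  expect_equal(max(sqrt(rowSums(m$vertices^2))), sqrt(3) * 3.1 + 1.3,
               tolerance = 0.02)
  s <- 8.8; r <- 1.3
  analytic <- 6 * (s - 2 * r)^2 + 12 * (pi * r / 2) * (s - 2 * r) +
    4 * pi * r^2
  expect_equal(surface_area(m), analytic, tolerance = 0.01)
  # smoothing reduces area relative to the sharp parent box
  expect_lt(surface_area(m), 6 * s^2)
})

test_that("corner radius at half the side yields a sphere", {
  m <- build_rounded_box(c(4, 4, 4), 2, resolution = 0.5)
  r <- sqrt(rowSums(m$vertices^2))
  expect_true(all(abs(r - 2) / 2 < 0.02))
})

test_that("excessive corner radius is rejected", {
  expect_error(build_rounded_box(c(4, 4, 4), 2.5), "corner_radius")
  expect_error(build_rounded_box(c(4, 4, -1), 1), "positive")
})

test_that("ellipsoids are watertight with quadrature-checked area", {
  e <- cached("ellipsoid_test", build_ellipsoid(c(10.3, 10.3, 16.8),
                                                resolution = 0.5))
  expect_true(is_watertight(e))
  expect_equal(surface_area(e), ellipsoid_area_quadrature(5.15, 8.4),
               tolerance = 0.02)
  expect_error(build_ellipsoid(c(4, 5, 6)), "two equal axes")
  s <- build_ellipsoid(c(6, 6, 6), resolution = 0.5)
  expect_true(all(abs(sqrt(rowSums(s$vertices^2)) - 3) < 0.02))
})

test_that("nearest_surface matches the brute-force all-triangle scan", {
  m <- small_cube_mesh()
  set.seed(42)
  pts <- matrix(stats::runif(3 * 40, -1.9, 1.9), ncol = 3)
  res <- nearest_surface(m, pts)
  for (i in seq_len(nrow(pts))) {
    expect_equal(res$distance[i], brute_force_mesh_distance(m, pts[i, ]),
                 tolerance = 1e-6)
  }
  # containment agrees with the analytic rounded-box membership
  # (points deep in the corners of the sampling cube are outside)
  truth <- rounded_box_inside(pts, c(4, 4, 4), 1)
  agree <- res$inside == truth
  # allow disagreement only within a mesh-facet tolerance of the surface
  expect_true(all(agree | res$distance < 0.02))
  # distance equals the Euclidean distance to the returned nearest point
  d2 <- sqrt(rowSums((pts - res$nearest)^2))
  expect_equal(res$distance, d2, tolerance = 1e-9)
})

test_that("containment and known distances behave as expected", {
  m <- small_cube_mesh()
  p <- nearest_surface(m, c(0, 0, 0))
  expect_true(p$inside)
  expect_equal(p$distance, 2, tolerance = 1e-6)
  expect_false(nearest_surface(m, c(8, 0, 0))$inside)
  e <- cached("ellipsoid_test", build_ellipsoid(c(10.3, 10.3, 16.8),
                                                resolution = 0.5))
  expect_equal(nearest_surface(e, c(0, 0, 0))$distance, 5.15,
               tolerance = 0.01)
  # sphere: distance from an interior point is R - r
  s <- build_rounded_box(c(4, 4, 4), 2, resolution = 0.5)
  expect_equal(nearest_surface(s, c(0.5, 0, 0))$distance, 1.5,
               tolerance = 0.02)
})

test_that("tangent planes pass through the probe with its normal", {
  m <- small_cube_mesh()
  pr <- nearest_surface(m, c(0, 0, 1.99))
  pl <- tangent_plane(pr)
  expect_equal(unname(pl$normal), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(pl$point, pr$nearest_point)
  # any tangential vector is orthogonal to the normal
  t1 <- c(pl$normal[2], -pl$normal[1], 0)
  expect_equal(sum(t1 * pl$normal), 0, tolerance = 1e-12)
  # on a sphere the plane normal is radial
  s <- build_rounded_box(c(4, 4, 4), 2, resolution = 0.5)
  q <- c(1, 1, 1) / sqrt(3) * 1.8
  prs <- nearest_surface(s, q)
  expect_gt(sum(prs$normal * q / sqrt(sum(q^2))), 0.999)
})

test_that("surface sampling is uniform per unit area and reproducible", {
  m <- small_cube_mesh()
  set.seed(7)
  s1 <- sample_surface_point(m, 20000)
  set.seed(7)
  s2 <- sample_surface_point(m, 20000)
  expect_identical(s1$points, s2$points)
  # sampled points lie on the surface
  d <- nearest_surface(m, s1$points[1:500, ])$distance
  expect_true(all(d < 1e-9))
  # chi-squared against per-triangle areas
  v <- m$vertices; f <- m$faces
  fn <- cross3_rows(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  areas <- sqrt(rowSums(fn^2)) / 2
  counts <- tabulate(s1$triangle, nbins = nrow(f))
  expected <- areas / sum(areas) * length(s1$triangle)
  chi2 <- sum((counts - expected)^2 / expected)
  expect_gt(stats::pchisq(chi2, df = nrow(f) - 1, lower.tail = FALSE), 0.01)
})

test_that("surface area converges under mesh refinement", {
  a1 <- surface_area(build_rounded_box(c(4, 4, 4), 1, resolution = 0.5))
  a2 <- surface_area(build_rounded_box(c(4, 4, 4), 1, resolution = 0.25))
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("meshes round-trip through OBJ and PLY", {
  m <- small_cube_mesh()
  for (ext in c("obj", "ply")) {
    path <- file.path(tempdir(), paste0("mesh_test.", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(m2$faces, m$faces)
    expect_equal(m2$normals, m$normals, tolerance = 1e-6,
                 ignore_attr = TRUE)
    unlink(path)
  }
})
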