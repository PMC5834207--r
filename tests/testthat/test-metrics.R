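test_that("nematic order parameter reproduces closed-form cases", {
  # perfectly aligned
  d <- matrix(rep(c(0, 0, 1), 100), 100, 3, byrow = TRUE)
  expect_equal(local_anisotropy(d)$A, 1, tolerance = 1e-12)
  # equal split over two orthogonal directions: eigenvalues (1/2, 1/2, 0)
  d2 <- rbind(matrix(rep(c(1, 0, 0), 50), 50, 3, byrow = TRUE),
              matrix(rep(c(0, 1, 0), 50), 50, 3, byrow = TRUE))
  expect_equal(local_anisotropy(d2)$A, sqrt(0.5), tolerance = 1e-12)
  # all two-direction mixtures against eigenvalue closed form
  set.seed(8)
  for (w in c(0.1, 0.25, 0.5, 0.8, 0.95)) {
    n <- 2000
    n1 <- round(w * n)
    dd <- rbind(matrix(rep(c(1, 0, 0), n1), n1, 3, byrow = TRUE),
                matrix(rep(c(0, 0, 1), n - n1), n - n1, 3, byrow = TRUE))
    lam <- c(n1 / n, 1 - n1 / n, 0)
    expect_equal(local_anisotropy(dd)$A, anisotropy_from_eigenvalues(lam),
                 tolerance = 1e-10)
  }
  expect_error(local_anisotropy(matrix(0, 0, 3)), "undefined")
})

test_that("isotropic direction clouds have near-zero anisotropy", {
  snap <- make_fixture("isotropic_cloud")
  d <- as.matrix(snap[, c("dx", "dy", "dz")])
  expect_lt(local_anisotropy(d)$A, 0.02)
})

test_that("anisotropy is invariant under rotations and sign flips", {
  set.seed(9)
  d <- random_unit_vector(500)
  d[1:300, ] <- matrix(rep(c(0.6, 0, 0.8), 300), 300, 3, byrow = TRUE)
  a0 <- local_anisotropy(d)$A
  for (i in 1:5) {
    R <- random_rotation()
    flip <- sample(c(-1, 1), 500, replace = TRUE)
    expect_equal(local_anisotropy((d %*% R) * flip)$A, a0, tolerance = 1e-9)
  }
})

test_that("grid anisotropy averages local order over occupied cubes", {
  snap <- make_fixture("aligned_cloud")
  g <- grid_anisotropy(snap)
  expect_equal(g$cell_average, 1, tolerance = 1e-12)
  expect_equal(g$grid, c(3, 3, 3))
  # a single occupied cube dominates the average
  one <- snap[snap$x_um < 0.34 & snap$y_um < 0.34 & snap$z_um < 0.34, ]
  g1 <- grid_anisotropy(one)
  expect_equal(g1$cell_average, g1$per_cube$A[1])
  expect_error(grid_anisotropy(snap[0, ]), "empty")
})

test_that("bundle fraction matches geometric expectations on fixtures", {
  expect_equal(bundle_fraction(make_fixture("two_parallel")), 1)
  expect_lt(bundle_fraction(make_fixture("two_crossing")), 0.05)
  single <- make_fixture("two_parallel")
  single <- single[single$mt_id == 0, ]
  expect_equal(bundle_fraction(single), 0)
})

test_that("bundle fraction is monotone in both thresholds", {
  m <- small_cube_mesh()
  traj <- cached("run_small_default",
                 run_simulation(m, growth_params(), n_steps = 1500, seed = 5,
                                snapshot_interval = 1500))
  snap <- final_snapshot(traj)
  b1 <- bundle_fraction(snap, dist_thresh = 0.015, angle_deg = 40)
  b2 <- bundle_fraction(snap, dist_thresh = 0.025, angle_deg = 40)
  b3 <- bundle_fraction(snap, dist_thresh = 0.025, angle_deg = 60)
  expect_lte(b1, b2)
  expect_lte(b2, b3)
})

test_that("membrane distance metric is exact on a placed segment", {
  fx <- make_fixture("single_near_face")
  expect_equal(mean_membrane_distance(fx$snapshot, fx$mesh), 100,
               tolerance = 0.01)
  # per-microtubule variant agrees for a single filament
  expect_equal(mean_membrane_distance(fx$snapshot, fx$mesh,
                                      per = "microtubule"), 100,
               tolerance = 0.01)
})

test_that("strong anchoring keeps the network on the membrane", {
  m <- small_cube_mesh()
  traj <- cached("run_small_strong",
                 run_simulation(m, growth_params(anchoring = "strong"),
                                n_steps = 1500, seed = 6,
                                snapshot_interval = 1500))
  snap <- final_snapshot(traj)
  expect_gt(nrow(snap), 100)
  expect_lt(mean_membrane_distance(snap, m), 5) # nm; within mesh tolerance
})

test_that("face orientation histograms peak where the directions point", {
  m <- small_cube_mesh()
  # segments along the reference axis near the top face
  n <- 200
  pos <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1),
               stats::runif(n, 1.8, 2))
  dir <- matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE)
  snap <- raw_snapshot(pos, dir, seq_len(n))
  h <- face_orientation_histogram(snap, m, c(0, 0, 1), c(1, 0, 0),
                                  bins = 18)
  expect_equal(h$n, n)
  expect_lt(abs(h$mids[which.max(h$counts)]), 10)  # modal bin straddles 0
  # diagonal directions produce symmetric peaks at +-45 degrees
  dir45 <- matrix(rep(c(1, 1, 0) / sqrt(2), n), n, 3, byrow = TRUE)
  dir45[seq(1, n, 2), 2] <- -dir45[seq(1, n, 2), 2]
  h45 <- face_orientation_histogram(raw_snapshot(pos, dir45, seq_len(n)),
                                    m, c(0, 0, 1), c(1, 0, 0), bins = 18)
  peaks <- order(h45$counts, decreasing = TRUE)[1:2]
  expect_setequal(round(h45$mids[peaks]), c(-45, 45))
  # empty selection warns
  far <- raw_snapshot(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3), 1L)
  expect_warning(face_orientation_histogram(far, m, c(0, 0, 1), c(1, 0, 0)),
                 "empty")
})

test_that("axis alignment histograms separate axial from hoop networks", {
  n <- 500
  pos <- matrix(stats::runif(3 * n), n, 3)
  axial <- raw_snapshot(pos, matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE),
                        seq_len(n))
  ha <- axis_alignment_histogram(axial, c(0, 0, 1))
  expect_equal(ha$counts[length(ha$counts)], n)
  th <- stats::runif(n, 0, 2 * pi)
  hoop <- raw_snapshot(pos, cbind(cos(th), sin(th), 0), seq_len(n))
  hh <- axis_alignment_histogram(hoop, c(0, 0, 1))
  expect_equal(hh$counts[1], n)
  expect_equal(sum(hh$counts), n)
})

test_that("network summaries count filaments and mean length", {
  mts <- list(microtubule(0L, c(0, 0, 0), matrix(rep(c(1, 0, 0), 10), 10, 3,
                                                 byrow = TRUE)),
              microtubule(1L, c(0, 1, 0), matrix(rep(c(1, 0, 0), 20), 20, 3,
                                                 byrow = TRUE)),
              microtubule(2L, c(0, 2, 0), matrix(rep(c(1, 0, 0), 30), 30, 3,
                                                 byrow = TRUE)))
  snap <- cortisim:::snapshot_from_mts(mts)
  s <- network_summary(snap)
  expect_equal(s$n_microtubules, 3L)
  expect_equal(s$mean_length_um, 0.16)
  expect_equal(s$total_segments, 60L)
  s0 <- network_summary(snap[0, ])
  expect_equal(s0$n_microtubules, 0L)
  expect_equal(s0$mean_length_um, 0)
})
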