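quiet_params <- function(...) {
  growth_params(n_p = 0, n_s = 0, r_d = 0, ...)
}

test_that("a lone microtubule grows one segment per step", {
  m <- small_cube_mesh()
  sim <- simulation(m, quiet_params(), seed = 1)
  sim_add_microtubule(sim, c(-0.5, 0, 0), matrix(c(1, 0, 0), 1, 3))
  sim_step(sim, 10)
  snap <- sim_snapshot(sim)
  expect_equal(nrow(snap), 11)
  expect_equal(max(snap$x_um), -0.5 + 11 * 0.008, tolerance = 1e-12)
})

test_that("a microtubule shrinking at both ends disappears in length/2 steps", {
  m <- small_cube_mesh()
  sim <- simulation(m, quiet_params(), seed = 1)
  sim_add_microtubule(sim, c(-0.5, 0, 0),
                      matrix(rep(c(1, 0, 0), 6), 6, 3, byrow = TRUE),
                      minus_shrinking = TRUE, plus_cat = TRUE)
  sim_step(sim, 2)
  expect_equal(nrow(sim_snapshot(sim)), 2)
  sim_step(sim, 1)
  expect_equal(nrow(sim_snapshot(sim)), 0)
  # bookkeeping stays exact through the removal (6 seeded segments)
  tr <- sim_trace(sim)
  expect_identical(diff(c(6L, tr$n_segments)), tr$added - tr$removed)
})

test_that("a shrinking minus end with growth disabled erases the filament", {
  m <- small_cube_mesh()
  sim <- simulation(m, quiet_params(), seed = 1)
  # plus end in catastrophe so it also shrinks: use minus shrinkage only
  sim_add_microtubule(sim, c(-0.5, 0, 0),
                      matrix(rep(c(1, 0, 0), 5), 5, 3, byrow = TRUE),
                      minus_shrinking = TRUE, plus_cat = FALSE)
  # tip keeps growing while the minus end shrinks: constant length
  sim_step(sim, 5)
  expect_equal(nrow(sim_snapshot(sim)), 5)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- small_cube_mesh()
  p <- growth_params()
  t1 <- run_simulation(m, p, n_steps = 300, seed = 42,
                       snapshot_interval = 300)
  t2 <- run_simulation(m, p, n_steps = 300, seed = 42,
                       snapshot_interval = 300)
  expect_identical(final_snapshot(t1), final_snapshot(t2))
  t3 <- run_simulation(m, p, n_steps = 300, seed = 43,
                       snapshot_interval = 300)
  expect_false(identical(final_snapshot(t1), final_snapshot(t3)))
})

test_that("segment bookkeeping is exact over a default run", {
  m <- small_cube_mesh()
  traj <- cached("run_small_default",
                 run_simulation(m, growth_params(), n_steps = 1500, seed = 5,
                                snapshot_interval = 1500))
  tr <- traj$trace
  expect_identical(diff(c(0L, tr$n_segments)), tr$added - tr$removed)
  expect_true(all(diff(tr$step) == 1L))
})

test_that("nucleation count matches the configured rate", {
  m <- small_cube_mesh()
  traj <- cached("run_small_default",
                 run_simulation(m, growth_params(), n_steps = 1500, seed = 5,
                                snapshot_interval = 1500))
  lambda <- growth_params()$n_p * surface_area(m) / 0.008^2
  nuc <- traj$trace$nucleated
  # Poisson mean within 4 standard errors
  expect_lt(abs(mean(nuc) - lambda), 4 * sqrt(lambda / length(nuc)))
  # and zero when disabled
  t0 <- run_simulation(m, growth_params(n_p = 0), n_steps = 50, seed = 1,
                       snapshot_interval = 50)
  expect_equal(sum(t0$trace$nucleated), 0)
})

test_that("snapshot interval bookkeeping yields the promised count", {
  m <- small_cube_mesh()
  traj <- run_simulation(m, growth_params(), n_steps = 100, seed = 2,
                         snapshot_interval = 100)
  expect_length(traj$snapshots, 2)
  s0 <- traj$snapshots[[1]]
  expect_true(nrow(s0) == 0 || all(s0$step == 0L))
  traj2 <- run_simulation(m, growth_params(), n_steps = 100, seed = 2,
                          snapshot_interval = 30)
  expect_length(traj2$snapshots, 4)
})

test_that("real-time conversion follows the step duration", {
  m <- small_cube_mesh()
  p <- growth_params(step_seconds = 0.12)
  traj <- run_simulation(m, p, n_steps = 0, seed = 1, snapshot_interval = 1)
  expect_equal(traj$real_time_min, 0)
  expect_equal(50000 * 0.12 / 60, 100)          # full protocol ~100 min
  expect_true(10000 * 0.1 / 60 >= 15 / 0.9 - 2) # 10k steps spans 15-30 min
  expect_equal(10000 * growth_params(step_seconds = 0.2)$step_seconds / 60,
               33.3, tolerance = 0.01)
})

test_that("snapshots round-trip through TSV and gzip TSV", {
  m <- small_cube_mesh()
  traj <- cached("run_small_default",
                 run_simulation(m, growth_params(), n_steps = 1500, seed = 5,
                                snapshot_interval = 1500))
  snap <- final_snapshot(traj)
  for (ext in c("tsv", "tsv.gz")) {
    path <- file.path(tempdir(), paste0("snap.", ext))
    write_snapshot(snap, path)
    back <- read_snapshot(path)
    expect_equal(as.data.frame(back), as.data.frame(snap),
                 tolerance = 1e-12, ignore_attr = TRUE)
    unlink(path)
  }
  # manifest
  mp <- file.path(tempdir(), "manifest.json")
  write_manifest(traj, mp)
  man <- jsonlite::read_json(mp)
  expect_equal(man$seed, 5)
  expect_equal(man$params$r_d, 0.025)
  unlink(mp)
})

test_that("spatial index queries agree with the brute-force oracle", {
  set.seed(17)
  pts <- matrix(stats::runif(3 * 1000, 0, 1), ncol = 3)
  idx <- spatial_index(pts, bucket = 0.05)
  for (i in 1:50) {
    q <- stats::runif(3)
    expect_identical(query_neighbors(idx, q, 0.05),
                     brute_force_neighbors(pts, q, 0.05))
  }
  # pairs at 20 nm see each other at 25 nm; distant pairs do not
  p2 <- rbind(c(0, 0, 0), c(0.020, 0, 0), c(1, 1, 1))
  idx2 <- spatial_index(p2, bucket = 0.05)
  expect_identical(query_neighbors(idx2, p2[1, ], 0.025), c(1L, 2L))
  expect_identical(query_neighbors(idx2, p2[3, ], 0.025), 3L)
  expect_error(query_neighbors(idx2, p2[1, ], 0.06), "bucket")
})
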