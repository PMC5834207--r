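test_that("growth proposals reduce to the noise-free and full-cue limits", {
  p0 <- growth_params(r_d = 0, b_d = 0)
  expect_equal(propose_growth_direction(c(0, 0, 1), p0), c(0, 0, 1))
  pc <- growth_params(r_d = 0, b_d = 1)
  expect_equal(propose_growth_direction(c(0, 0, 1), pc, b = c(1, 0, 0)),
               c(1, 0, 0))
  # unit norm for arbitrary draws
  p <- growth_params(r_d = 0.3)
  set.seed(1)
  for (i in 1:50) {
    v <- propose_growth_direction(random_unit_vector(1)[1, ], p)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
})

test_that("consecutive-direction correlation matches the 3D expansion", {
  # E[r_{n+1} . r_n] = 1 - r_d^2/3 - (2/3) r_d^3 + O(r_d^4), from the
  # second-order expansion of the normalised weighted average with u uniform
  # on the sphere (E[t] = 0, E[t^2] = 1/3); Monte-Carlo verified
  rd <- 0.025
  p <- growth_params(r_d = rd)
  set.seed(99)
  n <- 100000
  u <- random_unit_vector(n)
  v <- (1 - rd) * matrix(c(0, 0, 1), n, 3, byrow = TRUE) + rd * u
  v <- v / sqrt(rowSums(v^2))
  expected <- 1 - rd^2 / 3 - (2 / 3) * rd^3
  se <- stats::sd(v[, 3]) / sqrt(n)
  expect_lt(abs(mean(v[, 3]) - expected), 4 * se + 1e-6)
})

test_that("free tangent correlation decays exponentially at rate r_d^2/3", {
  # multiplicativity: E[t_{n+1} . a | t_n] = c (t_n . a) with
  # c = 1 - r_d^2/3 - (2/3) r_d^3, so <t_0 . t_s> = c^s
  rd <- 0.05
  p <- growth_params(r_d = rd)
  set.seed(123)
  ntraj <- 400; nstep <- 250
  t0 <- matrix(rep(c(0, 0, 1), each = ntraj), ntraj, 3)
  cur <- t0
  corr <- numeric(nstep)
  for (s in 1:nstep) {
    u <- random_unit_vector(ntraj)
    cur <- (1 - rd) * cur + rd * u
    cur <- cur / sqrt(rowSums(cur^2))
    corr[s] <- mean(rowSums(cur * t0))
  }
  fit <- stats::lm(log(corr) ~ seq_len(nstep))
  rate <- -unname(stats::coef(fit)[2])
  c_exp <- 1 - rd^2 / 3 - (2 / 3) * rd^3
  expect_lt(abs(rate - (-log(c_exp))) / (-log(c_exp)), 0.05)
})

test_that("persistence-length mapping reproduces the documented default", {
  expect_equal(persistence_length(growth_params()), 25.6)
  expect_equal(round(persistence_length(growth_params())), 26)
})

test_that("the circumferential cue is orthoradial everywhere off-axis", {
  expect_equal(circumferential_cue(c(1, 0, 5), c(0, 0, 1)), c(0, 1, 0))
  expect_error(circumferential_cue(c(0, 0, 3), c(0, 0, 1)), "undefined cue")
  set.seed(5)
  for (i in 1:200) {
    pos <- stats::rnorm(3) * 3
    if (sqrt(sum(pos[1:2]^2)) < 1e-3) next
    b <- circumferential_cue(pos, c(0, 0, 1))
    expect_equal(sum(b * c(0, 0, 1)), 0, tolerance = 1e-12)
    radial <- c(pos[1], pos[2], 0)
    expect_equal(sum(b * radial), 0, tolerance = 1e-9)
    expect_equal(sum(b^2), 1, tolerance = 1e-12)
  }
})

test_that("encounters classify by the undirected line angle", {
  tip <- c(0, 0, 1)
  mk <- function(theta_deg) {
    c(0, sin(theta_deg * pi / 180), cos(theta_deg * pi / 180))
  }
  expect_equal(classify_encounter(tip, mk(30), 40)$event, "zipper")
  expect_equal(classify_encounter(tip, mk(90), 40)$event, "catastrophe")
  # an apparent 170-degree encounter is a 10-degree line angle; the zipper
  # direction is the sign-flipped target
  r <- classify_encounter(tip, mk(170), 40)
  expect_equal(r$event, "zipper")
  expect_equal(r$angle_deg, 10, tolerance = 1e-9)
  expect_equal(r$direction, -mk(170))
  # boundary angle equals alpha: catastrophe (zippering is strict)
  expect_equal(classify_encounter(tip, mk(40), 40)$event, "catastrophe")
  # symmetry under target sign flip
  set.seed(11)
  for (i in 1:100) {
    a <- random_unit_vector(1)[1, ]; b <- random_unit_vector(1)[1, ]
    r1 <- classify_encounter(a, b, 40)
    r2 <- classify_encounter(a, -b, 40)
    expect_equal(r1$event, r2$event)
    expect_equal(r1$angle_deg, r2$angle_deg, tolerance = 1e-9)
    if (r1$event == "zipper") expect_equal(r1$direction, r2$direction)
  }
})

test_that("strong anchoring projects onto the tangent plane", {
  expect_equal(apply_strong_anchoring(c(1, 0, 1) / sqrt(2), c(0, 0, 1)),
               c(1, 0, 0))
  expect_equal(apply_strong_anchoring(c(0, 1, 0), c(0, 0, 1)), c(0, 1, 0))
  expect_error(apply_strong_anchoring(c(0, 0, 1), c(0, 0, 1)), "degenerate")
  set.seed(3)
  for (i in 1:200) {
    d <- random_unit_vector(1)[1, ]; n <- random_unit_vector(1)[1, ]
    if (abs(sum(d * n)) > 0.99) next
    t <- apply_strong_anchoring(d, n)
    expect_equal(sum(t * n), 0, tolerance = 1e-9)
    expect_equal(sum(t^2), 1, tolerance = 1e-12)
  }
})

test_that("weak anchoring kills steep membrane encounters and contains growth", {
  m <- small_cube_mesh()
  params <- growth_params()
  tip <- c(0, 0, 2 - 0.005)          # 5 nm under the top face
  probe <- nearest_surface(m, tip)
  steep <- c(0, sin(30 * pi / 180), cos(30 * pi / 180))  # 60 deg from plane
  res <- apply_weak_anchoring(tip, steep, steep, probe, m, params)
  expect_equal(res$event, "catastrophe")
  # tangential directions pass unchanged
  tang <- c(1, 0, 0)
  res2 <- apply_weak_anchoring(tip, tang, tang, probe, m, params)
  expect_equal(res2$event, "grow")
  expect_equal(res2$direction, tang)
  # shallow outward-pointing proposals are deflected inside
  set.seed(21)
  out20 <- c(cos(20 * pi / 180), 0, sin(20 * pi / 180))
  res3 <- apply_weak_anchoring(tip, c(1, 0, 0), out20, probe, m, params)
  expect_equal(res3$event, "grow")
  ep <- tip + params$ell * res3$direction
  expect_true(nearest_surface(m, ep)$inside)
})

test_that("nucleation respects anchoring mode and surface containment", {
  m <- small_cube_mesh()
  set.seed(31)
  pw <- growth_params(anchoring = "weak", nucleation_direction = "isotropic")
  pt <- growth_params(anchoring = "weak")   # tangential default
  ps <- growth_params(anchoring = "strong")
  iso_dots <- numeric(0)
  for (i in 1:50) {
    mt <- nucleate(m, pw, i)
    pr <- nearest_surface(m, mt$origin)
    expect_lt(pr$distance, 1e-9)
    expect_lte(sum(mt$dirs[1, ] * pr$normal), 1e-9)
    iso_dots <- c(iso_dots, sum(mt$dirs[1, ] * pr$normal))
    mtt <- nucleate(m, pt, i)
    prt <- nearest_surface(m, mtt$origin)
    expect_lt(abs(sum(mtt$dirs[1, ] * prt$normal)), 1e-6)
    mts <- nucleate(m, ps, i)
    prs <- nearest_surface(m, mts$origin)
    expect_lt(abs(sum(mts$dirs[1, ] * prs$normal)), 1e-6)
  }
  # the isotropic rule really explores the inward hemisphere
  expect_lt(min(iso_dots), -0.5)
})

test_that("minus-end updates flip, shrink, and remove microtubules", {
  params1 <- growth_params(n_s = 1)
  mt <- microtubule(0L, c(0, 0, 0), matrix(rep(c(1, 0, 0), 5), 5, 3,
                                           byrow = TRUE))
  set.seed(1)
  mt1 <- minus_end_update(mt, params1)     # onset step: no removal yet
  expect_true(mt1$minus_shrinking)
  expect_equal(nrow(mt1$dirs), 5)
  for (k in 1:4) mt1 <- minus_end_update(mt1, params1)
  expect_equal(nrow(mt1$dirs), 1)
  expect_null(minus_end_update(mt1, params1))
  # n_s = 0: never shrinks
  params0 <- growth_params(n_s = 0)
  mt0 <- minus_end_update(mt, params0)
  expect_false(mt0$minus_shrinking)
  expect_equal(nrow(mt0$dirs), 5)
})

test_that("plus-end updates grow, zipper, and start catastrophes", {
  params <- growth_params(r_d = 0)
  mt <- microtubule(0L, c(0, 0, 0), matrix(c(0, 0, 1), 1, 3))
  r <- plus_end_update(mt, NULL, NULL, params)
  expect_equal(r$event, "grow")
  expect_equal(nrow(r$mt$dirs), 2)
  expect_equal(r$mt$dirs[2, ], c(0, 0, 1))
  # a perpendicular segment 20 nm ahead triggers catastrophe
  tip <- mt$endpoints[1, ]
  nb <- list(pos = matrix(tip + c(0, 0, 0.020), 1, 3),
             dir = matrix(c(1, 0, 0), 1, 3), mt_id = 5L)
  r2 <- plus_end_update(mt, nb, NULL, params)
  expect_equal(r2$event, "catastrophe_start")
  expect_true(r2$mt$plus_cat)
  # a 20-degree inclined segment zippers; the new segment takes its direction
  host <- c(0, sin(20 * pi / 180), cos(20 * pi / 180))
  nb3 <- list(pos = matrix(tip + c(0, 0, 0.020), 1, 3),
              dir = matrix(host, 1, 3), mt_id = 5L)
  r3 <- plus_end_update(mt, nb3, NULL, params)
  expect_equal(r3$event, "zipper")
  expect_equal(r3$mt$dirs[2, ], host, tolerance = 1e-12)
  # shrinking plus end loses one segment per step
  mtc <- microtubule(1L, c(0, 0, 0), matrix(rep(c(1, 0, 0), 3), 3, 3,
                                            byrow = TRUE), plus_cat = TRUE)
  r4 <- plus_end_update(mtc, NULL, NULL, params)
  expect_equal(r4$event, "shrink")
  expect_equal(nrow(r4$mt$dirs), 2)
})
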