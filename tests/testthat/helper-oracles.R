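# Shared caches and independent brute-force oracles used across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small, cheap meshes reused throughout the suite
small_cube_mesh <- function() {
  cached("small_cube", build_rounded_box(c(4, 4, 4), 1, resolution = 0.5))
}

coarse_square_mesh <- function() {
  cached("coarse_square", build_rounded_box(c(9, 9, 4.7), 1.3,
                                            resolution = 0.6))
}

# brute-force point-to-triangle-soup distance (independent of the compiled
# index): exact closest point per triangle via constrained projection
brute_force_mesh_distance <- function(mesh, point) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c3 <- v[f[t, 3], ]
    d <- closest_point_on_triangle(point, a, b, c3)
    dist <- sqrt(sum((point - d)^2))
    if (dist < best) best <- dist
  }
  best
}

closest_point_on_triangle <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c3)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + (c3 - b) * w)
  }
  denom <- va + vb + vc
  a + ab * (vb / denom) + ac * (vc / denom)
}

# O(n^2) neighbour-query oracle
brute_force_neighbors <- function(points, query, radius) {
  d2 <- rowSums((points - matrix(query, nrow(points), 3, byrow = TRUE))^2)
  sort(which(d2 <= radius^2))
}

# numerical quadrature for the surface area of an axis-aligned ellipsoid
# with semi-axes (a, a, c): surface of revolution around z
ellipsoid_area_quadrature <- function(a, c3, n = 20000) {
  th <- seq(0, pi, length.out = n + 1)
  # parametrise r(theta) = (a sin th, 0, c cos th); revolve around z
  x <- a * sin(th)
  dx <- a * cos(th)
  dz <- -c3 * sin(th)
  ds <- sqrt(dx^2 + dz^2)
  f <- 2 * pi * x * ds
  sum((f[-1] + f[-length(f)]) / 2) * (pi / n)
}

# closed-form nematic order parameter from eigenvalues
anisotropy_from_eigenvalues <- function(lam) {
  lm <- mean(lam)
  sqrt(1.5 * sum((lam - lm)^2) / sum(lam^2))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# analytic signed containment for a rounded box centred at the origin
rounded_box_inside <- function(p, dims, r) {
  inner <- dims / 2 - r
  cl <- pmin(pmax(p, rep(-inner, each = nrow(p))), rep(inner, each = nrow(p)))
  sqrt(rowSums((p - cl)^2)) <= r
}

# build a snapshot data.frame from raw fields
raw_snapshot <- function(pos, dir, mt_id, step = 0L, ell = 0.008) {
  df <- data.frame(step = step, mt_id = as.integer(mt_id),
                   seg_index = seq_along(mt_id) - 1L,
                   x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                   dx = dir[, 1], dy = dir[, 2], dz = dir[, 3])
  attr(df, "ell") <- ell
  class(df) <- c("cortisim_snapshot", "data.frame")
  df
}
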