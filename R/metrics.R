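#' Nematic order parameter of a set of directions
#'
#' For N unit directions stacked as an N x 3 matrix D, the symmetric second
#' moment M = t(D) D / N is diagonalised; with eigenvalues lambda_i and
#' their mean lambda_m, the anisotropy is
#' `A = sqrt(3/2 * sum((lambda_i - lambda_m)^2) / sum(lambda_i^2))`,
#' which lies in [0, 1]: 1 for perfectly aligned directions, 0 in the
#' isotropic limit. A is invariant under global rotations and under sign
#' flips of any subset of directions (M is quadratic in D).
#'
#' @param directions n x 3 matrix of unit direction vectors
#' @return list with `A`, `eigenvalues` (decreasing), `lambda_m`
#' @export
local_anisotropy <- function(directions) {
  directions <- matrix(directions, ncol = 3)
  n <- nrow(directions)
  if (n < 1) stop("undefined metric: no directions")
  M <- crossprod(directions) / n
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lm <- mean(lam)
  A <- sqrt(1.5 * sum((lam - lm)^2) / sum(lam^2))
  list(A = min(A, 1), eigenvalues = lam, lambda_m = lm)
}

#' Anisotropy over a cubic spatial grid
#'
#' The cell bounding box (from the mesh when supplied, else from the
#' snapshot) is split into an s x s x s grid with `s = round(n_cubes^(1/3))`
#' axis-aligned cubes (27 by default). Local anisotropy is computed from the
#' directions of segments whose endpoints fall in each cube, and the
#' cell-average is the mean over non-empty cubes. A finer grid (e.g. 216
#' cubes) gives the same trends with globally higher values.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param mesh optional [tri_mesh()] fixing the bounding box
#' @param n_cubes target number of cubes (rounded to a perfect cube)
#' @return list of class `anisotropy_result` with `cell_average`,
#'   `per_cube` (data.frame: cube indices, count, A), `grid`
#' @export
grid_anisotropy <- function(snapshot, mesh = NULL, n_cubes = 27) {
  if (nrow(snapshot) == 0) stop("undefined metric: empty snapshot")
  s <- max(1L, round(n_cubes^(1 / 3)))
  p <- as.matrix(snapshot[, c("x_um", "y_um", "z_um")])
  d <- as.matrix(snapshot[, c("dx", "dy", "dz")])
  bb <- if (is.null(mesh)) apply(p, 2, range) else apply(mesh$vertices, 2,
                                                         range)
  idx <- sapply(1:3, function(j) {
    w <- (bb[2, j] - bb[1, j])
    i <- if (w <= 0) rep(1L, nrow(p))
         else pmin(s, pmax(1L, floor((p[, j] - bb[1, j]) / w * s) + 1L))
    as.integer(i)
  })
  cube <- (idx[, 3] - 1L) * s * s + (idx[, 2] - 1L) * s + idx[, 1]
  occupied <- sort(unique(cube))
  rows <- lapply(occupied, function(cc) {
    sel <- cube == cc
    la <- local_anisotropy(d[sel, , drop = FALSE])
    data.frame(ix = ((cc - 1L) %% s) + 1L,
               iy = (((cc - 1L) %/% s) %% s) + 1L,
               iz = ((cc - 1L) %/% (s * s)) + 1L,
               n = sum(sel), A = la$A,
               lambda1 = la$eigenvalues[1], lambda2 = la$eigenvalues[2],
               lambda3 = la$eigenvalues[3])
  })
  per_cube <- do.call(rbind, rows)
  structure(list(cell_average = mean(per_cube$A), per_cube = per_cube,
                 grid = c(s, s, s)), class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("anisotropy_result: %dx%dx%d grid, %d occupied cubes, A = %.4f\n",
              x$grid[1], x$grid[2], x$grid[3], nrow(x$per_cube),
              x$cell_average))
  invisible(x)
}

#' Fraction of tubulin in bundles
#'
#' A segment counts as bundled when at least one segment of a *different*
#' microtubule lies within `dist_thresh` of its endpoint with a line angle
#' of at most `angle_deg`. The defaults reuse the interaction geometry that
#' creates zippered bundles (25 nm, 40 degrees). The relation is symmetric
#' and the fraction is monotone non-decreasing in both thresholds.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param dist_thresh companion distance (um), default 0.025
#' @param angle_deg maximal line angle (degrees), default 40
#' @return fraction in [0, 1]
#' @export
bundle_fraction <- function(snapshot, dist_thresh = 0.025, angle_deg = 40) {
  if (nrow(snapshot) == 0) stop("undefined metric: empty snapshot")
  flags <- bundle_flags_cpp(
    as.matrix(snapshot[, c("x_um", "y_um", "z_um")]),
    as.matrix(snapshot[, c("dx", "dy", "dz")]),
    as.integer(snapshot$mt_id), dist_thresh, cos(angle_deg * pi / 180))
  mean(flags)
}

#' Mean distance of the network to the membrane
#'
#' Mean over segment endpoints (or per-microtubule means of those) of the
#' nearest-surface distance. Reported in nanometres, the scale on which
#' cortical localisation is assessed.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param mesh the cell [tri_mesh()]
#' @param per `"segment"` (default) or `"microtubule"` (mean of per-filament
#'   means)
#' @return mean distance in nm
#' @export
mean_membrane_distance <- function(snapshot, mesh,
                                   per = c("segment", "microtubule")) {
  per <- match.arg(per)
  if (nrow(snapshot) == 0) stop("undefined metric: empty snapshot")
  d <- nearest_surface(mesh,
                       as.matrix(snapshot[, c("x_um", "y_um", "z_um")]))$distance
  if (per == "segment") 1000 * mean(d)
  else 1000 * mean(tapply(d, snapshot$mt_id, mean))
}

#' Orientation histogram near a cell face
#'
#' Selects segments within `band` of the face(s) perpendicular to
#' `face_normal` (the extreme planes of the mesh along that axis), projects
#' their directions onto the face plane, and bins the signed angle to
#' `ref_axis` folded to (-90, 90] degrees (nematic lines).
#'
#' @param snapshot a `cortisim_snapshot`
#' @param mesh the cell [tri_mesh()]
#' @param face_normal outward unit normal of the face of interest
#' @param ref_axis in-plane unit reference axis (angle 0)
#' @param band selection depth from the face (um), default 0.5
#' @param bins number of angular bins
#' @param faces `"both"` (top and bottom pooled), `"top"`, or `"bottom"`
#' @return an `orientation_histogram` list: `breaks`, `mids`, `counts`, `n`
#' @export
face_orientation_histogram <- function(snapshot, mesh, face_normal,
                                       ref_axis, band = 0.5, bins = 18,
                                       faces = c("both", "top", "bottom")) {
  faces <- match.arg(faces)
  fn <- face_normal / sqrt(sum(face_normal^2))
  ra <- ref_axis - sum(ref_axis * fn) * fn
  if (sqrt(sum(ra^2)) < 1e-9) stop("ref_axis must not be parallel to face_normal")
  ra <- ra / sqrt(sum(ra^2))
  ya <- c(fn[2] * ra[3] - fn[3] * ra[2],
          fn[3] * ra[1] - fn[1] * ra[3],
          fn[1] * ra[2] - fn[2] * ra[1])
  p <- as.matrix(snapshot[, c("x_um", "y_um", "z_um")])
  h <- p %*% fn
  hv <- mesh$vertices %*% fn
  sel <- rep(FALSE, nrow(p))
  if (faces != "bottom") sel <- sel | (max(hv) - h <= band)
  if (faces != "top") sel <- sel | (h - min(hv) <= band)
  breaks <- seq(-90, 90, length.out = bins + 1)
  counts <- rep(0L, bins)
  if (!any(sel)) {
    warning("no segments within the face band; empty histogram")
  } else {
    d <- as.matrix(snapshot[sel, c("dx", "dy", "dz")])
    dt <- d - (d %*% fn) %*% t(fn)
    ang <- atan2(dt %*% ya, dt %*% ra) * 180 / pi
    ang[ang > 90] <- ang[ang > 90] - 180
    ang[ang <= -90] <- ang[ang <= -90] + 180
    counts <- as.integer(
      table(cut(drop(ang), breaks, include.lowest = TRUE)))
  }
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-bins - 1]) / 2,
                 counts = counts, n = sum(sel), reference = ra,
                 selection = faces, band = band),
            class = "orientation_histogram")
}

#' Histogram of alignment with a cell axis
#'
#' Bins the absolute scalar product between segment directions and a given
#' axis over all segments (support [0, 1]; microtubules are nematic, so the
#' absolute value is used). Mass near 1 means alignment with the axis; mass
#' near 0 means perpendicular (e.g. circumferential) orientation.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param long_axis unit axis vector
#' @param bins number of bins on [0, 1]
#' @return an `orientation_histogram` list (`breaks`, `mids`, `counts`, `n`)
#' @export
axis_alignment_histogram <- function(snapshot, long_axis, bins = 20) {
  a <- long_axis / sqrt(sum(long_axis^2))
  d <- as.matrix(snapshot[, c("dx", "dy", "dz")])
  s <- abs(d %*% a)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- as.integer(table(cut(drop(pmin(s, 1)), breaks,
                                 include.lowest = TRUE)))
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-bins - 1]) / 2,
                 counts = counts, n = nrow(d), reference = a,
                 selection = "whole cell", band = NA),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("orientation_histogram: %d segments in %d bins (%s)\n",
              x$n, length(x$counts), x$selection))
  invisible(x)
}

#' Basic network summary
#' @param snapshot a `cortisim_snapshot`
#' @param ell segment length in um (taken from the snapshot when available)
#' @return list with `n_microtubules`, `mean_length_um`, `total_segments`
#' @export
network_summary <- function(snapshot, ell = NULL) {
  if (is.null(ell)) ell <- attr(snapshot, "ell")
  if (is.null(ell)) ell <- 0.008
  if (nrow(snapshot) == 0)
    return(list(n_microtubules = 0L, mean_length_um = 0, total_segments = 0L))
  counts <- table(snapshot$mt_id)
  list(n_microtubules = length(counts),
       mean_length_um = mean(counts) * ell,
       total_segments = nrow(snapshot))
}

#' Tidy metrics table for a snapshot
#'
#' One row per metric, suitable for appending across snapshots and writing
#' as CSV for downstream plotting.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param mesh the cell [tri_mesh()]
#' @param label optional condition label
#' @return data.frame with columns `step`, `label`, `metric`, `value`
#' @export
snapshot_metrics <- function(snapshot, mesh, label = NA_character_) {
  step <- if (nrow(snapshot)) snapshot$step[1] else NA_integer_
  ns <- network_summary(snapshot)
  vals <- c(n_microtubules = ns$n_microtubules,
            mean_length_um = ns$mean_length_um,
            total_segments = ns$total_segments)
  if (nrow(snapshot) > 0) {
    vals <- c(vals,
              anisotropy = grid_anisotropy(snapshot, mesh)$cell_average,
              bundle_fraction = bundle_fraction(snapshot),
              mean_membrane_distance_nm = mean_membrane_distance(snapshot,
                                                                 mesh))
  }
  data.frame(step = step, label = label, metric = names(vals),
             value = unname(vals), row.names = NULL)
}
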