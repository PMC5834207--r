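#' Create a network simulation
#'
#' Builds the compiled simulation state: the cell mesh with its
#' nearest-surface index, the segment spatial hash (bucket size twice the
#' interaction radius, so a one-ring bucket scan covers every query), and a
#' dedicated deterministic random stream seeded from `seed`. Identical
#' `(mesh, params, seed)` give bit-identical trajectories.
#'
#' @param mesh a [tri_mesh()]
#' @param params a [growth_params()]
#' @param seed integer seed for the simulation's own random stream
#' @param cue a [cue_field()]; defaults to no cue
#' @return an object of class `cortisim_simulation`
#' @export
simulation <- function(mesh, params = growth_params(), seed = 1L,
                       cue = cue_field("none")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  validate_growth_params(params)
  cpp_params <- list(
    n_p = params$n_p, n_s = params$n_s, r_d = params$r_d, b_d = params$b_d,
    alpha_deg = params$alpha_deg, ell = params$ell,
    interaction_radius = params$interaction_radius,
    membrane_radius = params$membrane_radius,
    events_per_step = if (is.na(params$events_per_step)) -1
                      else params$events_per_step,
    anchoring = params$anchoring,
    cue = cue$kind,
    cue_axis = cue$axis,
    cue_center = if (is.null(cue$center)) colMeans(mesh$vertices)
                 else cue$center,
    retry_budget = params$retry_budget,
    self_exclusion = params$self_exclusion,
    nucleation_direction = params$nucleation_direction)
  ptr <- sim_create_cpp(mesh_index(mesh), cpp_params, as.numeric(seed))
  structure(list(ptr = ptr, mesh = mesh, params = params, seed = seed,
                 cue = cue), class = "cortisim_simulation")
}

#' Directional cue field
#'
#' `"none"` disables the cue. `"circumferential"` defines, at every off-axis
#' position, the hoop direction around `axis` (perpendicular both to the
#' axis of revolution and to the local radial vector); its weight in the
#' growth rule is `b_d` from [growth_params()]. The cue is an orientation,
#' not a signed vector: the kernel picks the sign with non-negative dot
#' product with the current tip direction.
#'
#' @param kind `"none"` or `"circumferential"`
#' @param axis unit vector of the axis of revolution (default z)
#' @param center a point on the axis; defaults to the mesh centroid at
#'   simulation time
#' @return an object of class `cue_field`
#' @export
cue_field <- function(kind = c("none", "circumferential"), axis = c(0, 0, 1),
                      center = NULL) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, axis = axis, center = center),
            class = "cue_field")
}

#' @export
print.cortisim_simulation <- function(x, ...) {
  info <- sim_info_cpp(x$ptr)
  cat(sprintf(paste0("cortisim_simulation: step %d, %d microtubules, ",
                     "%d segments (seed %d, %s anchoring)\n"),
              as.integer(info$step), info$n_mt, as.integer(info$n_segments),
              x$seed, x$params$anchoring))
  invisible(x)
}

#' Advance a simulation by discrete time steps
#'
#' Each step applies, in order: nucleation, minus-end updates (id order),
#' plus-end updates (id order; segments added earlier in the step are
#' already visible to the collision test), and removal of empty
#' microtubules.
#'
#' @param sim a [simulation()]
#' @param n number of steps
#' @return `sim`, invisibly (the state is updated in place)
#' @export
sim_step <- function(sim, n = 1L) {
  sim_step_cpp(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Current network snapshot
#'
#' The full set of segment records: one row per tubulin unit vector with its
#' endpoint position (um) and direction.
#'
#' @param sim a [simulation()]
#' @return a `cortisim_snapshot` data.frame with columns `step`, `mt_id`,
#'   `seg_index`, `x_um`, `y_um`, `z_um`, `dx`, `dy`, `dz`
#' @export
sim_snapshot <- function(sim) {
  s <- sim_snapshot_cpp(sim$ptr)
  df <- data.frame(step = rep(as.integer(s$step), length(s$mt_id)),
                   mt_id = s$mt_id,
                   seg_index = s$seg_index,
                   x_um = s$pos[, 1], y_um = s$pos[, 2], z_um = s$pos[, 3],
                   dx = s$dir[, 1], dy = s$dir[, 2], dz = s$dir[, 3])
  attr(df, "seed") <- sim$seed
  attr(df, "ell") <- sim$params$ell
  class(df) <- c("cortisim_snapshot", "data.frame")
  df
}

#' Per-step event trace
#'
#' Segment bookkeeping per step: counts of microtubules and segments,
#' additions and removals (their difference is exactly the change in total
#' segment count), nucleations, zippering and catastrophe events, and
#' anchoring retry fallbacks.
#'
#' @param sim a [simulation()]
#' @return data.frame, one row per executed step
#' @export
sim_trace <- function(sim) {
  as.data.frame(sim_trace_cpp(sim$ptr))
}

#' Inject a microtubule into a simulation (scripted scenarios)
#' @param sim a [simulation()]
#' @param origin minus-end origin (length 3, um)
#' @param directions k x 3 matrix of segment directions (normalised)
#' @param minus_shrinking,plus_cat initial dynamic-state flags
#' @return `sim`, invisibly
#' @export
sim_add_microtubule <- function(sim, origin, directions,
                                minus_shrinking = FALSE, plus_cat = FALSE) {
  sim_add_mt_cpp(sim$ptr, as.numeric(origin),
                 matrix(as.numeric(directions), ncol = 3),
                 minus_shrinking, plus_cat)
  invisible(sim)
}

#' Run a full simulation and collect snapshots
#'
#' @param mesh a [tri_mesh()]
#' @param params a [growth_params()]
#' @param n_steps number of time steps
#' @param seed integer seed
#' @param snapshot_interval steps between stored snapshots; the trajectory
#'   contains `floor(n_steps / snapshot_interval) + 1` snapshots including
#'   step 0
#' @param cue a [cue_field()]
#' @param trace keep the per-step event trace (default TRUE)
#' @return a `cortisim_trajectory` list with `snapshots`, `trace`, `params`,
#'   `seed`, `n_steps`, and `real_time_min` (`n_steps * step_seconds / 60`)
#' @export
run_simulation <- function(mesh, params = growth_params(), n_steps = 50000L,
                           seed = 1L, snapshot_interval = 1000L,
                           cue = cue_field("none"), trace = TRUE) {
  stopifnot(n_steps >= 0, snapshot_interval >= 1)
  sim <- simulation(mesh, params, seed, cue)
  n_snap <- floor(n_steps / snapshot_interval)
  snaps <- vector("list", n_snap + 1)
  snaps[[1]] <- sim_snapshot(sim)
  done <- 0L
  for (i in seq_len(n_snap)) {
    sim_step(sim, snapshot_interval)
    done <- done + as.integer(snapshot_interval)
    snaps[[i + 1]] <- sim_snapshot(sim)
  }
  if (done < n_steps) sim_step(sim, n_steps - done)
  structure(list(snapshots = snaps,
                 trace = if (trace) sim_trace(sim) else NULL,
                 params = params, seed = seed, n_steps = n_steps,
                 snapshot_interval = snapshot_interval,
                 real_time_min = n_steps * params$step_seconds / 60,
                 final = sim_snapshot(sim)),
            class = "cortisim_trajectory")
}

#' @export
print.cortisim_trajectory <- function(x, ...) {
  cat(sprintf(paste0("cortisim_trajectory: %d steps (~%.1f min real time), ",
                     "%d snapshots, seed %d\n"),
              x$n_steps, x$real_time_min, length(x$snapshots), x$seed))
  s <- x$final
  cat(sprintf("  final: %d microtubules, %d segments\n",
              length(unique(s$mt_id)), nrow(s)))
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param trajectory a `cortisim_trajectory`
#' @return a `cortisim_snapshot`
#' @export
final_snapshot <- function(trajectory) trajectory$final

# ---------------------------------------------------------------------------
# Snapshot / manifest I/O
# ---------------------------------------------------------------------------

#' Write a snapshot as TSV (optionally gzip-compressed)
#' @param snapshot a `cortisim_snapshot`
#' @param path output file; a `.gz` suffix selects compression
#' @return invisibly, `path`
#' @export
write_snapshot <- function(snapshot, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(snapshot), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a snapshot written by [write_snapshot()]
#' @param path TSV file (possibly `.gz`)
#' @return a `cortisim_snapshot`
#' @export
read_snapshot <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  class(df) <- c("cortisim_snapshot", "data.frame")
  df
}

#' Write a run manifest (config, seed, package version) as JSON
#' @param trajectory a `cortisim_trajectory`
#' @param path output JSON file
#' @return invisibly, `path`
#' @export
write_manifest <- function(trajectory, path) {
  m <- list(package = "cortisim",
            version = as.character(utils::packageVersion("cortisim")),
            seed = trajectory$seed, n_steps = trajectory$n_steps,
            snapshot_interval = trajectory$snapshot_interval,
            real_time_min = trajectory$real_time_min,
            params = unclass(trajectory$params))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Spatial index (exposed for neighbour-query verification)
# ---------------------------------------------------------------------------

#' Build a bucketed spatial index over points
#'
#' The same locality-sensitive bucketing used by the stepping kernel for its
#' collision tests. Queries are valid for radii up to the bucket size (the
#' kernel uses a bucket of twice the interaction radius).
#'
#' @param points n x 3 matrix
#' @param bucket bucket edge length (um)
#' @return an object of class `spatial_index`
#' @export
spatial_index <- function(points, bucket = 0.05) {
  points <- as.matrix(points)
  structure(list(ptr = point_grid_build(points, bucket), bucket = bucket,
                 n = nrow(points)), class = "spatial_index")
}

#' Indices of points within a radius of a query point
#' @param index a [spatial_index()]
#' @param point query position (length 3)
#' @param radius search radius; must not exceed the bucket size
#' @return integer vector of 1-based point indices (sorted)
#' @export
query_neighbors <- function(index, point, radius) {
  if (radius > index$bucket)
    stop("query radius exceeds the bucket size of the index")
  point_grid_query(index$ptr, as.numeric(point), radius)
}
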