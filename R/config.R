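CONFIG_SCHEMA_VERSION <- 1L

config_keys <- function() {
  list(
    top = c("schema_version", "shape", "mesh_path", "params", "cue",
            "engine", "metrics", "output_dir"),
    params = c("n_p", "n_s", "r_d", "b_d", "alpha_deg", "anchoring", "ell",
               "step_seconds", "interaction_radius", "membrane_radius",
               "events_per_step", "nucleation_direction", "retry_budget",
               "self_exclusion"),
    cue = c("kind", "axis", "center"),
    engine = c("n_steps", "snapshot_interval", "seed", "replicates"),
    metrics = c("anisotropy", "bundle_fraction", "membrane_distance",
                "network_summary"))
}

#' Default simulation configuration
#'
#' All default parameter values: nucleation frequency `n_p` = 4.7e-7 per
#' `ell^2` per step, minus-end shrinkage onset `n_s` = 1e-3, directional
#' noise `r_d` = 0.025, encounter threshold `alpha` = 40 degrees, cue weight
#' `b_d` = 0, weak anchoring; 50,000 steps with snapshots every 1,000 and 5
#' replicates.
#'
#' @return a named list of class `sim_config`
#' @export
default_config <- function() {
  structure(list(
    schema_version = CONFIG_SCHEMA_VERSION,
    shape = "sharp_square",
    mesh_path = NULL,
    params = list(n_p = 4.7e-7, n_s = 1e-3, r_d = 0.025, b_d = 0,
                  alpha_deg = 40, anchoring = "weak", ell = 0.008,
                  step_seconds = 0.12, interaction_radius = 0.025,
                  membrane_radius = 0.010, events_per_step = NA,
                  nucleation_direction = "tangential", retry_budget = 32L,
                  self_exclusion = 3L),
    cue = list(kind = "none", axis = c(0, 0, 1), center = NULL),
    engine = list(n_steps = 50000L, snapshot_interval = 1000L, seed = 1L,
                  replicates = 5L),
    metrics = list(anisotropy = TRUE, bundle_fraction = TRUE,
                   membrane_distance = TRUE, network_summary = TRUE),
    output_dir = NULL), class = "sim_config")
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration, fills missing entries with defaults, and
#' validates against the configuration schema. Unknown keys are rejected
#' with an error naming the offending key. An empty file yields the full
#' default configuration.
#'
#' @param path JSON file
#' @return a validated `sim_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- default_config()
  keys <- config_keys()
  bad <- setdiff(names(user), keys$top)
  if (length(bad)) stop("unknown configuration key: ", bad[1])
  for (section in c("params", "cue", "engine", "metrics")) {
    if (!is.null(user[[section]])) {
      bad <- setdiff(names(user[[section]]), keys[[section]])
      if (length(bad))
        stop("unknown configuration key: ", section, "$", bad[1])
      for (k in names(user[[section]]))
        cfg[[section]][[k]] <- user[[section]][[k]]
    }
  }
  for (k in setdiff(names(user), c("params", "cue", "engine", "metrics")))
    cfg[[k]] <- user[[k]]
  validate_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg a `sim_config` list
#' @return the validated config, invisibly usable
#' @export
validate_config <- function(cfg) {
  p <- cfg$params
  validate_growth_params(c(p, list()))
  if (!cfg$cue$kind %in% c("none", "circumferential"))
    stop("invalid configuration: cue$kind must be none or circumferential")
  if (is.null(cfg$mesh_path) && !cfg$shape %in% cell_shape_names())
    stop("invalid configuration: unknown shape '", cfg$shape, "'")
  e <- cfg$engine
  if (e$n_steps < 0 || e$snapshot_interval < 1 || e$replicates < 1)
    stop("invalid configuration: engine settings out of range")
  cfg
}

#' Growth parameters from a configuration
#' @param cfg a `sim_config`
#' @return a [growth_params()]
#' @export
config_params <- function(cfg) {
  do.call(growth_params, cfg$params)
}

#' Run the simulation described by a configuration
#' @param cfg a `sim_config` (see [load_config()])
#' @param seed optional seed override
#' @return a `cortisim_trajectory`
#' @export
run_config <- function(cfg, seed = NULL) {
  cfg <- validate_config(cfg)
  mesh <- if (!is.null(cfg$mesh_path)) read_mesh(cfg$mesh_path)
          else make_cell_shape(cfg$shape)
  cue <- cue_field(cfg$cue$kind, cfg$cue$axis, cfg$cue$center)
  run_simulation(mesh, config_params(cfg), n_steps = cfg$engine$n_steps,
                 seed = if (is.null(seed)) cfg$engine$seed else seed,
                 snapshot_interval = cfg$engine$snapshot_interval, cue = cue)
}

# ---------------------------------------------------------------------------
# Deterministic fixtures (scripted toy scenes)
# ---------------------------------------------------------------------------

snapshot_from_mts <- function(mts, step = 0L) {
  rows <- lapply(mts, function(m) {
    data.frame(step = step, mt_id = m$id,
               seg_index = seq_len(nrow(m$dirs)) - 1L,
               x_um = m$endpoints[, 1], y_um = m$endpoints[, 2],
               z_um = m$endpoints[, 3],
               dx = m$dirs[, 1], dy = m$dirs[, 2], dz = m$dirs[, 3])
  })
  df <- do.call(rbind, rows)
  attr(df, "ell") <- mts[[1]]$ell
  class(df) <- c("cortisim_snapshot", "data.frame")
  df
}

#' Deterministic toy scenes for testing metrics and dynamics
#'
#' Registry of scripted fixtures:
#' \describe{
#'   \item{two_parallel}{two straight parallel microtubules 10 nm apart
#'     (every segment bundled by construction)}
#'   \item{two_crossing}{two straight perpendicular microtubules passing
#'     20 nm apart (bundled fraction about zero)}
#'   \item{aligned_cloud}{1,000 segments all along +z at random positions}
#'   \item{isotropic_cloud}{100,000 segments with isotropic directions}
#'   \item{single_near_face}{a cube mesh plus one segment 100 nm inside the
#'     top face (returned as a list with `mesh` and `snapshot`)}
#' }
#' Fixture output is byte-identical across calls (a fixed internal seed is
#' used and the caller's RNG state is restored).
#'
#' @param name fixture name
#' @return a `cortisim_snapshot`, or a list for `single_near_face`
#' @export
make_fixture <- function(name) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(20260921L)
  ell <- 0.008
  straight <- function(id, origin, dir, n) {
    microtubule(id, origin, matrix(rep(dir / sqrt(sum(dir^2)), each = n),
                                   n, 3), ell)
  }
  switch(name,
    two_parallel = snapshot_from_mts(list(
      straight(0L, c(0, 0, 0), c(1, 0, 0), 50),
      straight(1L, c(0, 0.010, 0), c(1, 0, 0), 50))),
    two_crossing = snapshot_from_mts(list(
      straight(0L, c(-0.2, 0, 0), c(1, 0, 0), 50),
      straight(1L, c(0, -0.2, 0.020), c(0, 1, 0), 50))),
    aligned_cloud = {
      pos <- matrix(stats::runif(3000), 1000, 3)
      df <- data.frame(step = 0L, mt_id = seq_len(1000) - 1L, seg_index = 0L,
                       x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                       dx = 0, dy = 0, dz = 1)
      attr(df, "ell") <- ell
      class(df) <- c("cortisim_snapshot", "data.frame")
      df
    },
    isotropic_cloud = {
      n <- 100000L
      d <- random_unit_vector(n)
      pos <- matrix(stats::runif(3 * n, 0, 5), n, 3)
      df <- data.frame(step = 0L, mt_id = seq_len(n) - 1L, seg_index = 0L,
                       x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                       dx = d[, 1], dy = d[, 2], dz = d[, 3])
      attr(df, "ell") <- ell
      class(df) <- c("cortisim_snapshot", "data.frame")
      df
    },
    single_near_face = {
      mesh <- build_rounded_box(c(4, 4, 4), 1, resolution = 0.5)
      snap <- snapshot_from_mts(list(
        straight(0L, c(0 - ell, 0, 2 - 0.1), c(1, 0, 0), 1)))
      list(mesh = mesh, snapshot = snap)
    },
    stop("unknown fixture: ", name))
}

# ---------------------------------------------------------------------------
# Replication driver for the standard experiments
# ---------------------------------------------------------------------------

#' Run a standard condition grid and summarise the final snapshots
#'
#' Drives the standard experiment grids over cell shapes, anchoring modes
#' and cue strengths:
#' \describe{
#'   \item{fig2}{all six rounded-box shapes x weak/strong anchoring;
#'     membrane distance and network properties}
#'   \item{fig3}{three sharp shapes x weak/strong anchoring; network size
#'     and bundling}
#'   \item{fig4}{sharp vs smooth x weak/strong; anisotropy}
#'   \item{fig5}{three sharp shapes x weak/strong; face orientation
#'     histograms}
#'   \item{fig6}{ellipsoid with circumferential cue,
#'     `b_d` in 0, 0.001, 0.002, 0.01, 0.02 (weak anchoring, n_p 2.4e-7);
#'     axis-alignment histograms}
#' }
#' Only the last snapshot of each run is summarised, avoiding temporal
#' correlation between data points. The desk scale (10,000 steps, 3
#' replicates) shows the same trends as the full protocol (50,000 steps, 5
#' replicates) at a fraction of the cost.
#'
#' @param figure_id one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`
#' @param scale `"desk"` or `"full"`
#' @param n_steps,replicates optional overrides of the scale defaults
#' @param resolution mesh resolution (um)
#' @param seed base seed; replicate r of condition c uses
#'   `seed * 1000 + 100 * c + r`
#' @param out_dir optional directory for `metrics.csv` and histograms
#' @return list with `metrics` (tidy data.frame) and `histograms`
#'   (for fig5/fig6; NULL otherwise)
#' @export
replicate_experiment <- function(figure_id = c("fig2", "fig3", "fig4",
                                               "fig5", "fig6"),
                                 scale = c("desk", "full"), n_steps = NULL,
                                 replicates = NULL, resolution = 0.4,
                                 seed = 1L, out_dir = NULL) {
  figure_id <- match.arg(figure_id)
  scale <- match.arg(scale)
  if (is.null(n_steps)) n_steps <- if (scale == "desk") 10000L else 50000L
  if (is.null(replicates)) replicates <- if (scale == "desk") 3L else 5L

  conds <- switch(figure_id,
    fig2 = expand.grid(shape = setdiff(cell_shape_names(), "ellipsoid"),
                       anchoring = c("weak", "strong"),
                       stringsAsFactors = FALSE),
    fig3 = ,
    fig5 = expand.grid(shape = c("sharp_cube", "sharp_square", "sharp_long"),
                       anchoring = c("weak", "strong"),
                       stringsAsFactors = FALSE),
    fig4 = expand.grid(shape = setdiff(cell_shape_names(), "ellipsoid"),
                       anchoring = c("weak", "strong"),
                       stringsAsFactors = FALSE),
    fig6 = data.frame(shape = "ellipsoid",
                      anchoring = "weak",
                      b_d = c(0, 0.001, 0.002, 0.01, 0.02),
                      stringsAsFactors = FALSE))

  meshes <- new.env(parent = emptyenv())
  get_mesh <- function(name) {
    if (!exists(name, envir = meshes))
      assign(name, make_cell_shape(name, resolution), envir = meshes)
    get(name, envir = meshes)
  }

  metrics <- list()
  histograms <- list()
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, , drop = FALSE]
    mesh <- get_mesh(cond$shape)
    for (r in seq_len(replicates)) {
      run_seed <- seed * 1000L + 100L * ci + r
      if (figure_id == "fig6") {
        params <- growth_params(n_p = 2.4e-7, b_d = cond$b_d,
                                anchoring = "weak")
        cue <- cue_field("circumferential", c(0, 0, 1))
        label <- sprintf("b_d=%g", cond$b_d)
      } else {
        params <- growth_params(anchoring = cond$anchoring)
        cue <- cue_field("none")
        label <- sprintf("%s/%s", cond$shape, cond$anchoring)
      }
      traj <- run_simulation(mesh, params, n_steps = n_steps,
                             seed = run_seed,
                             snapshot_interval = n_steps, cue = cue,
                             trace = FALSE)
      snap <- final_snapshot(traj)
      m <- snapshot_metrics(snap, mesh, label = label)
      m$replicate <- r
      m$seed <- run_seed
      metrics[[length(metrics) + 1]] <- m
      if (figure_id == "fig5") {
        fn <- c(0, 0, 1)                       # largest faces are z-normal
        ra <- if (cond$shape == "sharp_long") c(0, 0, 1) else c(1, 0, 0)
        if (cond$shape == "sharp_long") {      # long axis is z: use x faces
          fn <- c(1, 0, 0)
        }
        histograms[[sprintf("%s_r%d", label, r)]] <-
          face_orientation_histogram(snap, mesh, fn, ra)
      }
      if (figure_id == "fig6") {
        histograms[[sprintf("%s_r%d", label, r)]] <-
          axis_alignment_histogram(snap, c(0, 0, 1))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics,
       histograms = if (length(histograms)) histograms else NULL,
       conditions = conds, n_steps = n_steps, replicates = replicates)
}
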