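# Desk-scale simulation grid shared by the acceptance-style tests.
# Runs are computed lazily and cached for the whole test session.
# Scale: 10,000 steps (past the initial transient on the standard shapes),
# default parameters unless stated; the final snapshot is scored.

DESK_STEPS <- 10000L

desk_mesh <- function(shape) cached(paste0("mesh_", shape),
                                    make_cell_shape(shape))

# one trajectory per (shape, anchoring, seed, cue weight)
desk_run <- function(shape, anchoring, seed, b_d = 0, n_p = 4.7e-7,
                     steps = DESK_STEPS) {
  key <- sprintf("run_%s_%s_np%g_s%d_b%g_k%d", shape, anchoring, n_p, seed,
                 b_d, steps)
  cached(key, {
    mesh <- desk_mesh(shape)
    params <- growth_params(n_p = n_p, anchoring = anchoring, b_d = b_d)
    cue <- if (shape == "ellipsoid")
      cue_field("circumferential", c(0, 0, 1)) else cue_field("none")
    run_simulation(mesh, params, n_steps = steps, seed = seed,
                   snapshot_interval = steps, cue = cue, trace = TRUE)
  })
}

# the nine default-parameter weak-anchoring runs behind the cortical-band
# checks: three seeds in each sharp shape
band_runs <- function() {
  runs <- list()
  seeds <- list(sharp_cube = 7011:7013, sharp_square = 7021:7023,
                sharp_long = 7031:7033)
  for (shape in names(seeds)) {
    for (s in seeds[[shape]]) {
      runs[[length(runs) + 1]] <- list(shape = shape, seed = s,
                                       traj = desk_run(shape, "weak", s))
    }
  }
  runs
}

median_axis_alignment <- function(snapshot, axis = c(0, 0, 1)) {
  d <- as.matrix(snapshot[, c("dx", "dy", "dz")])
  stats::median(abs(d %*% (axis / sqrt(sum(axis^2)))))
}
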