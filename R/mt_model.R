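#' Microtubule dynamics parameters
#'
#' Bundles the main microtubule-dynamics parameters with engine-level
#' settings. Units: a tubulin ring is a unit vector of physical length
#' `ell` = 8 nm = 0.008 um; one time step corresponds to `step_seconds`
#' (0.1-0.2 s, from a plus-end growth speed of 3-5 um/min).
#'
#' @param n_p nucleation frequency per `ell^2` of surface per time step.
#'   Default 4.7e-7; with the standard shapes this yields a few nucleation
#'   events per step.
#' @param n_s probability per step that a microtubule's minus end starts
#'   shrinking (treadmilling onset). Default 1e-3.
#' @param r_d directional noise weight in the growth rule; maps to a
#'   persistence length via [persistence_length()]. Default 0.025.
#' @param b_d directional-cue weight (0 disables the cue). Default 0.
#' @param alpha_deg encounter threshold angle in degrees: shallower
#'   encounters zipper, steeper ones trigger catastrophe. Default 40.
#' @param anchoring `"weak"` (microtubules may leave the surface) or
#'   `"strong"` (growth confined to the local tangent plane).
#' @param ell segment length in um (8 nm).
#' @param step_seconds real time per simulation step (s).
#' @param interaction_radius microtubule-microtubule encounter distance (um),
#'   25 nm.
#' @param membrane_radius distance from the membrane at which the
#'   weak-anchoring rule engages (um), 10 nm.
#' @param events_per_step direct override of the nucleation rate in events
#'   per step (`NA` derives it as `n_p * area / ell^2`).
#' @param nucleation_direction initial direction rule for weak anchoring:
#'   `"tangential"` (uniform in the local tangent plane, the default) or
#'   `"isotropic"` (uniform over directions, resampled to point inside or
#'   tangentially). Strong anchoring always nucleates tangentially. The
#'   tangential default reproduces the observed cortical localisation and
#'   bundling of the arrays; the isotropic variant floods the cell interior
#'   with crossing filaments (see the methods vignette).
#' @param retry_budget bounded retries when redrawing the noise vector near
#'   the membrane.
#' @param self_exclusion number of the tip's own trailing segments excluded
#'   from its collision test.
#' @return an object of class `growth_params`
#' @export
growth_params <- function(n_p = 4.7e-7, n_s = 1e-3, r_d = 0.025, b_d = 0,
                          alpha_deg = 40, anchoring = c("weak", "strong"),
                          ell = 0.008, step_seconds = 0.12,
                          interaction_radius = 0.025,
                          membrane_radius = 0.010, events_per_step = NA,
                          nucleation_direction = c("tangential", "isotropic"),
                          retry_budget = 32L, self_exclusion = 3L) {
  anchoring <- match.arg(anchoring)
  nucleation_direction <- match.arg(nucleation_direction)
  p <- list(n_p = n_p, n_s = n_s, r_d = r_d, b_d = b_d,
            alpha_deg = alpha_deg, anchoring = anchoring, ell = ell,
            step_seconds = step_seconds,
            interaction_radius = interaction_radius,
            membrane_radius = membrane_radius,
            events_per_step = events_per_step,
            nucleation_direction = nucleation_direction,
            retry_budget = as.integer(retry_budget),
            self_exclusion = as.integer(self_exclusion))
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  if (p$r_d < 0 || p$b_d < 0 || p$r_d + p$b_d > 1)
    stop("invalid parameters: need 0 <= r_d, b_d and r_d + b_d <= 1")
  if (p$alpha_deg <= 0 || p$alpha_deg >= 90)
    stop("invalid parameters: alpha_deg must lie in (0, 90)")
  if (p$n_p < 0 || p$n_s < 0 || p$n_s > 1)
    stop("invalid parameters: rates must be non-negative (n_s a probability)")
  if (p$ell <= 0 || p$interaction_radius <= 0 || p$membrane_radius <= 0)
    stop("invalid parameters: lengths must be positive")
  if (p$step_seconds < 0) stop("invalid parameters: step_seconds < 0")
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(paste0(
    "growth_params: n_p=%.3g per ell^2/step, n_s=%.3g, r_d=%.3g, b_d=%.3g,\n",
    "  alpha=%.1f deg, anchoring=%s, ell=%g um, step=%g s ",
    "(persistence length %.1f um)\n"),
    x$n_p, x$n_s, x$r_d, x$b_d, x$alpha_deg, x$anchoring, x$ell,
    x$step_seconds, persistence_length(x)))
  invisible(x)
}

#' Persistence length implied by the directional-noise weight
#'
#' The defaults were chosen through the small-noise mapping
#' `p = 2 * ell / r_d^2`, which for `r_d = 0.025` and `ell` = 8 nm gives
#' about 26 um, in the range measured in vivo. Note that the empirical
#' tangent-correlation decay of simulated free filaments in 3D is
#' `exp(-s * r_d^2 / 3)` per segment (see the methods vignette), so the
#' 3D-convention persistence length is `3 * ell / r_d^2`; this function
#' reports the mapping used to set the defaults.
#'
#' @param params a [growth_params()] (or anything with `ell` and `r_d`)
#' @return persistence length in um
#' @export
persistence_length <- function(params) {
  2 * params$ell / params$r_d^2
}

#' Uniform random unit vectors
#'
#' Exactly isotropic directions from normalised 3D Gaussians, using the R
#' random number generator.
#' @param n number of vectors
#' @return n x 3 matrix of unit rows
#' @export
random_unit_vector <- function(n = 1) {
  repeat {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    nn <- sqrt(rowSums(v^2))
    if (all(nn > 1e-8)) return(v / nn)
  }
}

#' Propose the next growth direction
#'
#' The plus-end growth rule: the new unit vector is the normalised weighted
#' average of the previous direction (weight `1 - r_d - b_d`), a fresh
#' uniform random unit vector (weight `r_d`), and, when a cue is supplied,
#' the cue direction (weight `b_d`). With `b` absent the cue weight is zero.
#'
#' @param r_prev previous unit direction (length 3)
#' @param params a [growth_params()]
#' @param u optional explicit random unit vector (drawn internally if NULL)
#' @param b optional unit cue vector
#' @return unit length-3 vector
#' @export
propose_growth_direction <- function(r_prev, params, u = NULL, b = NULL) {
  b_d <- if (is.null(b)) 0 else params$b_d
  for (k in 1:64) {
    uu <- if (is.null(u)) drop(random_unit_vector(1)) else u
    v <- (1 - params$r_d - b_d) * r_prev + params$r_d * uu
    if (!is.null(b)) v <- v + b_d * b
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) return(v / nv)
    if (!is.null(u)) stop("degenerate direction combination for supplied u")
  }
  r_prev
}

#' Circumferential (orthoradial) cue direction
#'
#' Unit vector perpendicular both to the axis of revolution and to the local
#' radial vector: the hoop direction around the axis.
#'
#' @param position query position (length 3)
#' @param axis unit vector along the axis of revolution
#' @param center a point on the axis (default the origin)
#' @return unit length-3 vector
#' @export
circumferential_cue <- function(position, axis, center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  rel <- position - center
  radial <- rel - sum(rel * axis) * axis
  rn <- sqrt(sum(radial^2))
  if (rn < 1e-9) stop("undefined cue: position lies on the axis of revolution")
  b <- c(axis[2] * radial[3] - axis[3] * radial[2],
         axis[3] * radial[1] - axis[1] * radial[3],
         axis[1] * radial[2] - axis[2] * radial[1]) / rn
  b / sqrt(sum(b^2))
}

#' Classify a microtubule-microtubule encounter
#'
#' The angle is measured between undirected lines: the target direction's
#' sign is chosen to give an angle of at most 90 degrees. Angles strictly
#' below `alpha_deg` zipper (the tip adopts the sign-adjusted target
#' direction); angles at or above the threshold trigger catastrophe.
#'
#' @param tip_dir unit direction of the growing tip
#' @param target_dir unit direction of the encountered segment
#' @param alpha_deg threshold angle in degrees
#' @return list with `event` (`"zipper"` or `"catastrophe"`), `angle_deg`,
#'   and for zippering the sign-adjusted `direction`
#' @export
classify_encounter <- function(tip_dir, target_dir, alpha_deg = 40) {
  d <- sum(tip_dir * target_dir)
  ang <- acos(pmin(1, abs(d))) * 180 / pi
  if (abs(d) > cos(alpha_deg * pi / 180)) {
    list(event = "zipper", angle_deg = ang,
         direction = if (d >= 0) target_dir else -target_dir)
  } else {
    list(event = "catastrophe", angle_deg = ang, direction = NULL)
  }
}

#' Project a growth direction onto the membrane tangent plane
#'
#' Strong-anchoring rule: growth keeps only the tangential component of the
#' proposed direction.
#'
#' @param dir proposed unit direction
#' @param plane_normal outward unit normal of the local tangent plane
#' @return unit tangential vector
#' @export
apply_strong_anchoring <- function(dir, plane_normal) {
  t <- dir - sum(dir * plane_normal) * plane_normal
  nt <- sqrt(sum(t^2))
  if (nt < 1e-8)
    stop("degenerate projection: direction parallel to the plane normal")
  t / nt
}

#' Weak-anchoring membrane rule at the plus end
#'
#' Applied when the tip endpoint is within `membrane_radius` (10 nm) of the
#' membrane. The angle between the microtubule (its current tip direction)
#' and the local tangent plane decides the outcome: steeper than `alpha_deg`
#' triggers catastrophe; otherwise the proposed direction is accepted if the
#' new endpoint stays inside the cell, and the noise vector is redrawn
#' (bounded retries) until it does, falling back to the tangential projection
#' so that endpoints never leave the cell.
#'
#' @param tip_endpoint current plus-end endpoint (length 3)
#' @param tip_dir current tip unit direction
#' @param proposed_dir proposed new unit direction
#' @param probe [nearest_surface()] probe at the tip endpoint
#' @param mesh the cell [tri_mesh()] (for containment checks on retries)
#' @param params a [growth_params()]
#' @return list with `event` (`"catastrophe"` or `"grow"`), `direction`,
#'   and `fallback` (TRUE when the retry budget was exhausted)
#' @export
apply_weak_anchoring <- function(tip_endpoint, tip_dir, proposed_dir, probe,
                                 mesh, params) {
  n <- probe$normal
  sin_alpha <- sin(params$alpha_deg * pi / 180)
  if (abs(sum(tip_dir * n)) > sin_alpha)
    return(list(event = "catastrophe", direction = NULL, fallback = FALSE))
  nd <- proposed_dir
  for (k in 0:params$retry_budget) {
    ep <- tip_endpoint + params$ell * nd
    pr <- nearest_surface(mesh, ep)
    s <- sum((ep - pr$nearest_point) * pr$normal)
    if (s < 1e-9)
      return(list(event = "grow", direction = nd, fallback = FALSE))
    nd <- propose_growth_direction(tip_dir, params)
  }
  t <- nd - sum(nd * n) * n
  nt <- sqrt(sum(t^2))
  while (nt < 1e-8) {
    d <- drop(random_unit_vector(1))
    t <- d - sum(d * n) * n
    nt <- sqrt(sum(t^2))
  }
  list(event = "grow", direction = t / nt, fallback = TRUE)
}

#' Nucleate a microtubule on the cell surface
#'
#' Single nucleation event: a uniform surface point with an initial direction
#' drawn per the configured nucleation rule (uniform in the local tangent
#' plane by default; optionally isotropic, resampled to point inside or
#' tangentially). Strong anchoring always nucleates tangentially. Uses the R
#' random number generator.
#'
#' @param mesh a [tri_mesh()]
#' @param params a [growth_params()]
#' @param id microtubule identifier
#' @return a `microtubule` list: `id`, `origin`, `dirs` (k x 3),
#'   `endpoints` (k x 3), `minus_shrinking`, `plus_cat`
#' @export
nucleate <- function(mesh, params, id = 0L) {
  s <- sample_surface_point(mesh, 1)
  p <- s$points[1, ]
  n <- s$normals[1, ]
  if (params$anchoring == "strong" ||
      params$nucleation_direction == "tangential") {
    repeat {
      d <- drop(random_unit_vector(1))
      t <- d - sum(d * n) * n
      if (sqrt(sum(t^2)) > 1e-8) { d <- t / sqrt(sum(t^2)); break }
    }
  } else {
    repeat {
      d <- drop(random_unit_vector(1))
      if (sum(d * n) <= 1e-12) break
    }
  }
  microtubule(id, p, matrix(d, 1, 3), params$ell)
}

#' Construct a microtubule from an origin and segment directions
#' @param id integer identifier
#' @param origin minus-end origin (length 3)
#' @param dirs k x 3 matrix of unit directions (minus to plus)
#' @param ell segment length (um)
#' @param minus_shrinking,plus_cat dynamic-state flags
#' @return a `microtubule` list
#' @export
microtubule <- function(id, origin, dirs, ell = 0.008,
                        minus_shrinking = FALSE, plus_cat = FALSE) {
  dirs <- matrix(dirs, ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cums <- apply(dirs, 2, cumsum)
  if (is.null(dim(cums))) cums <- matrix(cums, 1, 3)
  endpoints <- sweep(ell * cums, 2, origin, `+`)
  structure(list(id = as.integer(id), origin = origin, dirs = dirs,
                 endpoints = endpoints, minus_shrinking = minus_shrinking,
                 plus_cat = plus_cat, ell = ell), class = "microtubule")
}

#' Minus-end update (treadmilling onset and shrinkage)
#'
#' If the microtubule is not yet shrinking, it starts with probability `n_s`
#' (no segment is removed on the onset step); once shrinking, one segment is
#' removed from the minus end per step. A microtubule that loses its last
#' segment is returned as `NULL` (removed from the network).
#'
#' @param mt a `microtubule`
#' @param params a [growth_params()]
#' @return the updated `microtubule`, or `NULL` when it disappears
#' @export
minus_end_update <- function(mt, params) {
  if (!mt$minus_shrinking) {
    if (stats::runif(1) < params$n_s) mt$minus_shrinking <- TRUE
    return(mt)
  }
  if (nrow(mt$dirs) <= 1) return(NULL)
  mt$origin <- mt$endpoints[1, ]
  mt$dirs <- mt$dirs[-1, , drop = FALSE]
  mt$endpoints <- mt$endpoints[-1, , drop = FALSE]
  mt
}

#' Plus-end update against neighbours and the membrane
#'
#' One growth step for a single microtubule. If the plus end is in
#' catastrophe, one segment is removed (`"shrink"`). Otherwise a direction is
#' proposed; the nearest other-filament segment endpoint within the
#' interaction radius (excluding the tip's own trailing segments) is
#' classified as zippering or catastrophe; failing that, the membrane rule of
#' the active anchoring mode applies; otherwise the proposal is appended.
#'
#' @param mt a `microtubule`
#' @param neighbors list with `pos` (n x 3 endpoints), `dir` (n x 3), `mt_id`
#'   (length n), or `NULL` for no neighbours
#' @param mesh a [tri_mesh()] or `NULL` for unbounded growth
#' @param params a [growth_params()]
#' @param cue optional function(position) returning a unit cue vector
#' @return list with `event` (`"grow"`, `"zipper"`, `"catastrophe_start"`,
#'   `"shrink"`) and the updated `mt` (`NULL` if it disappeared)
#' @export
plus_end_update <- function(mt, neighbors = NULL, mesh = NULL, params,
                            cue = NULL) {
  k <- nrow(mt$dirs)
  if (mt$plus_cat) {
    if (k <= 1) return(list(event = "shrink", mt = NULL))
    mt$dirs <- mt$dirs[-k, , drop = FALSE]
    mt$endpoints <- mt$endpoints[-k, , drop = FALSE]
    return(list(event = "shrink", mt = mt))
  }
  tip <- mt$endpoints[k, ]
  tdir <- mt$dirs[k, ]
  b <- if (!is.null(cue)) cue(tip) else NULL
  if (!is.null(b) && sum(b * tdir) < 0) b <- -b
  prop <- propose_growth_direction(tdir, params, b = b)

  append_seg <- function(mt, d) {
    mt$dirs <- rbind(mt$dirs, d)
    mt$endpoints <- rbind(mt$endpoints, tip + params$ell * d)
    mt
  }

  # (a) microtubule encounter
  if (!is.null(neighbors) && length(neighbors$mt_id) > 0) {
    d2 <- rowSums((neighbors$pos - matrix(tip, length(neighbors$mt_id), 3,
                                          byrow = TRUE))^2)
    own <- neighbors$mt_id == mt$id
    gidx <- seq_along(d2)
    excl <- own & gidx > length(gidx) - params$self_exclusion
    ok <- which(!excl & d2 <= params$interaction_radius^2)
    if (length(ok)) {
      j <- ok[order(d2[ok], neighbors$mt_id[ok], gidx[ok])][1]
      cls <- classify_encounter(tdir, neighbors$dir[j, ], params$alpha_deg)
      if (cls$event == "zipper") {
        # the host direction replaces the previous vector; the usual noisy
        # growth update applies on top of it
        nd <- propose_growth_direction(cls$direction, params, b = b)
        return(list(event = "zipper", mt = append_seg(mt, nd)))
      }
      mt$plus_cat <- TRUE
      return(list(event = "catastrophe_start", mt = mt))
    }
  }

  # (b) membrane rule
  if (!is.null(mesh)) {
    probe <- nearest_surface(mesh, tip)
    if (params$anchoring == "strong") {
      t <- prop - sum(prop * probe$normal) * probe$normal
      r <- 0
      while (sqrt(sum(t^2)) < 1e-8 && r < params$retry_budget) {
        prop <- propose_growth_direction(tdir, params, b = b)
        t <- prop - sum(prop * probe$normal) * probe$normal
        r <- r + 1
      }
      t <- t / sqrt(sum(t^2))
      target <- tip + params$ell * t
      q <- nearest_surface(mesh, target)$nearest_point
      d <- q - tip
      d <- if (sqrt(sum(d^2)) > 1e-9) d / sqrt(sum(d^2)) else t
      return(list(event = "grow", mt = append_seg(mt, d)))
    }
    if (probe$distance <= params$membrane_radius) {
      res <- apply_weak_anchoring(tip, tdir, prop, probe, mesh, params)
      if (res$event == "catastrophe") {
        mt$plus_cat <- TRUE
        return(list(event = "catastrophe_start", mt = mt))
      }
      return(list(event = "grow", mt = append_seg(mt, res$direction)))
    }
  }

  # (c) free growth
  list(event = "grow", mt = append_seg(mt, prop))
}
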