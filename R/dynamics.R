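# Equations of motion, constraint projection, initialisation, relaxation and
# the top-level simulation loop. System state is held in a `trichome_system`
# object; positions are stored internally in SI metres and exposed in
# micrometres at the trajectory/plot boundary.

#' Hard-wall reaction force on the top and bottom domain boundaries
#'
#' The domain is periodic laterally but bounded above and below by stiff
#' planes. A vertex whose centerline sits closer than `theta / 2` to either
#' plane receives a restoring force proportional to the penetration:
#' `F_z = wall_c * (H - theta/2 - z)` above, `wall_c * (theta/2 - z)` below,
#' zero in between.
#'
#' @param z vertex height coordinate(s).
#' @param H domain height (same unit as `z`).
#' @param theta trichome diameter.
#' @param wall_c wall stiffness (force per length).
#' @return z-force per vertex (vectorised).
#' @examples
#' wall_forces(7.0, H = 7.5, theta = 1.5, wall_c = 1)  # -0.25
#' @export
wall_forces <- function(z, H, theta, wall_c) {
  if (wall_c <= 0) stop("wall_forces: wall_c must be positive")
  zhi <- H - theta / 2
  zlo <- theta / 2
  ifelse(z > zhi, wall_c * (zhi - z), ifelse(z < zlo, wall_c * (zlo - z), 0))
}

#' Overdamped velocity from force under anisotropic slender-body drag
#'
#' A slender filament moves roughly twice as easily along its axis as
#' perpendicular to it. The velocity response to a total vertex force `F` is
#' \deqn{v = \frac{1}{\zeta}\left(F_\parallel + \frac{1}{b} F_\perp\right)}
#' with the parallel/perpendicular split taken along the local unit tangent.
#'
#' @param F force vector (length 3) or n x 3 matrix.
#' @param tangent unit tangent, same shape as `F`.
#' @param zeta per-vertex drag coefficient.
#' @param b drag anisotropy ratio (perpendicular/tangential), ~2 for long
#'   thin filaments.
#' @return Velocity, same shape as `F`.
#' @export
project_velocity <- function(F, tangent, zeta, b = 2) {
  if (zeta <= 0 || b < 1) stop("project_velocity: zeta > 0 and b >= 1 required")
  if (is.matrix(F)) {
    ft <- rowSums(F * tangent)
    fpar <- ft * tangent
    (fpar + (F - fpar) / b) / zeta
  } else {
    ft <- sum(F * tangent)
    (ft * tangent + (F - ft * tangent) / b) / zeta
  }
}

#' Restore exact bond lengths after an unconstrained step
#'
#' Projects a proposed vertex chain back onto the inextensibility manifold
#' (all adjacent-vertex distances equal to `l`) using a LINCS-type solver:
#' corrections act along the bond directions of the reference chain, the
#' constraint coupling matrix (tridiagonal for a chain topology) is solved
#' exactly, and the correction is iterated until every bond length is
#' within `tol * l`.
#'
#' @param proposed (N+1) x 3 matrix, chain after an unconstrained step.
#' @param reference (N+1) x 3 matrix, constraint-satisfying chain the step
#'   started from (supplies the constraint directions).
#' @param l target bond length.
#' @param tol relative bond-length tolerance.
#' @param maxit maximum correction iterations.
#' @return Corrected (N+1) x 3 matrix.
#' @examples
#' ref <- cbind(0:3, 0, 0)
#' prop <- ref; prop[4, 1] <- 3.05
#' range(diff(lincs_project(prop, ref, l = 1)[, 1]))
#' @export
lincs_project <- function(proposed, reference, l, tol = 1e-8, maxit = 100) {
  stopifnot(is.matrix(proposed), is.matrix(reference),
            all(dim(proposed) == dim(reference)))
  par <- list(theta = 1, l = l, alpha = 0, zeta = 1, v0 = 0, omega = 0,
              epsilon = 0, eps_rep = 0, b_aniso = 1, cap_R = 0, wall_c = 1,
              W = 1, H = 1, D = 1, abs_accuracy = 1, dt_max = 1, dt_min = 0,
              lincs_tol = tol, lincs_maxit = as.integer(maxit))
  res <- cpp_lincs(proposed, reference, c(0L, nrow(proposed)), par)
  if (!res$converged)
    stop("lincs_project: constraint solver did not converge (step too large)")
  res$pos
}

# ---- system state ----------------------------------------------------------

.new_system <- function(params, pos, polarity, t = 0, dt = NULL) {
  # start the adaptive controller at a conservative fraction of the
  # characteristic time L/V; everything downstream of dt scales with it
  if (is.null(dt)) dt <- 1e-3 * params$scales$T
  structure(list(params = params, pos = pos, polarity = as.integer(polarity),
                 offsets = .make_offsets(params, nrow(pos)), t = t, dt = dt),
            class = "trichome_system")
}

.make_offsets <- function(params, n_vertices) {
  nv <- params$n_segments + 1L
  n_tri <- n_vertices %/% nv
  if (n_tri * nv != n_vertices)
    stop("vertex count is not a multiple of n_segments + 1")
  as.integer(seq(0L, n_tri * nv, by = nv))
}

#' Place straight trichomes at random in the domain
#'
#' Trichomes start straight, parallel to the xy plane, with uniformly random
#' centre, in-plane orientation and height (clear of the walls by
#' `theta / 2`), and equiprobable gliding polarity. The trichome count is
#' set by the volume fraction `rho` via [trichome_count()]. Draws come from
#' the current R RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param params a [system_params()] object.
#' @return A `trichome_system` object (positions in SI metres, clock at 0).
#' @examples
#' set.seed(1)
#' sys <- initialize_system(system_params(domain = c(300, 7.5, 300),
#'   lam = 150, n_segments = 25))
#' @export
initialize_system <- function(params) {
  n_tri <- params$n_trichomes
  if (n_tri < 1) {
    if (params$rho == 0)
      return(.new_system(params, matrix(numeric(0), 0, 3), integer(0)))
    stop("initialize_system: density too low for a single trichome")
  }
  nv <- params$n_segments + 1L
  W <- params$domain[1]; H <- params$domain[2]; D <- params$domain[3]
  l <- params$l
  k <- seq(0, params$n_segments) - params$n_segments / 2
  pos <- matrix(0, n_tri * nv, 3)
  polarity <- integer(n_tri)
  for (f in seq_len(n_tri)) {
    cx <- runif(1) * W
    cy <- runif(1) * D
    cz <- params$theta / 2 + runif(1) * (H - params$theta)
    phi <- runif(1) * 2 * pi
    polarity[f] <- if (runif(1) < 0.5) -1L else 1L
    rows <- ((f - 1) * nv + 1):(f * nv)
    pos[rows, 1] <- cx + k * l * cos(phi)
    pos[rows, 2] <- cy + k * l * sin(phi)
    pos[rows, 3] <- cz
  }
  .new_system(params, pos * .um, polarity)
}

#' Total force on every vertex of the system
#'
#' Sum of bending, gliding, contact and wall forces, evaluated with a fresh
#' neighbour list. Forces are in newtons (positions internally SI).
#'
#' @param state a `trichome_system`.
#' @param gliding logical; include the propulsion force.
#' @param repulsion_only logical; suppress contact attraction (the
#'   cohesionless hard core used during overlap relaxation).
#' @return n_vertices x 3 matrix of forces (N).
#' @export
compute_forces <- function(state, gliding = TRUE, repulsion_only = FALSE) {
  stopifnot(inherits(state, "trichome_system"))
  par <- .engine_params(state$params, gliding = gliding)
  cpp_total_forces(state$pos, state$offsets, state$polarity, par,
                   repulsion_only)
}

#' Candidate contact pairs within the interaction cutoff
#'
#' Broad-phase neighbour list: all edge pairs whose (minimum-image)
#' midpoint distance is below `2 * theta + l`, a guaranteed superset of the
#' pairs with true segment separation below the `2 * theta` force cutoff.
#' Edge pairs on the same trichome closer than 3 positions apart are
#' excluded (adjacent capsules overlap by construction). Inside the
#' integrator the list is reused until some vertex has moved `theta` from
#' its build-time position.
#'
#' @param state a `trichome_system`.
#' @return List with `pairs` (m x 2 matrix of 1-based global edge indices),
#'   `n_edges`, and `edge_trichome` (trichome id per edge).
#' @export
build_neighbor_list <- function(state) {
  stopifnot(inherits(state, "trichome_system"))
  par <- .engine_params(state$params)
  pairs <- cpp_neighbor_pairs(state$pos, state$offsets, par)
  nseg <- diff(state$offsets) - 1L
  list(pairs = pairs, n_edges = sum(nseg),
       edge_trichome = rep(seq_along(nseg), nseg))
}

#' Advance the system by one accepted adaptive Euler step
#'
#' Performs one step of the adaptive first-order integrator: step-doubling
#' error estimate (one full step against two half steps, error = maximum
#' vertex position difference), acceptance when the error is below the
#' configured absolute accuracy, LINCS bond-length projection after every
#' unconstrained substep, reversal sampling on acceptance, and step-size
#' adaptation with safety factor 0.9 and growth capped at 1.5x.
#'
#' @param state a `trichome_system`.
#' @param gliding,repulsion_only,reversals logicals selecting active force
#'   and process terms (all on by default).
#' @return Updated `trichome_system` (clock advanced by the accepted dt).
#' @export
adaptive_euler_step <- function(state, gliding = TRUE,
                                repulsion_only = FALSE, reversals = TRUE) {
  stopifnot(inherits(state, "trichome_system"))
  par <- .engine_params(state$params, gliding = gliding)
  res <- cpp_advance(state$pos, state$offsets, state$polarity, par,
                     t = state$t, t_target = state$t + 100 * par$dt_max,
                     dt = state$dt, repulsion_only = repulsion_only,
                     reversals = reversals, max_steps = 1L)
  state$pos <- res$pos
  state$polarity <- res$polarity
  state$t <- res$t
  state$dt <- res$dt
  state
}

# Advance to an absolute time (many steps); internal workhorse.
.advance_to <- function(state, t_target, gliding = TRUE,
                        repulsion_only = FALSE, reversals = TRUE,
                        max_steps = -1L) {
  par <- .engine_params(state$params, gliding = gliding)
  res <- cpp_advance(state$pos, state$offsets, state$polarity, par,
                     t = state$t, t_target = t_target, dt = state$dt,
                     repulsion_only = repulsion_only, reversals = reversals,
                     max_steps = as.integer(max_steps))
  state$pos <- res$pos
  state$polarity <- res$polarity
  state$t <- res$t
  state$dt <- res$dt
  attr(state, "step_stats") <- res[c("n_accept", "n_reject", "n_rebuild",
                                     "max_err")]
  state
}

#' Remove initial overlaps by steric-only relaxation
#'
#' Evolves the freshly initialised system with gliding, reversals and
#' cohesion all switched off — only the hard-core contact repulsion and the
#' walls act — until the deepest contact penetration (`theta - h` over all
#' neighbour pairs) falls below `tol_frac * theta` or the configuration has
#' reached its steric equilibrium (a simulated-time budget). In a shallow
#' domain, columns of several mutually crossing trichomes can be
#' geometrically unable to reach full `theta` layer spacing (the channel
#' height admits at most `H / theta` layers); such stacks equilibrate at a
#' slightly smaller spacing with balanced forces, which is accepted. Only a
#' persisting deep overlap (separation below `fail_frac * theta`) is
#' treated as an infeasibly dense packing and raises an error.
#'
#' @param state a `trichome_system`.
#' @param tol_frac admissible residual penetration as a fraction of theta.
#' @param max_time simulated-time budget for the relaxation (s); defaults
#'   to 35 characteristic times `scales$T` (~5 min at the default
#'   parameters), so that the whole procedure is invariant under the
#'   model's length-time rescaling.
#' @param fail_frac separation fraction of theta below which a remaining
#'   overlap after the budget is an error.
#' @return Relaxed `trichome_system` with the clock reset to 0.
#' @export
relax_overlaps <- function(state, tol_frac = 0.01, max_time = NULL,
                           fail_frac = 0.5) {
  stopifnot(inherits(state, "trichome_system"))
  if (is.null(max_time)) max_time <- 35 * state$params$scales$T
  par <- .engine_params(state$params, gliding = FALSE, reversals = FALSE)
  theta_m <- state$params$theta * .um
  target <- (1 - tol_frac) * theta_m
  t_stop <- state$t + max_time
  chunk <- 100L
  repeat {
    sep <- cpp_min_separation(state$pos, state$offsets, par)
    if (sep >= target) break
    if (state$t >= t_stop) {
      if (sep < fail_frac * theta_m)
        stop("relax_overlaps: deep overlap remains after the relaxation ",
             "budget (separation ", format(sep / theta_m, digits = 3),
             " theta); density too high")
      break  # steric quasi-equilibrium of a jammed stack
    }
    state <- .advance_to(state, t_target = t_stop,
                         gliding = FALSE, repulsion_only = TRUE,
                         reversals = FALSE, max_steps = chunk)
  }
  state$t <- 0
  state$dt <- min(state$dt, 0.01 * state$params$scales$T)
  state
}

#' Run a full simulation: initialise, relax, evolve, record frames
#'
#' The top-level driver. Seeds the RNG, places the trichomes, relaxes
#' overlaps with gliding off, then integrates the full dynamics to `t_end`,
#' recording a frame every `frame_interval` seconds (the post-relaxation
#' configuration is frame 0 at t = 0). Identical seeds give bit-identical
#' trajectories on the same platform.
#'
#' @param params a [system_params()] object (or a config file path, passed
#'   to [load_config()]).
#' @param t_end simulated end time (s).
#' @param frame_interval time between recorded frames (s); the default
#'   matches the sector-analysis sampling interval of 288 s.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param out_dir optional directory: frames and the run manifest are
#'   written there (see [write_trajectory()]).
#' @param relax logical; perform the initial steric relaxation.
#' @param verbose logical; progress messages per frame.
#' @return A `trichome_sim` object: list with `params`, `trajectory` (a
#'   `trichome_trajectory` frame table), `final_state` and `manifest`.
#' @examples
#' \donttest{
#' p <- system_params(domain = c(200, 7.5, 200), lam = 60, n_segments = 10,
#'                    rho = 0.005)
#' sim <- run_simulation(p, t_end = 60, frame_interval = 30, seed = 7)
#' summary(sim)
#' }
#' @export
run_simulation <- function(params, t_end, frame_interval = 288,
                           seed = NULL, out_dir = NULL, relax = TRUE,
                           verbose = FALSE) {
  if (is.character(params)) params <- load_config(params)
  stopifnot(inherits(params, "system_params"))
  if (is.null(seed)) seed <- params$seed
  set.seed(seed)
  state <- initialize_system(params)
  if (relax && state$params$n_trichomes > 0) state <- relax_overlaps(state)
  state$t <- 0

  frame_times <- seq(0, t_end, by = frame_interval)
  if (tail(frame_times, 1) < t_end) frame_times <- c(frame_times, t_end)
  frames <- vector("list", length(frame_times))
  frames[[1]] <- .frame_record(state, 0)
  stats <- list()
  for (k in seq_along(frame_times)[-1]) {
    state <- .advance_to(state, t_target = frame_times[k])
    frames[[k]] <- .frame_record(state, frame_times[k])
    stats[[k - 1]] <- attr(state, "step_stats")
    if (verbose)
      message(sprintf("t = %.0f s (dt = %.3g s, %d steps)", state$t,
                      state$dt, as.integer(stats[[k - 1]]$n_accept)))
  }
  traj <- .new_trajectory(data.table::rbindlist(frames), params, seed)
  manifest <- .run_manifest(params, seed, t_end, frame_interval)
  sim <- structure(list(params = params, trajectory = traj,
                        final_state = state, manifest = manifest,
                        step_stats = data.table::rbindlist(stats)),
                   class = "trichome_sim")
  if (!is.null(out_dir)) write_trajectory(sim, out_dir)
  sim
}

# One frame as a data.table in user units (um).
.frame_record <- function(state, time) {
  nv <- diff(state$offsets)
  data.table::data.table(
    time = time,
    trichome = rep(seq_along(nv), nv),
    vertex = unlist(lapply(nv, function(n) seq_len(n) - 1L)),
    x = state$pos[, 1] / .um,
    y = state$pos[, 2] / .um,
    z = state$pos[, 3] / .um,
    polarity = rep(state$polarity, nv)
  )
}

#' @export
print.trichome_system <- function(x, ...) {
  cat(sprintf("trichome_system: %d trichomes, %d vertices, t = %.1f s\n",
              length(x$polarity), nrow(x$pos), x$t))
  print(x$params)
  invisible(x)
}

#' @export
print.trichome_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("trichome_sim: %d trichomes, %d frames, t in [0, %.0f] s, seed %d\n",
              x$params$n_trichomes, length(unique(tr$frames$time)),
              max(tr$frames$time), x$manifest$seed))
  invisible(x)
}

#' @export
summary.trichome_sim <- function(object, ...) {
  tr <- object$trajectory$frames
  times <- unique(tr$time)
  cat("Gliding-trichome simulation\n")
  print(object$params)
  cat(sprintf("frames: %d (every %.0f s), final t = %.0f s\n",
              length(times), object$manifest$frame_interval, max(times)))
  if (nrow(object$step_stats) > 0) {
    cat(sprintf("integrator: %d accepted / %d rejected steps, %d list rebuilds\n",
                as.integer(sum(object$step_stats$n_accept)),
                as.integer(sum(object$step_stats$n_reject)),
                as.integer(sum(object$step_stats$n_rebuild))))
    cat(sprintf("max per-step error: %.3g um\n",
                max(object$step_stats$max_err) / .um))
  }
  invisible(object)
}

#' Plot the instantaneous configuration of a system or simulation frame
#'
#' Draws the trichome centerlines projected onto the xy plane (coordinates
#' wrapped into the periodic box).
#'
#' @param x a `trichome_system` or `trichome_sim` (for the latter, the frame
#'   closest to `time` is drawn).
#' @param time frame time for `trichome_sim` objects (default: last frame).
#' @param ... passed to [graphics::plot()].
#' @export
plot.trichome_system <- function(x, ...) {
  df <- .frame_record(x, x$t)
  .plot_frame(df, x$params, ...)
}

#' @rdname plot.trichome_system
#' @export
plot.trichome_sim <- function(x, time = NULL, ...) {
  fr <- x$trajectory$frames
  if (is.null(time)) time <- max(fr$time)
  tsel <- fr$time[which.min(abs(unique(fr$time) - time))]
  tt <- unique(fr$time)
  tsel <- tt[which.min(abs(tt - time))]
  .plot_frame(fr[fr$time == tsel, ], x$params, ...)
}

.plot_frame <- function(df, params, ...) {
  W <- params$domain[1]; D <- params$domain[3]
  graphics::plot(NA, xlim = c(0, W), ylim = c(0, D), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  for (f in unique(df$trichome)) {
    sub <- df[df$trichome == f, ]
    # split polylines at periodic wrap jumps
    xw <- sub$x %% W
    yw <- sub$y %% D
    jump <- c(FALSE, abs(diff(xw)) > W / 2 | abs(diff(yw)) > D / 2)
    seg <- cumsum(jump)
    for (s in unique(seg)) {
      i <- seg == s
      if (sum(i) > 1) graphics::lines(xw[i], yw[i], col = "#2c7fb8")
    }
  }
  invisible(NULL)
}
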