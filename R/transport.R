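# Overdamped particle transport: plane-Poiseuille channel flow, Stokes
# drag, buoyant gravity, trap force fields, RK4 trajectory integration and
# trap/repel outcome classification.
#
# Coordinates: x runs along the flow, y across the channel, z up from the
# electrode plane; the trap axis is the z axis through (x, y) = (0, 0).
# The axisymmetric field is sampled at (rho, z) with rho = sqrt(x^2 + y^2).

#' Pressure-driven channel flow model
#'
#' @param volumetric_rate Volumetric flow rate (m^3/s), >= 0.  The default
#'   is 2.5 uL/min.
#' @param enabled Logical; `FALSE` freezes the fluid (zero velocity
#'   everywhere) without touching the rate.
#' @return Object of class `flow_model`.
#' @export
flow_model <- function(volumetric_rate = 2.5e-9 / 60, enabled = TRUE) {
  stopifnot("volumetric_rate must be >= 0" = volumetric_rate >= 0,
            "enabled must be TRUE/FALSE" = isTRUE(enabled) || isFALSE(enabled))
  structure(list(volumetric_rate = volumetric_rate, enabled = enabled),
            class = "flow_model")
}

#' Axial flow velocity at height z (plane-Poiseuille profile)
#'
#' Parabolic profile between the channel floor and ceiling,
#' `u(z) = 6 u_mean (z/h)(1 - z/h)` with
#' `u_mean = Q / (channel_height * channel_width)`; no-slip at both walls.
#' The aspect ratio of the channel (250 um wide, 40 um high) makes the
#' parallel-plate profile a good approximation away from the side walls.
#'
#' @param z Height above the electrode plane (m); vectorised.  Must lie in
#'   `[0, channel_height]`.
#' @param flow A [flow_model()].
#' @param geometry A [device_geometry()].
#' @return Axial velocity (m/s).
#' @examples
#' flow_velocity(20e-6, flow_model(), device_geometry())  # ~6.25 mm/s
#' @export
flow_velocity <- function(z, flow, geometry) {
  h <- geometry$channel_height
  if (any(z < 0 | z > h)) stop("z outside the channel [0, channel_height]")
  if (!flow$enabled) return(rep.int(0, length(z)))
  u_mean <- flow$volumetric_rate / (h * geometry$channel_width)
  6 * u_mean * (z / h) * (1 - z / h)
}

#' Overdamped drift velocity from a force (Stokes drag closure)
#'
#' In the overdamped limit a micron-scale particle moves at the terminal
#' velocity `v = F / (6 pi eta R)` set by Stokes drag.
#'
#' @param force Force vector or matrix of row vectors (N).
#' @param cell_radius Particle radius (m), > 0.
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @return Velocity with the same shape as `force` (m/s).
#' @examples
#' drift_velocity(c(1.673e-10, 0, 0), 5e-6, 1e-3)  # ~1.775e-3 m/s
#' @export
drift_velocity <- function(force, cell_radius, viscosity) {
  stopifnot("cell_radius must be > 0" = cell_radius > 0,
            "viscosity must be > 0" = viscosity > 0)
  force / (6 * pi * viscosity * cell_radius)
}

#' Net gravity (weight minus buoyancy) on a spherical particle
#'
#' `F_z = -(4/3) pi R^3 (rho_cell - rho_medium) g`; negative (downward) for
#' a cell denser than the medium.  Under nDEP the vertical DEP force can
#' balance this weight, levitating a trapped cell above the electrode;
#' switching the drive off lets the cell settle onto the surface.
#'
#' @param cell_radius Particle radius (m), > 0.
#' @param cell_density,medium_density Mass densities (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @return Signed z-force (N).
#' @examples
#' gravity_force(5e-6, 1050, 1000)  # ~ -2.57e-13 N
#' @export
gravity_force <- function(cell_radius, cell_density, medium_density,
                          g = 9.81) {
  stopifnot("cell_radius must be > 0" = cell_radius > 0)
  -(4 / 3) * pi * cell_radius^3 * (cell_density - medium_density) * g
}

#' DEP force field over a solved ring-trap potential
#'
#' Builds a vectorised force function for the transport integrator from a
#' field solution and a dielectric context.  The prefactor
#' `2 pi R^3 eps_m Re[f_CM]` is evaluated once at the drive frequency; the
#' spatial factor is the interpolated `grad(E^2_rms)`.  Outside the solved
#' radial domain the far field is taken as zero force.
#'
#' @param solution A `field_solution` (its `drive` sets the frequency).
#' @param cell A [shelled_cell()] or [homogeneous_cell()].
#' @param medium A [dielectric_medium()].
#' @param re_fcm Optional override for the real part of the CM factor
#'   (used by frequency sweeps, which rescale the same field solution).
#' @return A function `f(pos)` mapping an n x 3 matrix of positions
#'   `(x, y, z)` (m) to an n x 3 matrix of DEP forces (N), with attributes
#'   `re_fcm` and `field_on`.
#' @export
trap_force_field <- function(solution, cell, medium, re_fcm = NULL) {
  stopifnot(inherits(solution, "field_solution"), !is.null(solution$e2))
  if (is.null(re_fcm)) {
    re_fcm <- Re(cm_factor_at(cell, medium, solution$drive$frequency))
  }
  pref <- 2 * pi * cell$radius^3 * medium$permittivity * re_fcm
  rmax <- solution$r[length(solution$r)]
  zmin <- solution$z[1]
  zmax <- solution$z[length(solution$z)]
  f <- function(pos) {
    pos <- rbind(pos)
    rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    zq <- pmin(pmax(pos[, 3], zmin), zmax)
    inside <- rho <= rmax
    out <- matrix(0, nrow(pos), 3)
    if (any(inside)) {
      rq <- rho[inside]
      gr <- interp_bilinear(solution$r, solution$z, solution$ge2_r,
                            rq, zq[inside])
      gz <- interp_bilinear(solution$r, solution$z, solution$ge2_z,
                            rq, zq[inside])
      ur <- ifelse(rq > 0, 1 / rq, 0)
      out[inside, 1] <- pref * gr * pos[inside, 1] * ur
      out[inside, 2] <- pref * gr * pos[inside, 2] * ur
      out[inside, 3] <- pref * gz
    }
    out
  }
  attr(f, "re_fcm") <- re_fcm
  attr(f, "field_on") <- pref != 0
  f
}

# Drift-velocity closure combining DEP force, gravity and channel flow.
make_velocity_fn <- function(force_fn, flow, geometry, cell_radius,
                             viscosity, gravity_fz) {
  mob <- 1 / (6 * pi * viscosity * cell_radius)
  h <- geometry$channel_height
  u_mean <- if (!is.null(flow) && flow$enabled) {
    flow$volumetric_rate / (h * geometry$channel_width)
  } else 0
  function(pos) {
    v <- force_fn(pos) * mob
    v[, 3] <- v[, 3] + gravity_fz * mob
    if (u_mean != 0) {
      zf <- pmin(pmax(pos[, 3], 0), h)
      v[, 1] <- v[, 1] + 6 * u_mean * (zf / h) * (1 - zf / h)
    }
    v
  }
}

#' Integrate an ensemble of overdamped particle trajectories
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of
#' `dx/dt = u_flow(z) xhat + (F_DEP + F_gravity) / (6 pi eta R)` for every
#' particle simultaneously.  After each step the height is clamped to
#' `[R, channel_height - R]`: a particle reaching a wall with a
#' wall-directed velocity has the normal component suppressed (it may slide
#' along the wall, never penetrate it).  A particle whose lateral position
#' leaves the simulation box is frozen at its exit state and flagged
#' `exited` (downstream advection).
#'
#' @param positions0 n x 3 matrix of initial positions `(x, y, z)` (m).
#' @param force_fn Force field function as built by [trap_force_field()] or
#'   [linear_trap_oracle()]; set to `NULL` for force-free motion.
#' @param geometry A [device_geometry()].
#' @param cell_radius Particle radius (m).
#' @param viscosity Medium dynamic viscosity (Pa s).
#' @param flow A [flow_model()] or `NULL` (no flow).
#' @param gravity_fz Constant z-directed force (N), e.g. [gravity_force()];
#'   0 disables gravity.
#' @param dt Time step (s), > 0.
#' @param t_end Final time (s); must cover the largest snapshot time.
#' @param snapshot_times Times (s) at which ensemble snapshots are flagged;
#'   each is matched to the nearest recorded step.
#' @param record_every Record every k-th step (k = 1 keeps all steps).
#' @param lateral_extent Half-width of the simulation box in x and y (m);
#'   defaults to the geometry `domain_radius`.
#' @return Object of class `ensemble_trajectories`: `times` (recorded
#'   times), `states` (n x 3 x length(times) array), `final_speed` (m/s,
#'   instantaneous drift speed at the final state), `exited`, `exit_time`,
#'   `snapshot_index` (named by snapshot time), `field_on`, and the inputs.
#' @export
integrate_ensemble <- function(positions0, force_fn, geometry,
                               cell_radius = 5e-6, viscosity = 1e-3,
                               flow = NULL, gravity_fz = 0,
                               dt = 1e-4, t_end = 2,
                               snapshot_times = numeric(),
                               record_every = 1L,
                               lateral_extent = NULL) {
  positions0 <- rbind(positions0)
  stopifnot("dt must be > 0" = dt > 0,
            "t_end must cover all snapshot times" =
              length(snapshot_times) == 0 ||
              t_end >= max(snapshot_times) - 1e-12)
  n <- nrow(positions0)
  h <- geometry$channel_height
  if (n > 0 && any(positions0[, 3] < cell_radius - 1e-12 |
                   positions0[, 3] > h - cell_radius + 1e-12)) {
    stop("initial height violates wall clearance R <= z <= height - R")
  }
  if (is.null(lateral_extent)) lateral_extent <- geometry$domain_radius
  field_on <- !is.null(force_fn) && isTRUE(attr(force_fn, "field_on"))
  if (is.null(force_fn)) {
    force_fn <- function(pos) matrix(0, nrow(pos), 3)
  }
  vel <- make_velocity_fn(force_fn, flow, geometry, cell_radius, viscosity,
                          gravity_fz)
  zlo <- cell_radius; zhi <- h - cell_radius
  nsteps <- max(0L, as.integer(round(t_end / dt)))
  rec_idx <- unique(c(seq(0L, nsteps, by = as.integer(record_every)), nsteps))
  times <- rec_idx * dt
  states <- array(NA_real_, dim = c(n, 3, length(rec_idx)))
  pos <- positions0
  active <- rep(TRUE, n)
  exited <- rep(FALSE, n)
  exit_time <- rep(NA_real_, n)
  rec_ptr <- 1L
  if (length(rec_idx) && rec_idx[1] == 0L) {
    states[, , 1] <- pos
    rec_ptr <- 2L
  }
  if (n == 0) nsteps <- 0L
  step <- 0L
  while (step < nsteps) {
    step <- step + 1L
    if (any(active)) {
      p <- pos[active, , drop = FALSE]
      k1 <- vel(p)
      k2 <- vel(clamp_z(p + dt / 2 * k1, zlo, zhi))
      k3 <- vel(clamp_z(p + dt / 2 * k2, zlo, zhi))
      k4 <- vel(clamp_z(p + dt * k3, zlo, zhi))
      p2 <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p2 <- clamp_z(p2, zlo, zhi)
      pos[active, ] <- p2
      gone <- abs(pos[, 1]) > lateral_extent | abs(pos[, 2]) > lateral_extent
      newly <- gone & active & !exited
      if (any(newly)) {
        exited[newly] <- TRUE
        exit_time[newly] <- step * dt
        active[newly] <- FALSE
      }
    }
    if (rec_ptr <= length(rec_idx) && rec_idx[rec_ptr] == step) {
      states[, , rec_ptr] <- pos
      rec_ptr <- rec_ptr + 1L
    }
  }
  # instantaneous drift speed at the final state, with wall suppression
  if (n > 0) {
    vf <- vel(pos)
    at_floor <- pos[, 3] <= zlo + 1e-12
    at_ceil <- pos[, 3] >= zhi - 1e-12
    vf[at_floor & vf[, 3] < 0, 3] <- 0
    vf[at_ceil & vf[, 3] > 0, 3] <- 0
    final_speed <- sqrt(rowSums(vf^2))
  } else {
    final_speed <- numeric(0)
  }
  snap_idx <- if (length(snapshot_times)) {
    vapply(snapshot_times, function(ts) which.min(abs(times - ts)), 1L)
  } else integer(0)
  structure(list(times = times, states = states,
                 initial = positions0, final = pos,
                 final_speed = final_speed,
                 exited = exited, exit_time = exit_time,
                 snapshot_index = setNames(snap_idx,
                                           as.character(snapshot_times)),
                 snapshot_times = snapshot_times,
                 field_on = field_on,
                 flow_on = !is.null(flow) && flow$enabled,
                 cell_radius = cell_radius, dt = dt, t_end = t_end,
                 geometry = geometry),
            class = "ensemble_trajectories")
}

clamp_z <- function(pos, zlo, zhi) {
  pos[, 3] <- pmin(pmax(pos[, 3], zlo), zhi)
  pos
}

#' Integrate a single particle trajectory
#'
#' Convenience wrapper around [integrate_ensemble()] for one particle.
#'
#' @param initial Numeric length-3 initial position `(x, y, z)` (m).
#' @inheritParams integrate_ensemble
#' @param ... Passed on to [integrate_ensemble()].
#' @return Object of class `trajectory`: data.frame `states` with columns
#'   `t`, `x`, `y`, `z`, plus attributes carried from the ensemble result
#'   (`final_speed`, `exited`, `field_on`, `snapshot_index`, ...).
#' @export
integrate_trajectory <- function(initial, force_fn, geometry, ...) {
  res <- integrate_ensemble(matrix(initial, nrow = 1), force_fn, geometry,
                            ...)
  traj <- data.frame(t = res$times,
                     x = res$states[1, 1, ],
                     y = res$states[1, 2, ],
                     z = res$states[1, 3, ])
  structure(list(states = traj,
                 final_speed = res$final_speed[1],
                 exited = res$exited[1],
                 exit_time = res$exit_time[1],
                 snapshot_index = res$snapshot_index,
                 field_on = res$field_on,
                 flow_on = res$flow_on,
                 cell_radius = res$cell_radius,
                 geometry = res$geometry),
            class = "trajectory")
}

# Shared outcome rule.  Precedence: trapped > advected > repelled > settled.
classify_one <- function(x0, xf, final_speed, exited, field_on, flow_on,
                         geometry, cell_radius) {
  rho_f <- sqrt(xf[1]^2 + xf[2]^2)
  if (rho_f < geometry$ring_inner_radius && final_speed < 1e-6) {
    return("trapped")
  }
  if (exited) return("advected")
  if (xf[3] - x0[3] > 5e-6 && rho_f >= geometry$ring_outer_radius) {
    return("repelled")
  }
  at_floor <- xf[3] <= cell_radius + 1e-9
  if (at_floor && !field_on) return("settled")
  # residual: still in transit with flow, or at rest without a clear label
  if (flow_on) "advected" else "settled"
}

#' Classify the outcome of a trajectory
#'
#' Labels a finished trajectory by the trap physics it displayed:
#' * `trapped` — final lateral distance from the trap axis below the ring
#'   inner radius and final drift speed below 1 um/s (held in the low-field
#'   centre);
#' * `advected` — left the simulation box laterally (carried away
#'   downstream);
#' * `repelled` — rose by more than 5 um while ending at or beyond the ring
#'   outer radius (pushed up and away by the nDEP wall);
#' * `settled` — resting on the channel floor with the drive off, or at
#'   rest without any of the above (residual label).
#'
#' Labels are mutually exclusive with precedence
#' `trapped > advected > repelled > settled`.
#'
#' @param trajectory A `trajectory` from [integrate_trajectory()].
#' @param geometry A [device_geometry()]; defaults to the one stored in the
#'   trajectory.
#' @return A single string label.
#' @export
classify_outcome <- function(trajectory, geometry = trajectory$geometry) {
  stopifnot(inherits(trajectory, "trajectory"))
  st <- trajectory$states
  if (nrow(st) == 0) stop("empty trajectory")
  x0 <- unlist(st[1, c("x", "y", "z")], use.names = FALSE)
  xf <- unlist(st[nrow(st), c("x", "y", "z")], use.names = FALSE)
  classify_one(x0, xf, trajectory$final_speed, trajectory$exited,
               trajectory$field_on, trajectory$flow_on, geometry,
               trajectory$cell_radius)
}

#' Classify every particle of an ensemble result
#'
#' @param ensemble An `ensemble_trajectories` from [integrate_ensemble()].
#' @param geometry A [device_geometry()]; defaults to the stored one.
#' @return Character vector of outcome labels, one per particle.
#' @export
classify_ensemble <- function(ensemble, geometry = ensemble$geometry) {
  stopifnot(inherits(ensemble, "ensemble_trajectories"))
  n <- nrow(ensemble$initial)
  vapply(seq_len(n), function(i) {
    classify_one(ensemble$initial[i, ], ensemble$final[i, ],
                 ensemble$final_speed[i], ensemble$exited[i],
                 ensemble$field_on, ensemble$flow_on, geometry,
                 ensemble$cell_radius)
  }, character(1))
}
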