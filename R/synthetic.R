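# Synthetic inputs: seeded uniform particle ensembles (the simulated
# experiment's "uniform initial distribution"), plus analytic field and
# force oracles used to validate the solver and the integrator.

#' Specification of a uniform random particle ensemble
#'
#' Describes a seeded ensemble of particle centres distributed independently
#' and uniformly over a box inside the channel, emulating a uniform initial
#' suspension.  Generation is a pure function of the spec: the same seed
#' always yields the same ensemble.
#'
#' The default region is the channel cross-section plane shown by the
#' trapping simulation: `x` across the full modelled width, `y = 0` (the
#' reference trajectory simulation is two-dimensional), `z` spanning the
#' channel height minus the particle-radius wall clearance.  Any 3-D box is
#' accepted.
#'
#' @param count Number of particles, >= 0.
#' @param x_range,y_range,z_range Length-2 numeric bounds (m) of the seeding
#'   box.  The z range must respect the wall clearance
#'   `[radius, channel_height - radius]`.
#' @param seed Integer seed for the Mersenne-Twister generator.
#' @param radius Particle radius (m), used for the wall-clearance check.
#' @param channel_height Channel height (m).
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(count = 50,
                          x_range = c(-120e-6, 120e-6),
                          y_range = c(0, 0),
                          z_range = c(5e-6, 35e-6),
                          seed = 42L,
                          radius = 5e-6,
                          channel_height = 40e-6) {
  stopifnot("count must be >= 0" = count >= 0,
            "x_range must be increasing" = diff(x_range) >= 0,
            "y_range must be increasing" = diff(y_range) >= 0,
            "z_range must be increasing" = diff(z_range) >= 0)
  if (z_range[1] < radius - 1e-15 ||
      z_range[2] > channel_height - radius + 1e-15) {
    stop("z_range violates wall clearance [radius, channel_height - radius]")
  }
  structure(list(count = as.integer(count), x_range = x_range,
                 y_range = y_range, z_range = z_range,
                 seed = as.integer(seed), radius = radius,
                 channel_height = channel_height),
            class = "ensemble_spec")
}

# Run fn with a locally seeded Mersenne-Twister; global RNG state restored.
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  fn()
}

#' Draw a uniform particle ensemble
#'
#' @param spec An [ensemble_spec()].
#' @return An n x 3 matrix of positions `(x, y, z)` in metres.
#' @examples
#' gen_uniform_ensemble(ensemble_spec(count = 5, seed = 7))
#' @export
gen_uniform_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$count
  if (n == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  with_local_seed(spec$seed, function() {
    cbind(x = runif(n, spec$x_range[1], spec$x_range[2]),
          y = runif(n, spec$y_range[1], spec$y_range[2]),
          z = runif(n, spec$z_range[1], spec$z_range[2]))
  })
}

#' Analytic parallel-plate field oracle
#'
#' Builds a `field_solution` for the ideal parallel-plate capacitor: uniform
#' field `|E| = V / h` directed along z, zero `grad(E^2)`.  Usable anywhere
#' a solved field is, which makes it a closed-form oracle for the solver and
#' for force-free transport tests.
#'
#' @param voltage Plate voltage difference (V), floor at `voltage`, ceiling
#'   grounded.
#' @param height Plate separation (m), > 0.
#' @param radial_extent Radial extent of the synthetic grid (m).
#' @param spacing Grid spacing (m).
#' @return Object of class `field_solution`.
#' @examples
#' pp <- analytic_parallel_plate(4, 40e-6)
#' sqrt(sample_field(pp, 0, 20e-6)$e2)  # 1e5 V/m
#' @export
analytic_parallel_plate <- function(voltage, height,
                                    radial_extent = 125e-6,
                                    spacing = 5e-6) {
  stopifnot("height must be > 0" = height > 0)
  r <- seq(0, radial_extent, by = spacing)
  z <- seq(0, height, length.out = max(2, round(height / spacing) + 1))
  phi <- outer(rep(1, length(r)), voltage * (1 - z / height))
  ez <- matrix(voltage / height, length(r), length(z))
  zero <- matrix(0, length(r), length(z))
  structure(list(r = r, z = z, phi = phi,
                 er = zero, ez = ez, e2 = ez^2,
                 ge2_r = zero, ge2_z = zero,
                 geometry = NULL,
                 drive = drive_signal(vpp = 2 * sqrt(2) * voltage,
                                      frequency = 1e6),
                 grid = grid_spec(spacing = spacing),
                 electrodes = "parallel_plate",
                 residual = 0, iterations = 0L),
            class = "field_solution")
}

#' Linear restoring-force oracle (harmonic trap)
#'
#' Synthetic force field `F(x) = -k (x - centre)` with closed-form
#' overdamped dynamics: each coordinate relaxes exponentially toward the
#' centre with time constant `tau = 6 pi eta R / k`.  Used to validate the
#' trajectory integrator against an exact solution.
#'
#' @param stiffness Spring constant k (N/m), > 0.
#' @param center Length-3 trap centre (m).
#' @return A force function `f(pos)` (n x 3 in, n x 3 out) with attributes
#'   `stiffness`, `center`, `field_on`, and `closed_form(t, x0, cell_radius,
#'   viscosity)` giving the exact position at time t.
#' @export
linear_trap_oracle <- function(stiffness, center = c(0, 0, 0)) {
  stopifnot("stiffness must be > 0" = stiffness > 0)
  f <- function(pos) {
    pos <- rbind(pos)
    -stiffness * sweep(pos, 2, center)
  }
  attr(f, "stiffness") <- stiffness
  attr(f, "center") <- center
  attr(f, "field_on") <- TRUE
  attr(f, "closed_form") <- function(t, x0, cell_radius, viscosity) {
    tau <- 6 * pi * viscosity * cell_radius / stiffness
    center + (x0 - center) * exp(-t / tau)
  }
  f
}
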