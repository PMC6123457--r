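# Electro-quasistatic field of the ring-shaped trap electrode, solved on a
# uniform axisymmetric (r, z) grid with a conservative 5-point stencil and a
# sparse direct solve.

#' Ring-trap device geometry
#'
#' Geometry of one ring-shaped trap electrode and the microfluidic channel
#' around it.  Defaults: ring internal diameter 40 um and width 20 um (so
#' inner radius 20 um, outer radius 40 um), a 20 um insulating gap to the
#' surrounding grounded counter electrode, a 40 um high, 250 um wide and
#' 3 cm long channel.  The axisymmetric computational domain extends to
#' `domain_radius` (default 125 um, half the channel width).
#'
#' @param ring_inner_radius,ring_outer_radius Driven ring annulus radii (m).
#' @param counter_inner_radius Inner radius of the grounded plane (m).
#' @param domain_radius Outer radius of the computational domain (m).
#' @param channel_height,channel_width,channel_length Channel dimensions (m).
#' @return Object of class `device_geometry`.
#' @export
device_geometry <- function(ring_inner_radius = 20e-6,
                            ring_outer_radius = 40e-6,
                            counter_inner_radius = 60e-6,
                            domain_radius = 125e-6,
                            channel_height = 40e-6,
                            channel_width = 250e-6,
                            channel_length = 3e-2) {
  ok <- 0 < ring_inner_radius && ring_inner_radius < ring_outer_radius &&
    ring_outer_radius < counter_inner_radius &&
    counter_inner_radius < domain_radius
  if (!ok) {
    stop("require 0 < ring_inner_radius < ring_outer_radius < ",
         "counter_inner_radius < domain_radius")
  }
  stopifnot("channel_height must be > 0" = channel_height > 0,
            "channel_width must be > 0" = channel_width > 0,
            "channel_length must be > 0" = channel_length > 0)
  structure(list(ring_inner_radius = ring_inner_radius,
                 ring_outer_radius = ring_outer_radius,
                 counter_inner_radius = counter_inner_radius,
                 domain_radius = domain_radius,
                 channel_height = channel_height,
                 channel_width = channel_width,
                 channel_length = channel_length),
            class = "device_geometry")
}

#' Finite-difference grid specification
#'
#' @param spacing Uniform grid spacing (m).  Must resolve the trap:
#'   [solve_potential()] requires `spacing <= ring_inner_radius / 4`.
#' @param solver_tolerance Relative residual accepted for the discrete
#'   Laplace system.
#' @param max_iterations Maximum iterative-refinement sweeps applied after
#'   the sparse direct solve.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(spacing = 0.5e-6, solver_tolerance = 1e-8,
                      max_iterations = 50) {
  stopifnot("spacing must be > 0" = spacing > 0,
            "solver_tolerance must be > 0" = solver_tolerance > 0,
            "max_iterations must be >= 1" = max_iterations >= 1)
  structure(list(spacing = spacing, solver_tolerance = solver_tolerance,
                 max_iterations = max_iterations),
            class = "grid_spec")
}

# Assemble and solve the axisymmetric Laplace problem
#   (1/r) d/dr (r dphi/dr) + d^2 phi / dz^2 = 0
# on the tensor grid r x z with Dirichlet values where dir_mask is TRUE and
# homogeneous Neumann (mirror ghost) elsewhere, including the axis r = 0.
# Returns list(phi = Nr x Nz matrix, residual, iterations).
solve_axisym_laplace <- function(r, z, dir_mask, dir_val,
                                 tol = 1e-8, max_iter = 50) {
  nr <- length(r); nz <- length(z); n <- nr * nz
  h <- r[2] - r[1]
  i <- rep.int(seq_len(nr), nz)          # r index of node k = (j-1)*nr + i
  j <- rep(seq_len(nz), each = nr)

  rp <- r + h / 2                         # r_{i+1/2}
  rm <- pmax(r - h / 2, 0)                # r_{i-1/2}
  # finite-volume coefficients scaled by h^2 (dimensionless, keeps the
  # assembled matrix well conditioned next to the Dirichlet identity rows);
  # the axis cell uses the regularised stencil
  vol <- r
  vol[1] <- h / 8                         # integral r dr over [0, h/2] / h
  ae <- rp[i] / vol[i]
  aw <- rm[i] / vol[i]
  ae[i == nr] <- 0
  aw[i == 1] <- 0
  # outer radial Neumann boundary: mirrored east neighbour folds into west
  out <- i == nr
  aw[out] <- (rp[nr] + rm[nr]) / r[nr]
  an <- rep.int(1, n)
  as_ <- rep.int(1, n)
  an[j == nz] <- 0; as_[j == 1] <- 0
  an[j == 1] <- 2                         # floor Neumann (where not Dirichlet)
  as_[j == nz] <- 2                       # ceiling Neumann

  dmask <- as.vector(dir_mask)
  dval <- as.vector(dir_val)
  free <- !dmask

  k <- seq_len(n)
  diag_c <- -(ae + aw + an + as_)
  trip_i <- c(k[free],
              k[free & ae > 0], k[free & aw > 0],
              k[free & an > 0], k[free & as_ > 0],
              k[dmask])
  trip_j <- c(k[free],
              k[free & ae > 0] + 1L, k[free & aw > 0] - 1L,
              k[free & an > 0] + nr, k[free & as_ > 0] - nr,
              k[dmask])
  trip_x <- c(diag_c[free],
              ae[free & ae > 0], aw[free & aw > 0],
              an[free & an > 0], as_[free & as_ > 0],
              rep.int(1, sum(dmask)))
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  b <- numeric(n)
  b[dmask] <- dval[dmask]

  x <- as.numeric(Matrix::solve(A, b))
  bs <- max(abs(b), 1)
  res <- max(abs(b - as.numeric(A %*% x))) / bs
  iter <- 0L
  while (res > tol && iter < max_iter) {
    x <- x + as.numeric(Matrix::solve(A, b - as.numeric(A %*% x)))
    res <- max(abs(b - as.numeric(A %*% x))) / bs
    iter <- iter + 1L
  }
  if (res > tol) {
    stop(sprintf("field solver did not converge: residual %.3e > %.3e",
                 res, tol))
  }
  list(phi = matrix(x, nrow = nr, ncol = nz), residual = res,
       iterations = iter)
}

#' Solve the electro-quasistatic potential of the ring trap
#'
#' Solves the axisymmetric Laplace equation
#' `(1/r) d/dr(r dphi/dr) + d^2 phi/dz^2 = 0` in the fluid volume above the
#' electrode plane.  Boundary conditions: the ring annulus
#' (`z = 0`, `ring_inner_radius <= r <= ring_outer_radius`) is held at the
#' rms drive voltage, the counter electrode (`z = 0`,
#' `r >= counter_inner_radius`) at 0 V, and every remaining surface — the
#' insulating gap, the inner disk, the channel ceiling, the outer rim and
#' the symmetry axis — carries a homogeneous Neumann (electrical insulation)
#' condition.  The potential is the rms phasor amplitude, so derived fields
#' are rms quantities.
#'
#' @param geometry A [device_geometry()].
#' @param drive A [drive_signal()]; the ring is held at `drive$vrms`.
#' @param grid A [grid_spec()].
#' @param electrodes `"ring"` for the trap device, or `"parallel_plate"` for
#'   a validation override with the whole floor at `vrms` and the whole
#'   ceiling grounded (closed-form uniform field `vrms / channel_height`).
#' @param gradients If `TRUE` (default), [field_and_gradients()] is applied
#'   before returning.
#' @return Object of class `field_solution`: grid axes `r`, `z`, potential
#'   matrix `phi` (rows index r), rms field components `er`, `ez`, squared
#'   field `e2`, its gradient `ge2_r`, `ge2_z`, plus solver metadata.
#' @examples
#' \donttest{
#' sol <- solve_potential(device_geometry(), drive_signal(),
#'                        grid_spec(spacing = 2e-6))
#' range(sol$phi)
#' }
#' @export
solve_potential <- function(geometry, drive, grid = grid_spec(),
                            electrodes = c("ring", "parallel_plate"),
                            gradients = TRUE) {
  stopifnot(inherits(geometry, "device_geometry"),
            inherits(drive, "drive_signal"),
            inherits(grid, "grid_spec"))
  electrodes <- match.arg(electrodes)
  h <- grid$spacing
  if (h > geometry$ring_inner_radius / 4) {
    stop("grid spacing must be <= ring_inner_radius / 4 to resolve the trap")
  }
  nr <- round(geometry$domain_radius / h)
  nz <- round(geometry$channel_height / h)
  r <- seq(0, by = h, length.out = nr + 1)
  z <- seq(0, by = h, length.out = nz + 1)

  dmask <- matrix(FALSE, nr + 1, nz + 1)
  dval <- matrix(0, nr + 1, nz + 1)
  tol_r <- h * 1e-9
  if (electrodes == "ring") {
    on_ring <- r >= geometry$ring_inner_radius - tol_r &
      r <= geometry$ring_outer_radius + tol_r
    on_counter <- r >= geometry$counter_inner_radius - tol_r
    dmask[on_ring | on_counter, 1] <- TRUE
    dval[on_ring, 1] <- drive$vrms
  } else {
    dmask[, 1] <- TRUE
    dval[, 1] <- drive$vrms
    dmask[, nz + 1] <- TRUE
    dval[, nz + 1] <- 0
  }

  fit <- solve_axisym_laplace(r, z, dmask, dval,
                              tol = grid$solver_tolerance,
                              max_iter = grid$max_iterations)
  sol <- structure(list(r = r, z = z, phi = fit$phi,
                        er = NULL, ez = NULL, e2 = NULL,
                        ge2_r = NULL, ge2_z = NULL,
                        geometry = geometry, drive = drive, grid = grid,
                        electrodes = electrodes,
                        residual = fit$residual,
                        iterations = fit$iterations),
                   class = "field_solution")
  if (gradients) sol <- field_and_gradients(sol) else sol
}

# d/dx along the rows (first margin) of matrix m with uniform spacing h;
# central differences inside, second-order one-sided at the edges.
diff_margin1 <- function(m, h) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  d[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * h)
  d[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * h)
  d
}

#' Derive rms field, squared field and its gradient from the potential
#'
#' Computes `E = -grad(phi)` by central differences (second-order one-sided
#' at boundaries), `E^2 = E_r^2 + E_z^2` and `grad(E^2)` by differencing the
#' squared field again.  Because the potential is the rms phasor amplitude,
#' `e2` is the time-averaged squared field entering the dipolar DEP force.
#'
#' @param solution A `field_solution` with `phi` populated.
#' @return The solution with `er`, `ez`, `e2`, `ge2_r`, `ge2_z` populated.
#' @export
field_and_gradients <- function(solution) {
  stopifnot(inherits(solution, "field_solution"), !is.null(solution$phi))
  h <- solution$r[2] - solution$r[1]
  solution$er <- -diff_margin1(solution$phi, h)
  solution$ez <- -t(diff_margin1(t(solution$phi), h))
  solution$e2 <- solution$er^2 + solution$ez^2
  solution$ge2_r <- diff_margin1(solution$e2, h)
  solution$ge2_z <- t(diff_margin1(t(solution$e2), h))
  solution
}

# Bilinear interpolation of grid matrix m (rows = r, cols = z) at query
# points (rq, zq); exact at nodes.  Vectorised; callers must pre-check the
# domain.
interp_bilinear <- function(rgrid, zgrid, m, rq, zq) {
  h <- rgrid[2] - rgrid[1]
  nr <- length(rgrid); nz <- length(zgrid)
  fi <- pmin(pmax(floor((rq - rgrid[1]) / h) + 1, 1), nr - 1)
  fj <- pmin(pmax(floor((zq - zgrid[1]) / h) + 1, 1), nz - 1)
  tr <- (rq - rgrid[fi]) / h
  tz <- (zq - zgrid[fj]) / h
  k00 <- cbind(fi, fj); k10 <- cbind(fi + 1, fj)
  k01 <- cbind(fi, fj + 1); k11 <- cbind(fi + 1, fj + 1)
  (1 - tr) * (1 - tz) * m[k00] + tr * (1 - tz) * m[k10] +
    (1 - tr) * tz * m[k01] + tr * tz * m[k11]
}

#' Sample the squared field and its gradient at points in the (r, z) plane
#'
#' Bilinear interpolation of the stored `e2` and `grad(E^2)` grids; exact at
#' grid nodes.
#'
#' @param solution A `field_solution` with gradients populated.
#' @param r,z Query coordinates (m); vectors of equal length.  All points
#'   must lie inside the solved domain.
#' @return A list with numeric vectors `e2`, `ge2_r`, `ge2_z`.
#' @export
sample_field <- function(solution, r, z) {
  stopifnot(inherits(solution, "field_solution"), !is.null(solution$e2))
  if (any(r < solution$r[1] | r > solution$r[length(solution$r)] |
          z < solution$z[1] | z > solution$z[length(solution$z)])) {
    stop("sample_field: query point outside the solved domain")
  }
  list(e2 = interp_bilinear(solution$r, solution$z, solution$e2, r, z),
       ge2_r = interp_bilinear(solution$r, solution$z, solution$ge2_r, r, z),
       ge2_z = interp_bilinear(solution$r, solution$z, solution$ge2_z, r, z))
}

#' Time-averaged dipolar DEP force at a point
#'
#' Evaluates `F_DEP = 2 pi R^3 eps_m Re[f_CM] grad(E^2_rms)` at a point of
#' the solved field.  With `re_fcm < 0` (nDEP) the force is antiparallel to
#' the gradient of the squared field, pushing the particle toward field
#' minima.
#'
#' @param r,z Evaluation point (m).
#' @param cell_radius Particle radius R (m).
#' @param medium A [dielectric_medium()] (its absolute permittivity enters
#'   the prefactor).
#' @param re_fcm Real part of the CM factor (dimensionless).
#' @param solution A `field_solution`.
#' @return Numeric vector `c(fr, fz)` in newtons.
#' @examples
#' \donttest{
#' sol <- solve_potential(device_geometry(), drive_signal(),
#'                        grid_spec(spacing = 2e-6))
#' dep_force_at(30e-6, 10e-6, 5e-6, dielectric_medium(), -0.45, sol)
#' }
#' @export
dep_force_at <- function(r, z, cell_radius, medium, re_fcm, solution) {
  s <- sample_field(solution, r, z)
  pref <- 2 * pi * cell_radius^3 * medium$permittivity * re_fcm
  c(fr = pref * s$ge2_r, fz = pref * s$ge2_z)
}

#' Export a field solution as a long-format CSV table
#'
#' One row per grid node with header
#' `r_um,z_um,phi_v,er_vpm,ez_vpm,e2,ge2_r,ge2_z`.
#'
#' @param solution A `field_solution` with gradients populated.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_field_csv <- function(solution, path) {
  stopifnot(inherits(solution, "field_solution"), !is.null(solution$e2))
  grid <- expand.grid(r = solution$r, z = solution$z)
  df <- data.frame(r_um = grid$r * 1e6, z_um = grid$z * 1e6,
                   phi_v = as.vector(solution$phi),
                   er_vpm = as.vector(solution$er),
                   ez_vpm = as.vector(solution$ez),
                   e2 = as.vector(solution$e2),
                   ge2_r = as.vector(solution$ge2_r),
                   ge2_z = as.vector(solution$ge2_z))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> ", x$electrodes, " electrodes, ",
      length(x$r), " x ", length(x$z), " grid (",
      format(x$grid$spacing * 1e6), " um), residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}
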