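# Axisymmetric electro-quasistatic solver: exactness on closed forms,
# convergence order, maximum principle, linearity, symmetry, sampling and
# the dipolar DEP force.

test_that("equal potentials on both electrodes give a constant field", {
  h <- 2e-6
  r <- seq(0, 60e-6, by = h); z <- seq(0, 20e-6, by = h)
  dm <- matrix(FALSE, length(r), length(z))
  dm[r >= 10e-6 & r <= 20e-6, 1] <- TRUE   # "ring"
  dm[r >= 40e-6, 1] <- TRUE                # "counter"
  dv <- matrix(0, length(r), length(z))
  dv[dm] <- 3                              # same 3 V everywhere
  fit <- deptrap:::solve_axisym_laplace(r, z, dm, dv, tol = 1e-10)
  expect_equal(max(abs(fit$phi - 3)), 0, tolerance = 1e-10)
})

test_that("parallel-plate override reproduces the capacitor field exactly", {
  geo <- device_geometry()
  drv <- drive_signal()
  pp <- solve_potential(geo, drv, grid_spec(spacing = 2e-6),
                        electrodes = "parallel_plate")
  e_exact <- drv$vrms / geo$channel_height
  expect_lt(max(abs(sqrt(pp$e2) - e_exact)) / e_exact, 1e-3)
  # the potential is linear in z and independent of r
  expect_equal(pp$phi[5, ], drv$vrms * (1 - pp$z / geo$channel_height),
               tolerance = 1e-10)
  expect_equal(max(abs(pp$ge2_r)), 0, tolerance = 1e-4 * e_exact^2)
})

test_that("solver converges at second order on a quartic harmonic", {
  # phi = z^4 - 3 z^2 r^2 + 3/8 r^4 solves the axisymmetric Laplace
  # equation and, unlike linear/quadratic solutions, is not reproduced
  # exactly by the stencil, so it exposes the truncation error
  exact <- function(r, z) outer(r, z, function(R, Z) Z^4 - 3 * Z^2 * R^2 +
                                  3 / 8 * R^4)
  err_at <- function(h) {
    r <- seq(0, 1, by = h); z <- seq(0, 1, by = h)
    dm <- matrix(FALSE, length(r), length(z))
    dm[1, ] <- TRUE; dm[length(r), ] <- TRUE
    dm[, 1] <- TRUE; dm[, length(z)] <- TRUE
    fit <- deptrap:::solve_axisym_laplace(r, z, dm, exact(r, z), tol = 1e-10)
    max(abs(fit$phi - exact(r, z)))
  }
  ratio <- err_at(1 / 16) / err_at(1 / 32)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("solved potential obeys the discrete maximum principle", {
  sol <- coarse_solution()
  expect_gte(min(sol$phi), 0 - 1e-12)
  expect_lte(max(sol$phi), sol$drive$vrms + 1e-12)
  expect_lt(sol$residual, sol$grid$solver_tolerance)
})

test_that("field scales linearly with voltage, e2 with its square", {
  sol1 <- coarse_solution()
  sol2 <- solve_potential(device_geometry(), drive_signal(vpp = 16),
                          grid_spec(spacing = 2e-6))
  expect_equal(sol2$phi, 2 * sol1$phi, tolerance = 1e-10)
  expect_equal(sol2$e2, 4 * sol1$e2, tolerance = 1e-10)
  expect_equal(sol2$ge2_r, 4 * sol1$ge2_r, tolerance = 1e-10)
})

test_that("swapping electrode potentials maps phi to vrms - phi", {
  geo <- device_geometry(); drv <- drive_signal()
  h <- 2e-6
  nr <- round(geo$domain_radius / h); nz <- round(geo$channel_height / h)
  r <- seq(0, by = h, length.out = nr + 1)
  z <- seq(0, by = h, length.out = nz + 1)
  dm <- matrix(FALSE, nr + 1, nz + 1)
  on_ring <- r >= geo$ring_inner_radius - 1e-12 &
    r <= geo$ring_outer_radius + 1e-12
  on_counter <- r >= geo$counter_inner_radius - 1e-12
  dm[on_ring | on_counter, 1] <- TRUE
  dv <- matrix(0, nr + 1, nz + 1); dv[on_ring, 1] <- drv$vrms
  dv_sw <- matrix(0, nr + 1, nz + 1); dv_sw[on_counter, 1] <- drv$vrms
  a <- deptrap:::solve_axisym_laplace(r, z, dm, dv, tol = 1e-10)
  b <- deptrap:::solve_axisym_laplace(r, z, dm, dv_sw, tol = 1e-10)
  expect_equal(b$phi, drv$vrms - a$phi, tolerance = 1e-9)
})

test_that("gradients of a quadratic harmonic potential are exact", {
  # phi = a (z^2 - r^2/2) is harmonic; E and grad(E^2) have closed forms
  # that central differences reproduce to rounding on a uniform grid
  a <- 2.5e9
  h <- 1e-6
  r <- seq(0, 40e-6, by = h); z <- seq(0, 20e-6, by = h)
  sol <- structure(list(r = r, z = z,
                        phi = outer(r, z, function(R, Z) a * (Z^2 - R^2 / 2)),
                        geometry = NULL, drive = drive_signal(),
                        grid = grid_spec(spacing = h),
                        electrodes = "synthetic", residual = 0,
                        iterations = 0L),
                   class = "field_solution")
  sol <- field_and_gradients(sol)
  er_exact <- outer(r, z, function(R, Z) a * R)
  ez_exact <- outer(r, z, function(R, Z) -2 * a * Z)
  expect_equal(sol$er, er_exact, tolerance = 1e-10)
  expect_equal(sol$ez, ez_exact, tolerance = 1e-10)
  e2_exact <- er_exact^2 + ez_exact^2
  expect_equal(sol$e2, e2_exact, tolerance = 1e-10)
  # grad(E^2) = (2 a^2 r, 8 a^2 z): quadratic, still exact for the stencil
  expect_equal(sol$ge2_r, outer(r, z, function(R, Z) 2 * a^2 * R),
               tolerance = 1e-8)
  expect_equal(sol$ge2_z, outer(r, z, function(R, Z) 8 * a^2 * Z),
               tolerance = 1e-8)
})

test_that("bilinear sampling is exact at nodes and linear in between", {
  sol <- coarse_solution()
  # node exactness
  i <- c(3L, 20L, 40L); j <- c(2L, 5L, 9L)
  s <- sample_field(sol, sol$r[i], sol$z[j])
  expect_identical(s$e2, sol$e2[cbind(i, j)])
  expect_identical(s$ge2_r, sol$ge2_r[cbind(i, j)])
  # midpoint of a cell equals the average of its four corners
  rq <- (sol$r[10] + sol$r[11]) / 2; zq <- (sol$z[4] + sol$z[5]) / 2
  expect_equal(sample_field(sol, rq, zq)$e2,
               mean(sol$e2[10:11, 4:5]), tolerance = 1e-12)
  # random interior points against an independently coded bilinear formula
  set.seed(99)
  rq <- runif(50, 0, max(sol$r)); zq <- runif(50, 0, max(sol$z))
  h <- sol$r[2] - sol$r[1]
  oracle <- vapply(seq_along(rq), function(k) {
    i <- min(max(floor(rq[k] / h) + 1, 1), length(sol$r) - 1)
    j <- min(max(floor(zq[k] / h) + 1, 1), length(sol$z) - 1)
    u <- (rq[k] - sol$r[i]) / h; v <- (zq[k] - sol$z[j]) / h
    sol$e2[i, j] * (1 - u) * (1 - v) + sol$e2[i + 1, j] * u * (1 - v) +
      sol$e2[i, j + 1] * (1 - u) * v + sol$e2[i + 1, j + 1] * u * v
  }, numeric(1))
  got <- sample_field(sol, rq, zq)$e2
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(sample_field(sol, 200e-6, 1e-6), "outside")
  expect_error(sample_field(sol, 10e-6, -1e-6), "outside")
})

test_that("DEP force follows the dipolar formula and its scalings", {
  # synthetic solution with a uniform grad(E^2) so the force is pure
  # arithmetic: F = 2 pi R^3 eps_m Re[f_CM] * grad(E^2)
  h <- 5e-6
  r <- seq(0, 50e-6, by = h); z <- seq(0, 20e-6, by = h)
  zero <- matrix(0, length(r), length(z))
  sol <- structure(list(r = r, z = z, phi = zero, er = zero, ez = zero,
                        e2 = zero, ge2_r = zero + 1e15, ge2_z = zero,
                        geometry = NULL, drive = drive_signal(),
                        grid = grid_spec(spacing = h),
                        electrodes = "synthetic", residual = 0,
                        iterations = 0L),
                   class = "field_solution")
  med <- dielectric_medium()  # eps_m = 7.1e-10 F/m
  f <- dep_force_at(10e-6, 10e-6, 5e-6, med, -0.3, sol)
  oracle <- 2 * pi * (5e-6)^3 * 7.1e-10 * (-0.3) * 1e15
  expect_equal(unname(f[1]), oracle, tolerance = 1e-12)
  expect_equal(abs(oracle), 1.673e-10, tolerance = 1e-3)
  expect_equal(unname(f[2]), 0)
  # R^3 scaling: doubling the radius multiplies the force by 8
  f2 <- dep_force_at(10e-6, 10e-6, 10e-6, med, -0.3, sol)
  expect_equal(unname(f2[1]), 8 * unname(f[1]), tolerance = 1e-12)
  # nDEP force is antiparallel to grad(E^2)
  expect_lt(unname(f[1]) * 1e15, 0)
  # zero gradient -> zero force
  sol0 <- sol; sol0$ge2_r <- zero
  expect_equal(unname(dep_force_at(10e-6, 10e-6, 5e-6, med, -0.3, sol0)),
               c(0, 0))
})

test_that("ring-trap field has its trap-zone minimum on the axis and its
           maximum at the ring edge", {
  sol <- solve_potential(device_geometry(), drive_signal(),
                         grid_spec(spacing = 1e-6))
  r <- sol$r
  s <- sample_field(sol, r, rep(2.5e-6, length(r)))
  trap_zone <- r <= sol$geometry$counter_inner_radius
  expect_equal(r[trap_zone][which.min(s$e2[trap_zone])], 0)
  rmax <- r[which.max(s$e2)]
  expect_gte(rmax, 40e-6 - 1e-9)
  expect_lte(rmax, 60e-6 + 1e-9)
})

test_that("field CSV export writes the documented long-format header", {
  sol <- coarse_solution()
  path <- withr::local_tempfile(fileext = ".csv")
  export_field_csv(sol, path)
  expect_identical(readLines(path, n = 1),
                   "r_um,z_um,phi_v,er_vpm,ez_vpm,e2,ge2_r,ge2_z")
  expect_identical(length(readLines(path)) - 1L,
                   length(sol$r) * length(sol$z))
})
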