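# Frequency-domain dielectric response: complex permittivity, CM factor,
# single-shell reduction, crossover frequency.

test_that("complex permittivity combines dielectric and conductive response", {
  w <- 2 * pi * 1e7
  e <- complex_permittivity(7.1e-10, 0.75, w)
  expect_equal(Re(e), 7.1e-10)
  expect_equal(Im(e), -0.75 / w)
  expect_equal(Im(e), -1.1936620732e-8, tolerance = 1e-9)

  # zero conductivity: purely real; high-frequency limit: loss term vanishes
  expect_equal(complex_permittivity(3e-10, 0, w), complex(real = 3e-10))
  expect_lt(abs(Im(complex_permittivity(3e-10, 1, 1e18))), 1e-17)
  expect_error(complex_permittivity(3e-10, 1, 0), "angular_frequency")
  expect_error(complex_permittivity(3e-10, 1, -5), "angular_frequency")
})

test_that("CM factor hits its analytic limits", {
  em <- complex(real = 7.1e-10, imaginary = -2e-8)
  expect_equal(cm_factor(em, em), 0 + 0i)
  # highly polarizable particle -> +1; vanishing particle response -> -0.5
  expect_equal(Re(cm_factor(em * 1e9, em)), 1, tolerance = 1e-8)
  expect_equal(Re(cm_factor(em * 1e-12, em)), -0.5, tolerance = 1e-8)
  expect_error(cm_factor(-2 * em, em), "denominator")
})

test_that("CM factor low- and high-frequency limits match closed forms", {
  cell <- homogeneous_cell(permittivity = 50 * EPS0, conductivity = 0.2)
  med <- dielectric_medium(permittivity = 78 * EPS0, conductivity = 1.2)
  lo <- (cell$conductivity - med$conductivity) /
    (cell$conductivity + 2 * med$conductivity)
  hi <- (cell$permittivity - med$permittivity) /
    (cell$permittivity + 2 * med$permittivity)
  expect_equal(Re(cm_factor_at(cell, med, 1e-7)), lo, tolerance = 1e-6)
  expect_equal(Re(cm_factor_at(cell, med, 1e17)), hi, tolerance = 1e-6)
})

test_that("single-shell reduction collapses to the cytoplasm in both limits", {
  w <- 2 * pi * 1e6
  # degenerate shell: membrane identical to cytoplasm
  same <- shelled_cell(membrane_permittivity = 7.1e-10,
                       membrane_conductivity = 0.75)
  expect_equal(effective_cell_permittivity(same, w),
               complex_permittivity(7.1e-10, 0.75, w), tolerance = 1e-12)
  # vanishing shell
  thin <- shelled_cell(membrane_thickness = 1e-15)
  expect_equal(effective_cell_permittivity(thin, w),
               complex_permittivity(7.1e-10, 0.75, w), tolerance = 1e-6)
})

test_that("single-shell effective permittivity matches the frozen oracle", {
  # independent brute-force evaluation of the shell formula (complex
  # arithmetic coded separately), frozen at 10 MHz with the default
  # neuronal parameters and a 5 nm membrane
  e <- effective_cell_permittivity(shelled_cell(), 2 * pi * 1e7)
  expect_equal(Re(e), 1.743151233429e-09, tolerance = 1e-9)
  expect_equal(Im(e), -2.611413685276e-10, tolerance = 1e-9)
})

test_that("effective permittivity is continuous in every parameter", {
  w <- 2 * pi * 1e7
  base <- list(radius = 5e-6, membrane_thickness = 5e-9,
               membrane_permittivity = 1.8e-12, membrane_conductivity = 1e-7,
               cytoplasm_permittivity = 7.1e-10,
               cytoplasm_conductivity = 0.75)
  e0 <- effective_cell_permittivity(do.call(shelled_cell, base), w)
  for (p in names(base)) {
    pert <- base
    pert[[p]] <- pert[[p]] * (1 + 1e-9)
    e1 <- effective_cell_permittivity(do.call(shelled_cell, pert), w)
    expect_lt(abs(e1 - e0) / abs(e0), 1e-6)
  }
})

test_that("CM spectrum table is structural and sign-correct", {
  cell <- shelled_cell()
  med <- dielectric_medium()
  expect_identical(nrow(re_cm_spectrum(cell, med, numeric(0))), 0L)

  f <- 10^seq(3, 9, length.out = 41)
  sp <- re_cm_spectrum(cell, med, f)
  expect_identical(names(sp), c("frequency_hz", "re_fcm", "im_fcm"))
  expect_identical(nrow(sp), 41L)
  expect_identical(sp$frequency_hz, f)
  expect_false(is.unsorted(sp$frequency_hz))
  expect_true(all(sp$re_fcm >= -0.5 - 1e-12 & sp$re_fcm <= 1 + 1e-12))

  # particle dielectrically identical to the medium: no contrast
  twin <- homogeneous_cell(permittivity = med$permittivity,
                           conductivity = med$conductivity)
  expect_equal(re_cm_spectrum(twin, med, 1e7)$re_fcm, 0)

  # operating point of the device: nDEP with the default cell and medium
  at10 <- re_cm_spectrum(cell, med, 1e7)
  expect_lt(at10$re_fcm, 0)
  expect_equal(at10$re_fcm, -0.488302802658, tolerance = 1e-9)
})

test_that("CM factor real part stays within [-0.5, 1] for physical inputs", {
  set.seed(11)
  f <- 10^seq(3, 9, length.out = 50)
  for (k in 1:30) {
    cell <- homogeneous_cell(
      permittivity = runif(1, 1, 100) * EPS0,
      conductivity = 10^runif(1, -7, 1))
    med <- dielectric_medium(
      permittivity = runif(1, 1, 100) * EPS0,
      conductivity = 10^runif(1, -7, 1))
    re <- re_cm_spectrum(cell, med, f)$re_fcm
    expect_gte(min(re), -0.5 - 1e-12)
    expect_lte(max(re), 1 + 1e-12)
  }
  # the shelled model obeys the same bound
  for (k in 1:10) {
    cell <- shelled_cell(
      membrane_thickness = runif(1, 2e-9, 20e-9),
      membrane_permittivity = runif(1, 1, 20) * EPS0,
      membrane_conductivity = 10^runif(1, -8, -4),
      cytoplasm_permittivity = runif(1, 40, 100) * EPS0,
      cytoplasm_conductivity = runif(1, 0.1, 2))
    med <- dielectric_medium(permittivity = runif(1, 40, 100) * EPS0,
                             conductivity = runif(1, 0.01, 2))
    re <- re_cm_spectrum(cell, med, f)$re_fcm
    expect_gte(min(re), -0.5 - 1e-12)
    expect_lte(max(re), 1 + 1e-12)
  }
})

test_that("crossover frequency matches a dense scan and has small residual", {
  # conductivity contrast favours pDEP at low f, permittivity contrast
  # favours nDEP at high f: exactly one crossover in a wide bracket
  cell <- homogeneous_cell(permittivity = 80 * EPS0, conductivity = 0.1)
  med <- dielectric_medium(permittivity = 60 * EPS0, conductivity = 0.5)
  f <- crossover_frequency(cell, med, 1e3, 1e9)

  lf <- seq(3, 9, length.out = 1e5)
  re <- Re(cm_factor_at(cell, med, 10^lf))
  k <- which(re[-1] * re[-length(re)] <= 0)
  expect_length(k, 1)
  dense <- 10^mean(lf[c(k, k + 1)])
  expect_equal(f, dense, tolerance = 1e-4)
  expect_lt(abs(Re(cm_factor_at(cell, med, f))), 1e-9)

  # no sign change on the bracket -> none
  expect_true(is.na(crossover_frequency(shelled_cell(), dielectric_medium(),
                                        1e6, 1e7)))
  expect_error(crossover_frequency(cell, med, 1e6, 1e3), "f_low")
})

test_that("spectrum CSV round-trips through the documented header", {
  sp <- re_cm_spectrum(shelled_cell(), dielectric_medium(), c(1e6, 1e7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  expect_identical(readLines(path, n = 1), "frequency_hz,re_fcm,im_fcm")
  back <- read.csv(path)
  expect_equal(back$re_fcm, sp$re_fcm, tolerance = 1e-12)
})
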