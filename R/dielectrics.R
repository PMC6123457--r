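# Frequency-domain dielectric response: complex permittivities, the
# Clausius-Mossotti (CM) factor, the single-shell cell model and crossover
# frequencies.  All permittivities are ABSOLUTE (F/m); conductivities S/m.

#' Suspending-medium dielectric and hydrodynamic properties
#'
#' Describes the fluid in which cells are suspended: its absolute
#' permittivity and conductivity (which set the medium complex permittivity
#' entering the CM factor) plus the viscosity and density used by the
#' transport module.
#'
#' Defaults describe a physiological cell-culture medium: permittivity
#' 7.1e-10 F/m (about 80 relative), conductivity 1.5 S/m (typical of
#' neuronal culture media), viscosity 1e-3 Pa s and density 1000 kg/m^3.
#'
#' @param permittivity Absolute permittivity (F/m), > 0.
#' @param conductivity Conductivity (S/m), >= 0.
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @param density Mass density (kg/m^3), > 0.
#' @return An object of class `dielectric_medium`.
#' @examples
#' m <- dielectric_medium()
#' m$conductivity
#' @export
dielectric_medium <- function(permittivity = 7.1e-10, conductivity = 1.5,
                              viscosity = 1.0e-3, density = 1000) {
  stopifnot(
    "permittivity must be > 0" = is.numeric(permittivity) && permittivity > 0,
    "conductivity must be >= 0" = is.numeric(conductivity) && conductivity >= 0,
    "viscosity must be > 0" = is.numeric(viscosity) && viscosity > 0,
    "density must be > 0" = is.numeric(density) && density > 0
  )
  structure(list(permittivity = permittivity, conductivity = conductivity,
                 viscosity = viscosity, density = density),
            class = "dielectric_medium")
}

#' Homogeneous spherical particle model
#'
#' A cell (or bead) modelled as a uniform dielectric sphere.  Useful for
#' sensitivity studies; the default cell model for trap simulations is the
#' single-shell [shelled_cell()].
#'
#' @param radius Particle radius (m), > 0.
#' @param permittivity Absolute permittivity (F/m), > 0.  A relative
#'   permittivity `er` converts as `er * EPS0`.
#' @param conductivity Conductivity (S/m), >= 0.
#' @param density Particle mass density (kg/m^3), > 0.
#' @return An object of class `homogeneous_cell`.
#' @examples
#' homogeneous_cell(radius = 5e-6, permittivity = 80 * EPS0, conductivity = 0.5)
#' @export
homogeneous_cell <- function(radius = 5e-6, permittivity = 80 * EPS0,
                             conductivity = 0.5, density = 1050) {
  stopifnot(
    "radius must be > 0" = is.numeric(radius) && radius > 0,
    "permittivity must be > 0" = is.numeric(permittivity) && permittivity > 0,
    "conductivity must be >= 0" = is.numeric(conductivity) && conductivity >= 0,
    "density must be > 0" = is.numeric(density) && density > 0
  )
  structure(list(radius = radius, permittivity = permittivity,
                 conductivity = conductivity, density = density),
            class = "homogeneous_cell")
}

#' Single-shell cell model (cytoplasm sphere coated by a thin membrane)
#'
#' A biological cell modelled as a conductive cytoplasm sphere surrounded by
#' a thin, poorly conducting membrane.  The shell collapses to an equivalent
#' homogeneous sphere via [effective_cell_permittivity()] before entering
#' the CM factor.
#'
#' Defaults are the neuronal-cell parameters used throughout the package:
#' outer radius 5 um, cytoplasm permittivity 7.1e-10 F/m and conductivity
#' 0.75 S/m, membrane permittivity 1.8e-12 F/m and conductivity 1e-7 S/m.
#' The membrane thickness defaults to 5 nm (a typical lipid bilayer).
#'
#' @param radius Outer radius including the membrane (m).
#' @param membrane_thickness Membrane thickness (m), in (0, radius).
#' @param membrane_permittivity,membrane_conductivity Membrane absolute
#'   permittivity (F/m) and conductivity (S/m).
#' @param cytoplasm_permittivity,cytoplasm_conductivity Cytoplasm absolute
#'   permittivity (F/m) and conductivity (S/m).
#' @param density Cell mass density (kg/m^3).
#' @return An object of class `shelled_cell`.
#' @examples
#' shelled_cell()
#' @export
shelled_cell <- function(radius = 5e-6, membrane_thickness = 5e-9,
                         membrane_permittivity = 1.8e-12,
                         membrane_conductivity = 1e-7,
                         cytoplasm_permittivity = 7.1e-10,
                         cytoplasm_conductivity = 0.75,
                         density = 1050) {
  stopifnot(
    "radius must be > 0" = is.numeric(radius) && radius > 0,
    "membrane_thickness must be in (0, radius)" =
      is.numeric(membrane_thickness) && membrane_thickness > 0 &&
      membrane_thickness < radius,
    "membrane_permittivity must be > 0" = membrane_permittivity > 0,
    "membrane_conductivity must be >= 0" = membrane_conductivity >= 0,
    "cytoplasm_permittivity must be > 0" = cytoplasm_permittivity > 0,
    "cytoplasm_conductivity must be >= 0" = cytoplasm_conductivity >= 0,
    "density must be > 0" = density > 0
  )
  structure(list(radius = radius, membrane_thickness = membrane_thickness,
                 membrane_permittivity = membrane_permittivity,
                 membrane_conductivity = membrane_conductivity,
                 cytoplasm_permittivity = cytoplasm_permittivity,
                 cytoplasm_conductivity = cytoplasm_conductivity,
                 density = density),
            class = "shelled_cell")
}

#' Sinusoidal AC drive signal
#'
#' @param vpp Peak-to-peak voltage (V), >= 0.
#' @param frequency Frequency (Hz), > 0.
#' @return Object of class `drive_signal` with derived fields `amplitude`
#'   (= vpp/2), `vrms` (= vpp / (2 sqrt(2))) and `omega` (= 2 pi frequency).
#' @examples
#' d <- drive_signal(vpp = 8, frequency = 10e6)
#' d$vrms     # 2.828 V
#' @export
drive_signal <- function(vpp = 8, frequency = 10e6) {
  stopifnot(
    "vpp must be >= 0" = is.numeric(vpp) && vpp >= 0,
    "frequency must be > 0" = is.numeric(frequency) && frequency > 0
  )
  structure(list(vpp = vpp, frequency = frequency,
                 amplitude = vpp / 2, vrms = vpp / (2 * sqrt(2)),
                 omega = 2 * pi * frequency),
            class = "drive_signal")
}

#' Complex permittivity at a given angular frequency
#'
#' Combines dielectric and conductive response into the complex permittivity
#' `eps* = eps - j sigma / omega`.
#'
#' @param permittivity Absolute permittivity (F/m).
#' @param conductivity Conductivity (S/m).
#' @param angular_frequency Angular frequency omega (rad/s), > 0.  Vectorised.
#' @return Complex permittivity (F/m), complex vector.
#' @examples
#' complex_permittivity(7.1e-10, 0.75, 2 * pi * 1e7)
#' @export
complex_permittivity <- function(permittivity, conductivity, angular_frequency) {
  if (!is.numeric(angular_frequency) || any(angular_frequency <= 0)) {
    stop("angular_frequency must be > 0")
  }
  complex(real = permittivity, imaginary = -conductivity / angular_frequency)
}

#' Clausius-Mossotti factor of a sphere in a medium
#'
#' The frequency-dependent effective polarizability of a homogeneous sphere,
#' `f_CM = (eps*_p - eps*_m) / (eps*_p + 2 eps*_m)`.  Its real part lies in
#' `[-0.5, 1]` for physical inputs and sets the direction of the DEP force:
#' positive means attraction toward field-intensity maxima (pDEP), negative
#' means motion toward field minima (nDEP).
#'
#' @param particle_eps_star Complex permittivity of the particle (F/m).
#' @param medium_eps_star Complex permittivity of the medium (F/m).
#' @return Complex CM factor (dimensionless).  Vectorised.
#' @examples
#' w <- 2 * pi * 1e7
#' cm_factor(complex_permittivity(7.1e-10, 0.75, w),
#'           complex_permittivity(7.1e-10, 1.5, w))
#' @export
cm_factor <- function(particle_eps_star, medium_eps_star) {
  den <- particle_eps_star + 2 * medium_eps_star
  scale <- Mod(particle_eps_star) + 2 * Mod(medium_eps_star)
  if (any(Mod(den) <= 1e-14 * scale)) {
    stop("cm_factor: denominator eps*_p + 2 eps*_m vanishes")
  }
  (particle_eps_star - medium_eps_star) / den
}

#' Equivalent homogeneous complex permittivity of a shelled cell
#'
#' Collapses the single-shell model (cytoplasm sphere of radius `R - d`
#' coated by a membrane of thickness `d`) into one equivalent homogeneous
#' sphere using the radius-ratio-cubed Maxwell-Garnett reduction:
#' \deqn{\varepsilon^*_{eff} = \varepsilon^*_{mem}
#'   \frac{\gamma^3 + 2A}{\gamma^3 - A}, \quad
#'   \gamma = \frac{R}{R-d}, \quad
#'   A = \frac{\varepsilon^*_{cyt} - \varepsilon^*_{mem}}
#'            {\varepsilon^*_{cyt} + 2\varepsilon^*_{mem}}.}
#' The result feeds [cm_factor()] directly.
#'
#' @param cell A [shelled_cell()].
#' @param angular_frequency Angular frequency (rad/s), > 0.  Vectorised.
#' @return Complex permittivity (F/m).
#' @examples
#' effective_cell_permittivity(shelled_cell(), 2 * pi * 1e7)
#' @export
effective_cell_permittivity <- function(cell, angular_frequency) {
  stopifnot(inherits(cell, "shelled_cell"))
  if (cell$membrane_thickness >= cell$radius) {
    stop("membrane_thickness must be smaller than the cell radius")
  }
  e_cyt <- complex_permittivity(cell$cytoplasm_permittivity,
                                cell$cytoplasm_conductivity, angular_frequency)
  e_mem <- complex_permittivity(cell$membrane_permittivity,
                                cell$membrane_conductivity, angular_frequency)
  g3 <- (cell$radius / (cell$radius - cell$membrane_thickness))^3
  a <- (e_cyt - e_mem) / (e_cyt + 2 * e_mem)
  e_mem * (g3 + 2 * a) / (g3 - a)
}

# Complex particle permittivity for either supported cell model.
particle_eps_star <- function(cell, angular_frequency) {
  if (inherits(cell, "shelled_cell")) {
    effective_cell_permittivity(cell, angular_frequency)
  } else if (inherits(cell, "homogeneous_cell")) {
    complex_permittivity(cell$permittivity, cell$conductivity,
                         angular_frequency)
  } else {
    stop("cell must be a shelled_cell or homogeneous_cell")
  }
}

#' CM factor of a cell/medium pair at one or more frequencies
#'
#' @param cell A [shelled_cell()] or [homogeneous_cell()].
#' @param medium A [dielectric_medium()].
#' @param frequency Frequency in Hz (not angular), > 0.  Vectorised.
#' @return Complex CM factor.
#' @export
cm_factor_at <- function(cell, medium, frequency) {
  if (length(frequency) && (!is.numeric(frequency) || any(frequency <= 0))) {
    stop("frequency must be > 0")
  }
  w <- 2 * pi * frequency
  cm_factor(particle_eps_star(cell, w),
            complex_permittivity(medium$permittivity, medium$conductivity, w))
}

#' CM-factor spectrum over a frequency grid
#'
#' Evaluates the real and imaginary parts of the CM factor for a cell in a
#' medium across a list of frequencies.  The sign of `re_fcm` at the drive
#' frequency decides the trapping regime: negative (nDEP) pushes cells into
#' the low-field centre of a ring trap; positive (pDEP) pulls them onto
#' electrode edges.
#'
#' @inheritParams cm_factor_at
#' @param frequencies Numeric vector of frequencies (Hz), all > 0.  An empty
#'   vector yields an empty table.
#' @return A data.frame with columns `frequency_hz`, `re_fcm`, `im_fcm`.
#' @examples
#' re_cm_spectrum(shelled_cell(), dielectric_medium(), 10^seq(4, 9, by = 1))
#' @export
re_cm_spectrum <- function(cell, medium, frequencies) {
  if (length(frequencies) == 0) {
    return(data.frame(frequency_hz = numeric(0), re_fcm = numeric(0),
                      im_fcm = numeric(0)))
  }
  fcm <- cm_factor_at(cell, medium, frequencies)
  data.frame(frequency_hz = as.numeric(frequencies),
             re_fcm = Re(fcm), im_fcm = Im(fcm))
}

#' Write a CM spectrum table to CSV
#'
#' @param spectrum Data.frame from [re_cm_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(all(c("frequency_hz", "re_fcm", "im_fcm") %in% names(spectrum)))
  write.csv(spectrum, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' DEP crossover frequency (sign change of Re[f_CM])
#'
#' Finds the frequency in `[f_low, f_high]` where the real part of the CM
#' factor changes sign, separating the pDEP and nDEP regimes.  Uses
#' bisection/Brent root finding on the log-frequency axis with relative
#' tolerance 1e-6.
#'
#' @inheritParams cm_factor_at
#' @param f_low,f_high Bracket in Hz, `0 < f_low < f_high`.
#' @return The crossover frequency (Hz), or `NA_real_` if `Re[f_CM]` does
#'   not change sign on the bracket.
#' @export
crossover_frequency <- function(cell, medium, f_low = 1e3, f_high = 1e9) {
  if (!is.numeric(f_low) || !is.numeric(f_high) || f_low <= 0 ||
      f_low >= f_high) {
    stop("require 0 < f_low < f_high")
  }
  g <- function(lf) Re(cm_factor_at(cell, medium, 10^lf))
  lo <- log10(f_low); hi <- log10(f_high)
  glo <- g(lo); ghi <- g(hi)
  if (glo == 0) return(f_low)
  if (ghi == 0) return(f_high)
  if (sign(glo) == sign(ghi)) {
    # scan for an interior sign change (Re[f_CM] may be non-monotone)
    lf <- seq(lo, hi, length.out = 257)
    gv <- g(lf)
    k <- which(gv[-1] * gv[-length(gv)] <= 0)
    if (length(k) == 0) return(NA_real_)
    lo <- lf[k[1]]; hi <- lf[k[1] + 1]
  }
  root <- uniroot(g, c(lo, hi), tol = 1e-6 / log(10) / 4)$root
  f <- 10^root
  # polish on the linear axis to the stated relative tolerance
  uniroot(function(x) Re(cm_factor_at(cell, medium, x)),
          c(f * (1 - 1e-4), f * (1 + 1e-4)), tol = f * 1e-13,
          extendInt = "yes")$root
}
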