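---
title: "Modelling single-cell trapping by negative dielectrophoresis on ring microelectrodes"
author: "deptrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-cell trapping by negative dielectrophoresis on ring microelectrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deptrap)
```

## The physical problem

Dielectrophoresis (DEP) is the translation of a polarizable particle in a
spatially non-uniform AC electric field.  Ring-shaped microelectrodes
driven against a surrounding grounded plane create a local minimum of the
field intensity at the ring centre; a cell that is *less* polarizable than
its suspending medium experiences **negative DEP** (nDEP) and is pushed
into that minimum, where it can be held against flow, released, and
cultured in place.  `deptrap` simulates this device physics end to end:
the frequency-dependent dielectric response of the cell, the
electro-quasistatic field of the ring trap, and the overdamped motion of
cell-sized particles in the microchannel.

## Dielectric model

The time-averaged dipolar DEP force on a sphere of radius $R$ is

$$\vec F_{DEP} = 2\pi R^3 \varepsilon_m\, \mathrm{Re}[f_{CM}(\omega)]\,
  \nabla \vec E_{rms}^2 ,$$

with the Clausius–Mossotti factor

$$f_{CM}(\omega) =
  \frac{\varepsilon_p^* - \varepsilon_m^*}
       {\varepsilon_p^* + 2\varepsilon_m^*},
\qquad
 \varepsilon^* = \varepsilon - j\,\sigma/\omega .$$

$\mathrm{Re}[f_{CM}]$ is bounded in $[-1/2, 1]$ for any physical
permittivities and conductivities; its sign separates pDEP (attraction to
field maxima) from nDEP (expulsion toward minima).  Both bounds are
exercised by property tests over randomized parameter sets, and the
package's acceptance script recomputes them from scratch.

A biological cell is modelled as a conductive cytoplasm sphere coated by a
thin, nearly insulating membrane.  `effective_cell_permittivity()`
collapses this single-shell structure into an equivalent homogeneous
sphere with the radius-ratio-cubed reduction

$$\varepsilon^*_{eff} = \varepsilon^*_{mem}\,
  \frac{\gamma^3 + 2A}{\gamma^3 - A},\qquad
  \gamma = \frac{R}{R - d},\qquad
  A = \frac{\varepsilon^*_{cyt}-\varepsilon^*_{mem}}
           {\varepsilon^*_{cyt}+2\varepsilon^*_{mem}},$$

which then enters $f_{CM}$ like any homogeneous particle.  A plain
homogeneous sphere model (relative permittivity 80 by default) is kept
alongside for sensitivity studies.

```{r}
re_cm_spectrum(shelled_cell(), dielectric_medium(),
               c(1e5, 1e6, 1e7, 1e8))
```

At the 10 MHz operating point the default cell/medium pair gives
$\mathrm{Re}[f_{CM}] \approx -0.49$, deep in the nDEP regime, which is why
`load_config()` refuses (by default) configurations that drift into pDEP.

### Parameters and defaults

| parameter | default | why |
|---|---|---|
| cell radius | 5 µm | nominal size of the trapped cells |
| cytoplasm $\varepsilon$, $\sigma$ | 7.1e-10 F/m, 0.75 S/m | neuronal cytoplasm values used by the device model |
| membrane $\varepsilon$, $\sigma$ | 1.8e-12 F/m, 1e-7 S/m | lipid-bilayer shell |
| membrane thickness $d$ | 5 nm | typical bilayer thickness; not fixed by the device description, configurable |
| medium $\varepsilon$ | 7.1e-10 F/m | aqueous culture medium (≈ 80 relative) |
| medium $\sigma$ | 1.5 S/m | typical neuronal culture media; not fixed by the device description, configurable.  Must keep the operating point in nDEP |
| drive | 8 Vpp, 10 MHz | device operating signal; $V_{rms} = V_{pp}/(2\sqrt2)$ |
| viscosity, densities | 1e-3 Pa·s, 1000/1050 kg/m³ | water-like medium, slightly denser cell |

All permittivities in the programming interface are **absolute** (F/m).
The medium permittivity is treated as absolute throughout: the value
7.1e-10 F/m carries the units of an absolute permittivity and Eq. above is
only dimensionally consistent with that reading.

## Field solver

The drive wavelength at 10 MHz is metres; the device is tens of
micrometres, so the electro-quasistatic approximation holds and the
potential obeys Laplace's equation.  With a single ring electrode the
geometry is cylindrically symmetric and the problem reduces to the
axisymmetric form

$$\frac1r \partial_r ( r\, \partial_r \varphi ) + \partial_z^2 \varphi = 0$$

on the rectangle $0 \le r \le 125\,\mu m$ (half the channel width),
$0 \le z \le 40\,\mu m$ (channel height).  Boundary conditions: the ring
annulus ($z=0$, $20 \le r \le 40\,\mu m$) is a Dirichlet strip at
$V_{rms}$, the grounded plane ($z=0$, $r \ge 60\,\mu m$) at $0$; the
inner disk, the 20 µm gap, the ceiling, the outer rim and the axis are
insulating (homogeneous Neumann).  Electrodes are modelled as
infinitesimally thin (the 250 nm conductor thickness is three orders of
magnitude below the channel height); a single ring is solved and
cross-coupling between neighbouring traps in the array is neglected.

Numerics:

* conservative finite-volume 5-point stencil on a uniform grid
  (default spacing 0.5 µm, i.e. 251 × 81 nodes), with the regularized
  axis cell at $r=0$ and mirror ghosts for Neumann sides;
* the stencil rows are scaled by $h^2$ so the assembled sparse matrix is
  well conditioned next to the unit Dirichlet rows, then solved directly
  (sparse LU via `Matrix`), with iterative refinement until the relative
  residual is below `solver_tolerance` (default 1e-8; the direct solve
  already reaches ~1e-14);
* $E = -\nabla\varphi$ and $\nabla E^2$ by central differences
  (second-order one-sided at boundaries).  Because $\varphi$ is the rms
  phasor amplitude, $E^2$ is the time-averaged squared field of the force
  law.

The solver is verified against closed forms: a parallel-plate override
(floor at $V_{rms}$, ceiling grounded) whose uniform field the stencil
reproduces to rounding, and a degree-4 axisymmetric harmonic
$\varphi = z^4 - 3z^2r^2 + \tfrac38 r^4$, which is *not* in the stencil's
null space and exposes the expected second-order convergence (error ratio
≈ 4 when the spacing is halved).  The linear parallel-plate solution
cannot serve as a convergence oracle precisely because the stencil solves
it exactly.

Two facts about the solved topology matter for trapping:

* on horizontal planes near the floor, $E^2$ restricted to the **trap
  zone** ($r \le 60\,\mu m$, the ring plus gap) attains its minimum at
  the axis $r=0$ and its maximum at the ring's outer edge in the gap;
* far above the grounded counter electrode ($r \gtrsim 100\,\mu m$) the
  field decays below the trap-centre value.  The global minimum over the
  whole cross-section therefore sits at the far outer rim, not at the
  trap centre; the trap-centre minimum is the statement that holds within
  the region the reference field map actually displays, and it is the one
  the trapping dynamics depend on.

The electrode edges carry the usual field singularity of a thin Dirichlet
strip; the grid regularizes it.  Particles never probe it: their centres
stay at least one radius (5 µm) above the floor, where the interpolated
field is smooth.

## Transport model

At the micron scale the particle Reynolds number is
$\mathrm{Re}_p = \rho u R/\eta \sim 10^{-5}$ and the inertial relaxation
time $m/(6\pi\eta R) \sim 3\,\mu s$ is far below any trajectory timescale,
so motion is overdamped: velocity is mobility times force,

$$\frac{d\vec x}{dt} = u_{flow}(z)\,\hat x +
  \frac{\vec F_{DEP} + \vec F_g}{6\pi\eta R}.$$

* **Flow**: plane-Poiseuille profile
  $u(z) = 6\,u_{mean}\,(z/h)(1-z/h)$ with
  $u_{mean} = Q/(hw)$; for $Q = 2.5\,\mu L/min$ in the 40 µm × 250 µm
  channel, $u_{mean} \approx 4.17$ mm/s and the centreline moves at
  6.25 mm/s.  The wide, flat channel (aspect 6.25:1) makes the
  parallel-plate profile a good approximation away from the side walls.
* **Gravity**: optional buoyant weight
  $F_z = -\tfrac43\pi R^3(\rho_c-\rho_m)g \approx -0.26$ pN for the
  default densities.
* **Integration**: classical fixed-step RK4 (default $dt = 10^{-4}$ s),
  validated against the exponential closed form of a linear restoring
  force to 1e-6 relative and showing the expected ~16× error drop per dt
  halving.  The step keeps sub-micrometre displacements at the largest
  drift speeds that occur at particle height (~mm/s).
* **Walls**: after each step the height is clamped to
  $[R,\, h-R]$ — a particle reaching a wall slides along it; it never
  penetrates, and wall-directed velocity is suppressed when reporting the
  final drift speed.  Hydrodynamic wall corrections to the drag (Faxén
  terms) are deliberately omitted as a model simplification.

With flow and gravity off, the nDEP force is the (negative) gradient of
$E^2$ up to a positive mobility factor, so $E^2$ evaluated along a
trajectory is a Lyapunov function: it decreases monotonically until the
particle rests in a field minimum.  The test suite asserts this discrete
descent property step by step on the reference ensemble.

Outcomes are classified per trajectory with precedence
`trapped > advected > repelled > settled`: *trapped* means ending within
the ring inner radius at a drift speed below 1 µm/s; *advected* means
leaving the simulation box laterally; *repelled* means rising more than
5 µm while ending at or beyond the ring outer radius; *settled* covers
floor contact with the drive off and any residual case (a particle still
in transit is counted `advected` when flow is on, `settled` otherwise,
since the four labels are not exhaustive mid-experiment).

## The reference trapping scenario

The packaged configuration (`inst/extdata/paper_defaults.yaml`, identical
to `load_config()` with no file) reproduces the device's simulated
trapping demonstration: 8 Vpp at 10 MHz, 5 µm single-shell cells, 50
particles seeded uniformly, snapshots at 0.3, 1 and 2 s, flow off.

Two generator decisions deserve explanation:

* **Seeding region.**  The reference trajectory simulation is a
  two-dimensional cross-section: particles are seeded uniformly over the
  $(x, z)$ plane, $x \in [-120, 120]\,\mu m$, $z \in [5, 35]\,\mu m$
  (one radius of wall clearance), $y = 0$.  The bounds keep all particles
  inside the modelled axisymmetric cell, where the field is defined; the
  generator accepts any 3-D box for other studies.
* **Gravity off.**  The reference trajectories show outer particles
  rising monotonically and staying levitated — dynamics without
  sedimentation — so the reproduction scenario disables the gravity term.
  It is available (`gravity: enabled: true`) and produces the
  settle-on-release behaviour used when cells are plated for culture
  after the drive is switched off.

With these defaults every particle starting inside the ring
(lateral distance < 20 µm) below mid-channel ends trapped on the axis by
2 s, and every particle starting beyond the grounded-plane edge
(> 60 µm) is pushed upward — the trap/repel dichotomy that makes the
device selective.

```{r, eval = FALSE}
res <- run_trap_experiment(load_config())
res$counts
#>  trapped repelled advected  settled
#>       17        6        0       27
```

(The 27 "settled" particles here are slow outer particles that rose by
less than the 5 µm the `repelled` label requires — over the grounded
plane far from the gap the repulsive force is weak.)

Frequency sweeps reuse the single field solve: the force law factorizes
into $\mathrm{Re}[f_{CM}]$ times a geometry-only field factor, so only
the dielectric prefactor changes with frequency while geometry and
voltage are fixed.  This factorization is asserted exactly in the tests.

## Problem sizes and runtime choices

The shipped configuration solves 251 × 81 nodes (0.5 µm spacing) in
about a second and integrates 50 particles for 2 s at $dt = 10^{-4}$ s
(20 000 RK4 steps, states recorded every 10 steps) in a few seconds.
Unit tests run on 2 µm grids and smaller ensembles; the full-resolution
scenario is exercised once in the acceptance suite.

## What the synthetic data does and does not show

The generator reproduces the *conditions* of the reference simulation —
uniform seeding, ideal geometry, noiseless dielectric parameters.  It
does not emulate Brownian motion (for a 5 µm sphere the DEP drift
dominates diffusion by orders of magnitude at these field gradients, but
near the trap centre thermal jitter would blur the final position),
particle–particle dipolar interactions, cell size/property dispersion,
electrode polarization layers, or AC electro-osmotic and electrothermal
flows.  Passing tests therefore demonstrate the correctness of the
implemented model, not quantitative agreement with live-cell behaviour in
a real device.

## Known limitations

* Single ring, axisymmetric: no multi-trap coupling, no relay sequencing
  between neighbouring electrodes.
* Dipole-order DEP force only; no higher multipoles, valid while the
  particle is small compared to the field's variation scale.
* Thin-electrode idealization; dielectric passivation layers are not in
  the solve.
* One-layer shell model; no frequency dependence of the intrinsic
  material parameters.
* Fixed-step integrator; no adaptive error control (the validated fixed
  step is small relative to every timescale in the problem).
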