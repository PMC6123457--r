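# Shared fixtures: coarse grids keep unit tests fast; the full-resolution
# solve lives only in the acceptance suite.  Everything is generated in
# code, nothing is read from disk except the packaged fixture config.

.fixtures <- new.env(parent = emptyenv())

# Ring-trap field on a 2 um grid, solved once per test run.
coarse_solution <- function() {
  if (is.null(.fixtures$coarse_sol)) {
    .fixtures$coarse_sol <- solve_potential(
      device_geometry(), drive_signal(), grid_spec(spacing = 2e-6))
  }
  .fixtures$coarse_sol
}

# Default experiment config with laboratory-unit overrides applied.
test_config <- function(...) {
  load_config(overrides = list(...))
}

# Coarse, short version of the default trapping scenario.
coarse_config <- function(count = 10, t_end = 0.5, seed = 42, ...) {
  test_config(grid = list(spacing_um = 2),
              ensemble = list(count = count, seed = seed),
              integration = list(t_end_s = t_end,
                                 snapshot_times_s = c(0.1, t_end)),
              ...)
}
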