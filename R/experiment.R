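# Experiment runner: solve the trap field once, integrate a seeded particle
# ensemble, classify outcomes, capture snapshots and export CSV artifacts
# with a checksummed manifest.

OUTCOME_LEVELS <- c("trapped", "repelled", "advected", "settled")

#' Run a complete trap experiment
#'
#' Executes one declarative trapping simulation: solves the ring-trap
#' potential once, evaluates the CM factor at the drive frequency, builds
#' the DEP force field, draws the seeded uniform ensemble, integrates every
#' particle, classifies outcomes and captures ensemble snapshots.  The run
#' is bit-reproducible for a fixed configuration and seed.
#'
#' @param config A `trap_experiment_config` from [load_config()].
#' @param solution Optional pre-solved `field_solution` for this geometry
#'   and drive (reused by sweeps); solved on demand when `NULL`.
#' @param re_fcm Optional override of the real CM factor (sweeps rescale
#'   the shared field solution this way).
#' @return Object of class `trap_experiment_result` with elements
#'   `solution`, `ensemble` (the `ensemble_trajectories`), `outcomes`,
#'   `counts` (named integer vector over
#'   trapped/repelled/advected/settled), `snapshots` (list of n x 3
#'   matrices keyed by snapshot time), `re_fcm`, and `provenance` (config
#'   hash, seed, package version, timestamp).
#' @examples
#' \donttest{
#' cfg <- load_config()
#' cfg$raw$grid$spacing_um <- 2            # coarse demo grid
#' cfg$raw$ensemble$count <- 8
#' cfg <- deptrap:::as_trap_experiment_config(cfg$raw)
#' res <- run_trap_experiment(cfg)
#' res$counts
#' }
#' @export
run_trap_experiment <- function(config, solution = NULL, re_fcm = NULL) {
  stopifnot(inherits(config, "trap_experiment_config"))
  if (is.null(solution)) {
    solution <- solve_potential(config$geometry, config$drive, config$grid)
  }
  force_fn <- trap_force_field(solution, config$cell, config$medium,
                               re_fcm = re_fcm)
  positions0 <- gen_uniform_ensemble(config$ensemble)
  gravity_fz <- if (isTRUE(config$gravity$enabled)) {
    gravity_force(config$cell$radius, config$cell$density,
                  config$medium$density, g = config$gravity$g_m_per_s2)
  } else 0
  ens <- integrate_ensemble(
    positions0, force_fn, config$geometry,
    cell_radius = config$cell$radius,
    viscosity = config$medium$viscosity,
    flow = config$flow, gravity_fz = gravity_fz,
    dt = config$integration$dt_s,
    t_end = config$integration$t_end_s,
    snapshot_times = config$integration$snapshot_times_s,
    record_every = config$integration$record_every
  )
  outcomes <- classify_ensemble(ens, config$geometry)
  counts <- table(factor(outcomes, levels = OUTCOME_LEVELS))
  counts <- setNames(as.integer(counts), names(counts))
  snapshots <- lapply(ens$snapshot_index, function(k) ens$states[, , k,
                                                                 drop = TRUE])
  snapshots <- lapply(snapshots, function(s) {
    s <- rbind(s)
    colnames(s) <- c("x", "y", "z")
    s
  })
  structure(list(solution = solution, ensemble = ens,
                 outcomes = outcomes, counts = counts,
                 snapshots = snapshots,
                 re_fcm = attr(force_fn, "re_fcm"),
                 config = config,
                 provenance = list(config_hash = config$hash,
                                   seed = config$ensemble$seed,
                                   solver_iterations = solution$iterations,
                                   package_version =
                                     as.character(utils::packageVersion("deptrap")),
                                   timestamp = format(Sys.time(),
                                                      "%Y-%m-%dT%H:%M:%S%z"))),
            class = "trap_experiment_result")
}

#' @export
print.trap_experiment_result <- function(x, ...) {
  cat("<trap_experiment_result> n = ", length(x$outcomes),
      ", Re[f_CM] = ", format(x$re_fcm, digits = 4), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Frequency sweep of trapping outcomes
#'
#' Runs one full trap experiment per frequency with a shared seed.  Because
#' the dipolar DEP force factorises into a dielectric prefactor
#' (`Re[f_CM]`) and a purely geometric field factor (`grad(E^2_rms)`), the
#' Laplace problem is solved once and rescaled per frequency through the CM
#' factor.
#'
#' @param config A `trap_experiment_config`.
#' @param frequencies Non-empty numeric vector of drive frequencies (Hz).
#' @return Data.frame with one row per frequency: `frequency_hz`, `re_fcm`,
#'   `trapped`, `repelled`, `advected`, `settled`.
#' @export
frequency_sweep <- function(config, frequencies) {
  stopifnot(inherits(config, "trap_experiment_config"),
            "frequencies must be non-empty" = length(frequencies) > 0,
            "frequencies must be > 0" = all(frequencies > 0))
  solution <- solve_potential(config$geometry, config$drive, config$grid)
  rows <- lapply(frequencies, function(f) {
    re_fcm <- Re(cm_factor_at(config$cell, config$medium, f))
    res <- run_trap_experiment(config, solution = solution, re_fcm = re_fcm)
    data.frame(frequency_hz = f, re_fcm = re_fcm,
               trapped = res$counts[["trapped"]],
               repelled = res$counts[["repelled"]],
               advected = res$counts[["advected"]],
               settled = res$counts[["settled"]])
  })
  do.call(rbind, rows)
}

#' Export trajectory records as CSV
#'
#' Long-format table with header `particle_id,t_s,x_um,y_um,z_um,outcome`;
#' one row per particle per recorded time.  Identical simulations write
#' byte-identical files.
#'
#' @param result A `trap_experiment_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectories_csv <- function(result, path) {
  stopifnot(inherits(result, "trap_experiment_result"))
  ens <- result$ensemble
  n <- dim(ens$states)[1]
  nt <- length(ens$times)
  df <- data.frame(
    particle_id = rep(seq_len(n), each = nt),
    t_s = rep(ens$times, times = n),
    x_um = as.vector(t(ens$states[, 1, , drop = FALSE][, 1, ])) * 1e6,
    y_um = as.vector(t(ens$states[, 2, , drop = FALSE][, 1, ])) * 1e6,
    z_um = as.vector(t(ens$states[, 3, , drop = FALSE][, 1, ])) * 1e6,
    outcome = rep(result$outcomes, each = nt)
  )
  if (n == 0) df <- df[0, ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all artifacts of an experiment to a directory
#'
#' Emits `trajectories.csv`, `field.csv`, `outcomes.csv` and a
#' `manifest.json` listing every file with its md5 checksum alongside the
#' provenance record.
#'
#' @param result A `trap_experiment_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
export_experiment <- function(result, out_dir) {
  stopifnot(inherits(result, "trap_experiment_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trajectories = file.path(out_dir, "trajectories.csv"),
             field = file.path(out_dir, "field.csv"),
             outcomes = file.path(out_dir, "outcomes.csv"))
  export_trajectories_csv(result, paths[["trajectories"]])
  export_field_csv(result$solution, paths[["field"]])
  oc <- data.frame(particle_id = seq_along(result$outcomes),
                   outcome = result$outcomes)
  write.csv(oc, paths[["outcomes"]], row.names = FALSE, quote = FALSE)
  manifest <- list(
    files = lapply(seq_along(paths), function(i) {
      list(name = basename(paths[[i]]),
           md5 = unname(tools::md5sum(paths[[i]])))
    }),
    counts = as.list(result$counts),
    re_fcm = result$re_fcm,
    provenance = result$provenance
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
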