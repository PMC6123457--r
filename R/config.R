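# Declarative experiment configuration: laboratory-unit structured-text
# files (YAML or JSON), validated fast with field-path messages and
# converted to SI exactly once at load.

#' Default experiment configuration (laboratory units)
#'
#' The configuration that reproduces the reference trapping simulation:
#' 8 Vpp at 10 MHz on a ring electrode of 40 um internal diameter and
#' 20 um width with a 20 um gap to the grounded plane, a 40 um x 250 um x
#' 3 cm channel, a 5 um-radius single-shell cell in culture medium, a
#' 2.5 uL/min flow model (disabled for the trajectory scenario), 50
#' uniformly seeded particles and snapshots at 0.3, 1 and 2 s.
#'
#' @return A nested list of laboratory-unit values, the same structure a
#'   YAML configuration file uses.
#' @export
default_config <- function() {
  list(
    geometry = list(
      ring_inner_radius_um = 20, ring_outer_radius_um = 40,
      counter_inner_radius_um = 60, domain_radius_um = 125,
      channel_height_um = 40, channel_width_um = 250,
      channel_length_mm = 30
    ),
    drive = list(vpp = 8, frequency_mhz = 10),
    medium = list(
      permittivity_f_per_m = 7.1e-10, conductivity_s_per_m = 1.5,
      viscosity_pa_s = 1.0e-3, density_kg_per_m3 = 1000
    ),
    cell = list(
      model = "shelled", radius_um = 5,
      membrane_thickness_nm = 5,
      membrane_permittivity_f_per_m = 1.8e-12,
      membrane_conductivity_s_per_m = 1.0e-7,
      cytoplasm_permittivity_f_per_m = 7.1e-10,
      cytoplasm_conductivity_s_per_m = 0.75,
      relative_permittivity = 80, conductivity_s_per_m = 0.5,
      density_kg_per_m3 = 1050
    ),
    flow = list(enabled = FALSE, volumetric_rate_ul_min = 2.5),
    grid = list(spacing_um = 0.5, solver_tolerance = 1e-8,
                max_iterations = 50),
    integration = list(dt_s = 1e-4, t_end_s = 2,
                       snapshot_times_s = c(0.3, 1, 2),
                       record_every = 10),
    ensemble = list(count = 50, seed = 42,
                    x_range_um = c(-120, 120), y_range_um = c(0, 0),
                    z_range_um = c(5, 35)),
    gravity = list(enabled = FALSE, g_m_per_s2 = 9.81),
    require_ndep = TRUE
  )
}

# Recursive merge of user values over defaults; unknown keys error with
# their dotted path.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, extra[1]), collapse = "."), collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
  }
  defaults
}

check_field <- function(ok, path, why) {
  if (!isTRUE(ok)) stop("invalid configuration: `", path, "` ", why)
}

validate_raw_config <- function(cfg) {
  g <- cfg$geometry
  check_field(g$ring_inner_radius_um > 0, "geometry.ring_inner_radius_um",
              "must be > 0")
  check_field(g$ring_outer_radius_um > g$ring_inner_radius_um,
              "geometry.ring_outer_radius_um",
              "must exceed ring_inner_radius_um")
  check_field(g$counter_inner_radius_um > g$ring_outer_radius_um,
              "geometry.counter_inner_radius_um",
              "must exceed ring_outer_radius_um")
  check_field(g$domain_radius_um > g$counter_inner_radius_um,
              "geometry.domain_radius_um",
              "must exceed counter_inner_radius_um")
  check_field(g$channel_height_um > 0, "geometry.channel_height_um",
              "must be > 0")
  check_field(cfg$drive$vpp >= 0, "drive.vpp", "must be >= 0")
  check_field(cfg$drive$frequency_mhz > 0, "drive.frequency_mhz",
              "must be > 0")
  check_field(cfg$medium$permittivity_f_per_m > 0,
              "medium.permittivity_f_per_m", "must be > 0")
  check_field(cfg$medium$conductivity_s_per_m >= 0,
              "medium.conductivity_s_per_m", "must be >= 0")
  check_field(cfg$medium$viscosity_pa_s > 0, "medium.viscosity_pa_s",
              "must be > 0")
  check_field(cfg$cell$model %in% c("shelled", "homogeneous"), "cell.model",
              "must be \"shelled\" or \"homogeneous\"")
  check_field(cfg$cell$radius_um > 0, "cell.radius_um", "must be > 0")
  check_field(cfg$flow$volumetric_rate_ul_min >= 0,
              "flow.volumetric_rate_ul_min", "must be >= 0")
  check_field(cfg$grid$spacing_um > 0, "grid.spacing_um", "must be > 0")
  check_field(cfg$integration$dt_s > 0, "integration.dt_s", "must be > 0")
  check_field(cfg$integration$t_end_s >=
                max(c(0, cfg$integration$snapshot_times_s)),
              "integration.t_end_s", "must cover all snapshot times")
  check_field(cfg$ensemble$count >= 0, "ensemble.count", "must be >= 0")
  invisible(cfg)
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration file, overlays it on
#' [default_config()], rejects unknown keys (so typos never pass silently),
#' validates every invariant with a field-path message, and converts all
#' laboratory units (um, nm, mm, MHz, uL/min) to SI exactly once.
#'
#' When `require_ndep` is `TRUE` (the default) the loaded dielectric
#' context must give `Re[f_CM] < 0` at the drive frequency: the trapping
#' principle is negative DEP, and a configuration that silently flips into
#' the pDEP regime would pull cells onto electrode edges instead of the
#' trap centre.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   pure defaults.  An empty file also yields the defaults.
#' @param overrides Optional nested list of laboratory-unit values merged
#'   over the file (or defaults), validated by the same rules.  Convenient
#'   for programmatic studies, e.g.
#'   `load_config(overrides = list(drive = list(vpp = 4)))`.
#' @return Object of class `trap_experiment_config` with SI components:
#'   `geometry` ([device_geometry()]), `drive` ([drive_signal()]), `medium`
#'   ([dielectric_medium()]), `cell` ([shelled_cell()] or
#'   [homogeneous_cell()]), `flow` ([flow_model()]), `grid`
#'   ([grid_spec()]), `integration`, `ensemble` ([ensemble_spec()]),
#'   `gravity`, `raw` (the merged laboratory-unit list) and `hash`.
#' @examples
#' cfg <- load_config()
#' cfg$flow$volumetric_rate    # 4.1667e-11 m^3/s
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  raw <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    raw <- merge_config(raw, user)
  }
  if (!is.null(overrides)) raw <- merge_config(raw, overrides)
  validate_raw_config(raw)
  as_trap_experiment_config(raw)
}

# Build the SI config object from a validated laboratory-unit list.
as_trap_experiment_config <- function(raw) {
  um <- 1e-6
  geometry <- device_geometry(
    ring_inner_radius = raw$geometry$ring_inner_radius_um * um,
    ring_outer_radius = raw$geometry$ring_outer_radius_um * um,
    counter_inner_radius = raw$geometry$counter_inner_radius_um * um,
    domain_radius = raw$geometry$domain_radius_um * um,
    channel_height = raw$geometry$channel_height_um * um,
    channel_width = raw$geometry$channel_width_um * um,
    channel_length = raw$geometry$channel_length_mm * 1e-3
  )
  drive <- drive_signal(vpp = raw$drive$vpp,
                        frequency = raw$drive$frequency_mhz * 1e6)
  medium <- dielectric_medium(
    permittivity = raw$medium$permittivity_f_per_m,
    conductivity = raw$medium$conductivity_s_per_m,
    viscosity = raw$medium$viscosity_pa_s,
    density = raw$medium$density_kg_per_m3
  )
  cell <- if (raw$cell$model == "shelled") {
    shelled_cell(
      radius = raw$cell$radius_um * um,
      membrane_thickness = raw$cell$membrane_thickness_nm * 1e-9,
      membrane_permittivity = raw$cell$membrane_permittivity_f_per_m,
      membrane_conductivity = raw$cell$membrane_conductivity_s_per_m,
      cytoplasm_permittivity = raw$cell$cytoplasm_permittivity_f_per_m,
      cytoplasm_conductivity = raw$cell$cytoplasm_conductivity_s_per_m,
      density = raw$cell$density_kg_per_m3
    )
  } else {
    homogeneous_cell(
      radius = raw$cell$radius_um * um,
      permittivity = raw$cell$relative_permittivity * EPS0,
      conductivity = raw$cell$conductivity_s_per_m,
      density = raw$cell$density_kg_per_m3
    )
  }
  flow <- flow_model(
    volumetric_rate = raw$flow$volumetric_rate_ul_min * 1e-9 / 60,
    enabled = isTRUE(raw$flow$enabled)
  )
  grid <- grid_spec(spacing = raw$grid$spacing_um * um,
                    solver_tolerance = raw$grid$solver_tolerance,
                    max_iterations = raw$grid$max_iterations)
  ensemble <- ensemble_spec(
    count = raw$ensemble$count,
    x_range = raw$ensemble$x_range_um * um,
    y_range = raw$ensemble$y_range_um * um,
    z_range = raw$ensemble$z_range_um * um,
    seed = raw$ensemble$seed,
    radius = cell$radius,
    channel_height = geometry$channel_height
  )
  if (isTRUE(raw$require_ndep) && drive$vpp > 0) {
    re_fcm <- Re(cm_factor_at(cell, medium, drive$frequency))
    if (re_fcm >= 0) {
      stop("configuration yields Re[f_CM] = ", format(re_fcm, digits = 4),
           " >= 0 at the drive frequency: the device traps by negative ",
           "DEP; set `require_ndep: false` to study the pDEP regime")
    }
  }
  structure(list(geometry = geometry, drive = drive, medium = medium,
                 cell = cell, flow = flow, grid = grid,
                 integration = raw$integration,
                 ensemble = ensemble,
                 gravity = raw$gravity,
                 raw = raw,
                 hash = config_hash(raw)),
            class = "trap_experiment_config")
}

# Deterministic md5 of the canonical YAML rendering of the raw config.
# Integers are promoted to double first so `count: 50` hashes the same
# whether it came from YAML (integer) or from default_config() (double).
config_hash <- function(raw) {
  canon <- rapply(raw, as.numeric, classes = "integer", how = "replace")
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(canon, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.trap_experiment_config <- function(x, ...) {
  cat("<trap_experiment_config> ", x$raw$cell$model, " cell R = ",
      x$raw$cell$radius_um, " um, ", x$drive$vpp, " Vpp @ ",
      x$raw$drive$frequency_mhz, " MHz, ensemble n = ", x$ensemble$count,
      ", flow ", if (x$flow$enabled) "on" else "off",
      ", hash ", substr(x$hash, 1, 8), "\n", sep = "")
  invisible(x)
}
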