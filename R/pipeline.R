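#' Default run configuration
#'
#' The full configuration tree used by the pipeline runners, with one block
#' per model ingredient: `beam` (uniform barbule section for modal
#' analysis), `barbule` and `barb` (tapered cantilevers for static
#' deflection), `load` (air pressure), `excitation` (tip force and phase)
#' and `generator` (synthetic feather distributions). Values are SI. A
#' YAML file with the same structure can override any subset; flags passed
#' to the runners override both.
#'
#' @return A named list (class `run_config`).
#' @examples
#' str(default_run_config(), max.level = 1)
#' @export
default_run_config <- function() {
  gen <- generator_config()
  structure(list(
    n_modes = 6L,
    seed = 1L,
    beam = list(
      length_l = 350e-6, young_E = 2.5e9, density_rho = 1150,
      section_area = 2e-10, inertia_Iz = 1.666667e-21
    ),
    barbule = list(
      length_l = 350e-6, root_thickness_t = 10e-6, width_w = 20e-6,
      young_E = 2.5e9
    ),
    barb = list(
      length_l = 20e-3, root_thickness_t = 250e-6, width_w = 500e-6,
      young_E = 2.5e9
    ),
    load = list(
      bird_mass_m = 0.35, gravity_g = 9.81, wing_body_area_A = 0.065
    ),
    excitation = list(tip_force_F = 1e-6, phase_phi = pi / 2),
    generator = unclass(gen)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Reads a YAML mapping and merges it over [default_run_config()]: any
#' block or field present in the file replaces the default, anything
#' absent keeps its default. `NULL` reads the defaults unchanged.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (!is.list(user)) {
    stop("config file must contain a YAML mapping", call. = FALSE)
  }
  structure(modify_list_deep(unclass(cfg), user), class = "run_config")
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

require_block <- function(config, block, fields) {
  blk <- config[[block]]
  if (is.null(blk)) {
    stop(sprintf("config is missing the '%s' block", block), call. = FALSE)
  }
  missing <- setdiff(fields, names(blk))
  if (length(missing) > 0) {
    stop(sprintf(
      "config block '%s' is missing field(s): %s",
      block, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  blk[fields]
}

beam_from_config <- function(config) {
  blk <- require_block(config, "beam", c(
    "length_l", "young_E", "density_rho", "section_area", "inertia_Iz"
  ))
  do.call(beam_section, blk)
}

tapered_from_config <- function(config, block = "barbule") {
  blk <- require_block(config, block, c(
    "length_l", "root_thickness_t", "width_w", "young_E"
  ))
  do.call(tapered_beam, blk)
}

load_from_config <- function(config) {
  blk <- require_block(config, "load", c(
    "bird_mass_m", "gravity_g", "wing_body_area_A"
  ))
  do.call(air_load, blk)
}

generator_from_config <- function(config, seed = NULL) {
  blk <- config$generator
  if (is.null(blk)) {
    stop("config is missing the 'generator' block", call. = FALSE)
  }
  if (!is.null(seed)) blk$seed <- seed
  do.call(generator_config, blk)
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  path
}

echo_config <- function(config, out_dir) {
  path <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(unclass(config), path)
  path
}

write_run_log <- function(out_dir, lines) {
  path <- file.path(out_dir, "run.log")
  header <- c(
    sprintf("featherbeam %s", as.character(utils::packageVersion("featherbeam"))),
    sprintf("%s", R.version.string),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  writeLines(c(header, lines), path)
  path
}

prepare_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  invisible(out_dir)
}

#' Run the modal-analysis stage
#'
#' Solves the requested eigenvalues for the configured uniform beam and
#' writes the mode table (mode_index, beta, wavenumber_k, sigma, omega_p)
#' as CSV and/or JSON, a config echo sufficient to replay the run, and a
#' run log that records the characteristic-equation residual of every
#' reported eigenvalue.
#'
#' @param config A `run_config` (see [read_run_config()]), or a path to a
#'   YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param n_modes Override for `config$n_modes`.
#' @param format Output formats, subset of `c("csv", "json")`.
#' @return Invisibly, a list with the mode table and the written paths.
#' @export
run_modes <- function(config = NULL, out_dir, n_modes = NULL,
                      format = c("csv", "json")) {
  config <- as_run_config(config)
  format <- match.arg(format, several.ok = TRUE)
  if (!is.null(n_modes)) config$n_modes <- n_modes
  if (!is.numeric(config$n_modes) || length(config$n_modes) != 1L ||
    config$n_modes < 1 || config$n_modes != round(config$n_modes)) {
    stop("n_modes must be a positive integer", call. = FALSE)
  }
  beam <- beam_from_config(config)
  tab <- mode_table(beam, config$n_modes)
  prepare_out_dir(out_dir)
  paths <- character()
  if ("csv" %in% format) {
    paths <- c(paths, write_report_csv(tab, file.path(out_dir, "modes.csv")))
  }
  if ("json" %in% format) {
    paths <- c(paths, write_report_json(tab, file.path(out_dir, "modes.json")))
  }
  paths <- c(paths, echo_config(config, out_dir))
  res <- characteristic_residual(tab$beta)
  paths <- c(paths, write_run_log(out_dir, c(
    sprintf("n_modes = %d", nrow(tab)),
    sprintf(
      "mode %d: beta = %.12f, |residual| = %.3e",
      tab$mode_index, tab$beta, abs(res)
    )
  )))
  invisible(list(modes = tab, paths = paths))
}

#' Run the static-deflection stage
#'
#' Computes the deflection profile of the configured tapered barbule and
#' barb under the distributed air load, writes each profile as CSV
#' (x, shear, moment, inertia, deflection) and a JSON summary with
#' delta_max, plus a config echo and run log.
#'
#' @inheritParams run_modes
#' @param n_stations Stations along each beam (default 101).
#' @return Invisibly, a list with both profiles, the summary and paths.
#' @export
run_deflect <- function(config = NULL, out_dir, n_stations = 101) {
  config <- as_run_config(config)
  barbule <- tapered_from_config(config, "barbule")
  barb <- tapered_from_config(config, "barb")
  load <- load_from_config(config)
  prof_bbl <- deflection_profile(barbule, load, n = n_stations)
  prof_barb <- deflection_profile(barb, load, n = n_stations)
  summary <- list(
    pressure_q = load$pressure_q,
    barbule = list(
      delta_max = max(prof_bbl$deflection),
      delta_ratio = max(prof_bbl$deflection) / barbule$length_l
    ),
    barb = list(
      delta_max = max(prof_barb$deflection),
      delta_ratio = max(prof_barb$deflection) / barb$length_l
    )
  )
  prepare_out_dir(out_dir)
  paths <- c(
    write_report_csv(prof_bbl, file.path(out_dir, "deflection_barbule.csv")),
    write_report_csv(prof_barb, file.path(out_dir, "deflection_barb.csv")),
    write_report_json(summary, file.path(out_dir, "deflection_summary.json")),
    echo_config(config, out_dir),
    write_run_log(out_dir, c(
      sprintf("barbule delta_max = %.6e m", summary$barbule$delta_max),
      sprintf("barb    delta_max = %.6e m", summary$barb$delta_max)
    ))
  )
  invisible(list(
    barbule = prof_bbl, barb = prof_barb, summary = summary, paths = paths
  ))
}

#' Run the vibration-response stage
#'
#' Builds the first-mode vibration field of the configured beam under the
#' configured tip excitation and writes the tip time series (time,
#' tip_displacement, tip_velocity, angular_velocity) as CSV plus a
#' kinematics summary JSON (tip coefficient, v_max, omega_max, period).
#'
#' @inheritParams run_modes
#' @param periods Number of vibration periods in the time series.
#' @param samples_per_period Samples per period (default 4096).
#' @return Invisibly, a list with the series, kinematics and paths.
#' @export
run_vibrate <- function(config = NULL, out_dir, periods = 1,
                        samples_per_period = 4096) {
  config <- as_run_config(config)
  beam <- beam_from_config(config)
  exc <- require_block(config, "excitation", c("tip_force_F", "phase_phi"))
  field <- vibration_field(
    beam,
    amplitude_from_tip_force(exc$tip_force_F, beam, exc$phase_phi)
  )
  series <- tip_time_series(field, periods, samples_per_period)
  kin <- tip_kinematics(field)
  summary <- list(
    beta1 = field$mode$beta, omega_p1 = field$mode$omega_p,
    period = 2 * pi / field$mode$omega_p,
    amplitude_C = field$excitation$amplitude_C,
    tip_coefficient = kin$coeff, v_max = kin$v_max,
    omega_max = kin$omega_max
  )
  prepare_out_dir(out_dir)
  paths <- c(
    write_report_csv(series, file.path(out_dir, "tip_time_series.csv")),
    write_report_json(summary, file.path(out_dir, "kinematics.json")),
    echo_config(config, out_dir),
    write_run_log(out_dir, c(
      sprintf(
        "beta1 = %.12f, |residual| = %.3e",
        field$mode$beta, abs(characteristic_residual(field$mode$beta))
      ),
      sprintf("v_max = %.6e m/s, omega_max = %.6e rad/s",
              kin$v_max, kin$omega_max)
    ))
  )
  invisible(list(
    series = series, kinematics = kin, summary = summary, paths = paths
  ))
}

feather_geometry_to_list <- function(geometry) {
  list(
    schema = "featherbeam/feather-geometry/v1",
    seed = geometry$config$seed,
    config_hash = geometry$config_hash,
    config = unclass(geometry$config),
    material = geometry$material,
    load = unclass(geometry$load),
    barbs = lapply(geometry$barbs, function(barb) {
      tb <- barb$tapered_beam
      list(
        barb_index = barb$barb_index,
        length_l = tb$length_l,
        root_thickness_t = tb$root_thickness_t,
        width_w = tb$width_w,
        barbules = lapply(barb$barbules, function(bbl) {
          u <- bbl$tapered_beam
          s <- bbl$beam_section
          list(
            barbule_index = bbl$barbule_index,
            length_l = u$length_l,
            root_thickness_t = u$root_thickness_t,
            width_w = u$width_w,
            section_area = s$section_area,
            inertia_Iz = s$inertia_Iz
          )
        })
      )
    })
  )
}

#' Generate a synthetic feather and write its geometry
#'
#' Runs the synthetic generator and writes the geometry as a
#' schema-versioned JSON document (echoing the full configuration and its
#' hash) plus a config echo and run log.
#'
#' @inheritParams run_modes
#' @param seed Override for the generator seed.
#' @return Invisibly, a list with the `feather_geometry` and paths.
#' @export
run_generate <- function(config = NULL, out_dir, seed = NULL) {
  config <- as_run_config(config)
  gen_cfg <- generator_from_config(config, seed)
  feather <- generate_feather(gen_cfg)
  prepare_out_dir(out_dir)
  paths <- c(
    write_report_json(
      feather_geometry_to_list(feather),
      file.path(out_dir, "geometry.json")
    ),
    echo_config(config, out_dir),
    write_run_log(out_dir, c(
      sprintf("generator seed = %d", gen_cfg$seed),
      sprintf("config hash = %s", feather$config_hash),
      sprintf("barbs = %d", length(feather$barbs))
    ))
  )
  invisible(list(feather = feather, paths = paths))
}

#' Run the full analysis pipeline on a synthetic feather
#'
#' Generates a feather from the configured distributions, runs the modal
#' and static stages on every barbule, and writes the geometry JSON, the
#' per-barbule summary CSV, a config echo and a run log recording the
#' seed, config hash, package versions and the characteristic-equation
#' residual of the eigenvalue used. Identical configurations (including
#' the seed) produce byte-identical geometry and summary files.
#'
#' @inheritParams run_generate
#' @return Invisibly, a list with the feather, the summary table and the
#'   written paths.
#' @examples
#' \donttest{
#' out <- run_analyze(out_dir = tempfile())
#' head(out$summary)
#' }
#' @export
run_analyze <- function(config = NULL, out_dir, seed = NULL) {
  config <- as_run_config(config)
  gen_cfg <- generator_from_config(config, seed)
  feather <- generate_feather(gen_cfg)
  summary <- summarize_feather(feather)
  beta1 <- solve_eigenvalues(1)
  prepare_out_dir(out_dir)
  paths <- c(
    write_report_json(
      feather_geometry_to_list(feather),
      file.path(out_dir, "geometry.json")
    ),
    write_report_csv(summary, file.path(out_dir, "summary.csv")),
    echo_config(config, out_dir),
    write_run_log(out_dir, c(
      sprintf("generator seed = %d", gen_cfg$seed),
      sprintf("config hash = %s", feather$config_hash),
      sprintf(
        "beta1 = %.12f, |residual| = %.3e",
        beta1, abs(characteristic_residual(beta1))
      ),
      sprintf(
        "barbs = %d, barbules = %d", length(feather$barbs), nrow(summary)
      ),
      sprintf(
        "linearity warnings = %d", sum(summary$linearity_warning)
      )
    ))
  )
  invisible(list(feather = feather, summary = summary, paths = paths))
}

as_run_config <- function(config) {
  if (is.null(config)) {
    return(default_run_config())
  }
  if (is.character(config)) {
    return(read_run_config(config))
  }
  if (inherits(config, "run_config")) {
    return(config)
  }
  if (is.list(config)) {
    return(structure(
      modify_list_deep(unclass(default_run_config()), config),
      class = "run_config"
    ))
  }
  stop("config must be NULL, a path, or a run_config list", call. = FALSE)
}
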