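#' Configuration for the synthetic feather generator
#'
#' Describes the distributions from which a hierarchical feather
#' micro-structure (rachis carrying barbs, barbs carrying barbules) is
#' sampled, plus the shared material and the air load. Counts are drawn
#' uniformly over their integer ranges; dimensions are drawn log-uniformly
#' (they are scale parameters) within their ranges. The default ranges are
#' pigeon-scale placeholders chosen from the biomechanics literature on
#' feather keratin and flight-feather morphology — they are package
#' defaults, not measured values — and every generated geometry and report
#' echoes the configuration it was produced from.
#'
#' @param seed Integer seed for the generator.
#' @param n_barbs_range Integer range `c(lo, hi)` of barbs per feather.
#' @param barbules_per_barb_range Integer range of barbules per barb.
#' @param barb_length_range Range of barb length (m).
#' @param barb_thickness_range Range of barb root thickness (m).
#' @param barbule_length_range Range of barbule length (m).
#' @param barbule_thickness_range Range of barbule root thickness (m).
#' @param width_to_thickness_ratio Section width divided by root thickness.
#' @param young_E Young's modulus of feather keratin (Pa).
#' @param density_rho Density of feather keratin (kg/m^3).
#' @param bird_mass_m Bird mass (kg).
#' @param wing_body_area_A Wing-plus-body area (m^2).
#' @param gravity_g Gravitational acceleration (m/s^2).
#' @return An object of class `generator_config`.
#' @examples
#' generator_config(seed = 1)
#' @export
generator_config <- function(seed = 1L,
                             n_barbs_range = c(8L, 12L),
                             barbules_per_barb_range = c(15L, 25L),
                             barb_length_range = c(15e-3, 30e-3),
                             barb_thickness_range = c(150e-6, 350e-6),
                             barbule_length_range = c(200e-6, 500e-6),
                             barbule_thickness_range = c(5e-6, 15e-6),
                             width_to_thickness_ratio = 2,
                             young_E = 2.5e9,
                             density_rho = 1150,
                             bird_mass_m = 0.35,
                             wing_body_area_A = 0.065,
                             gravity_g = 9.81) {
  cfg <- list(
    seed = as.integer(seed),
    n_barbs_range = as.integer(n_barbs_range),
    barbules_per_barb_range = as.integer(barbules_per_barb_range),
    barb_length_range = as.numeric(barb_length_range),
    barb_thickness_range = as.numeric(barb_thickness_range),
    barbule_length_range = as.numeric(barbule_length_range),
    barbule_thickness_range = as.numeric(barbule_thickness_range),
    width_to_thickness_ratio = width_to_thickness_ratio,
    young_E = young_E, density_rho = density_rho,
    bird_mass_m = bird_mass_m, wing_body_area_A = wing_body_area_A,
    gravity_g = gravity_g
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  ranges <- c(
    "n_barbs_range", "barbules_per_barb_range", "barb_length_range",
    "barb_thickness_range", "barbule_length_range",
    "barbule_thickness_range"
  )
  for (nm in ranges) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[1] > r[2]) {
      stop(sprintf(
        "%s must be c(lo, hi) with 0 < lo <= hi, got (%s)",
        nm, paste(r, collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (cfg$barbule_length_range[2] > cfg$barb_length_range[1]) {
    stop(paste(
      "hierarchy violated: barbule_length_range upper bound must not",
      "exceed barb_length_range lower bound"
    ), call. = FALSE)
  }
  stop_unless_positive_scalars(c(
    width_to_thickness_ratio = cfg$width_to_thickness_ratio,
    young_E = cfg$young_E, density_rho = cfg$density_rho,
    bird_mass_m = cfg$bird_mass_m,
    wing_body_area_A = cfg$wing_body_area_A, gravity_g = cfg$gravity_g
  ))
  invisible(TRUE)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> synthetic feather generator\n")
  cat(sprintf("  seed %d; %d-%d barbs x %d-%d barbules\n", x$seed,
    x$n_barbs_range[1], x$n_barbs_range[2],
    x$barbules_per_barb_range[1], x$barbules_per_barb_range[2]
  ))
  cat(sprintf(
    "  barb    l in [%g, %g] m, t in [%g, %g] m\n",
    x$barb_length_range[1], x$barb_length_range[2],
    x$barb_thickness_range[1], x$barb_thickness_range[2]
  ))
  cat(sprintf(
    "  barbule l in [%g, %g] m, t in [%g, %g] m\n",
    x$barbule_length_range[1], x$barbule_length_range[2],
    x$barbule_thickness_range[1], x$barbule_thickness_range[2]
  ))
  cat(sprintf(
    "  material E = %g Pa, rho = %g kg/m^3; load m = %g kg, A = %g m^2\n",
    x$young_E, x$density_rho, x$bird_mass_m, x$wing_body_area_A
  ))
  invisible(x)
}

# log-uniform draw within [lo, hi]; degenerate ranges collapse exactly
runif_log <- function(n, lo, hi) {
  if (lo == hi) {
    return(rep(lo, n))
  }
  exp(stats::runif(n, log(lo), log(hi)))
}

# uniform integer draw within [lo, hi] inclusive
sample_int_range <- function(n, lo, hi) {
  if (lo == hi) {
    return(rep(as.integer(lo), n))
  }
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' Generate a synthetic feather geometry
#'
#' Samples a hierarchical rachis -> barb -> barbule structure from the
#' configured distributions. Every barb and every barbule is a tapered
#' cantilever; each barbule also carries the uniform [beam_section()]
#' derived from its root cross-section (A = w t, Iz = w t^3/12) for modal
#' analysis. Sampling uses R's RNG seeded from `config$seed`; the caller's
#' RNG state is restored on exit, so the output is a pure function of the
#' configuration.
#'
#' @param config A [generator_config()].
#' @return An object of class `feather_geometry`: list with `config`,
#'   `config_hash`, `material` (E, rho), `load` (an [air_load()]) and
#'   `barbs`, a list where each element holds the barb's `tapered_beam`
#'   and a list of barbule entries (`tapered_beam` + `beam_section`).
#' @examples
#' feather <- generate_feather(generator_config(seed = 42))
#' feather
#' @export
generate_feather <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n_barbs <- sample_int_range(
    1L, config$n_barbs_range[1], config$n_barbs_range[2]
  )
  barbs <- lapply(seq_len(n_barbs), function(bi) {
    barb_l <- runif_log(
      1, config$barb_length_range[1], config$barb_length_range[2]
    )
    barb_t <- runif_log(
      1, config$barb_thickness_range[1], config$barb_thickness_range[2]
    )
    barb <- tapered_beam(
      length_l = barb_l, root_thickness_t = barb_t,
      width_w = config$width_to_thickness_ratio * barb_t,
      young_E = config$young_E
    )
    n_bbl <- sample_int_range(
      1L, config$barbules_per_barb_range[1],
      config$barbules_per_barb_range[2]
    )
    barbules <- lapply(seq_len(n_bbl), function(ui) {
      bbl_l <- runif_log(
        1, config$barbule_length_range[1], config$barbule_length_range[2]
      )
      bbl_t <- runif_log(
        1, config$barbule_thickness_range[1],
        config$barbule_thickness_range[2]
      )
      tb <- tapered_beam(
        length_l = bbl_l, root_thickness_t = bbl_t,
        width_w = config$width_to_thickness_ratio * bbl_t,
        young_E = config$young_E
      )
      list(
        barbule_index = ui,
        tapered_beam = tb,
        beam_section = as_beam_section(tb, config$density_rho)
      )
    })
    list(barb_index = bi, tapered_beam = barb, barbules = barbules)
  })

  structure(
    list(
      config = config,
      config_hash = rlang::hash(unclass(config)),
      material = list(young_E = config$young_E,
                      density_rho = config$density_rho),
      load = air_load(
        bird_mass_m = config$bird_mass_m, gravity_g = config$gravity_g,
        wing_body_area_A = config$wing_body_area_A
      ),
      barbs = barbs
    ),
    class = "feather_geometry"
  )
}

#' @export
print.feather_geometry <- function(x, ...) {
  n_bbl <- sum(vapply(x$barbs, function(b) length(b$barbules), integer(1)))
  cat("<feather_geometry> synthetic rachis -> barb -> barbule structure\n")
  cat(sprintf(
    "  %d barbs, %d barbules; seed %d, config hash %s\n",
    length(x$barbs), n_bbl, x$config$seed, x$config_hash
  ))
  invisible(x)
}

#' Per-barbule mechanical summary of a feather
#'
#' Runs the modal and static stages over every barbule: first natural
#' frequency (from the root-section uniform beam), peak tip-velocity
#' coefficient per unit modal amplitude (v_max / C, 1/s), maximum static
#' deflection under the feather's air load, and a flag marking barbules
#' whose delta_max exceeds 10% of their length (linear model suspect).
#' Rows are ordered by barb index then barbule index.
#'
#' @param geometry A [generate_feather()] result.
#' @return A data.frame with columns `barb_index`, `barbule_index`,
#'   `length_l`, `root_thickness_t`, `width_w`, `section_area`,
#'   `inertia_Iz`, `beta1`, `omega_p1`, `freq1_hz`, `vmax_per_C`,
#'   `delta_max`, `delta_ratio`, `linearity_warning`.
#' @export
summarize_feather <- function(geometry) {
  stopifnot(inherits(geometry, "feather_geometry"))
  beta1 <- solve_eigenvalues(1)
  tip_coeff <- beta1^2 * mode_shape(beta1, 1)
  rows <- list()
  for (barb in geometry$barbs) {
    for (bbl in barb$barbules) {
      sec <- bbl$beam_section
      tb <- bbl$tapered_beam
      omega1 <- natural_frequency(beta1, sec)
      scale <- sqrt(sec$young_E * sec$inertia_Iz /
        (sec$density_rho * sec$section_area))
      dmax <- deflection_tapered(tb, geometry$load, tb$length_l)
      rows[[length(rows) + 1L]] <- data.frame(
        barb_index = barb$barb_index,
        barbule_index = bbl$barbule_index,
        length_l = sec$length_l,
        root_thickness_t = tb$root_thickness_t,
        width_w = tb$width_w,
        section_area = sec$section_area,
        inertia_Iz = sec$inertia_Iz,
        beta1 = beta1,
        omega_p1 = omega1,
        freq1_hz = omega1 / (2 * pi),
        vmax_per_C = tip_coeff / sec$length_l^2 * scale,
        delta_max = dmax,
        delta_ratio = dmax / tb$length_l,
        linearity_warning = dmax / tb$length_l > 0.1
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      barb_index = integer(), barbule_index = integer(),
      length_l = numeric(), root_thickness_t = numeric(),
      width_w = numeric(), section_area = numeric(),
      inertia_Iz = numeric(), beta1 = numeric(), omega_p1 = numeric(),
      freq1_hz = numeric(), vmax_per_C = numeric(), delta_max = numeric(),
      delta_ratio = numeric(), linearity_warning = logical()
    ))
  }
  do.call(rbind, rows)
}
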