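#' Uniform cantilever beam section
#'
#' Bundles the geometry and material of a uniform-section cantilevered beam
#' (a feather barbule clamped at its root on the barb): length, Young's
#' modulus, mass density, cross-sectional area and second moment of area
#' about the bending axis. All quantities are SI.
#'
#' @param length_l Beam length l (m).
#' @param young_E Young's elastic modulus E (Pa).
#' @param density_rho Mass density rho (kg/m^3).
#' @param section_area Cross-sectional area A (m^2).
#' @param inertia_Iz Second moment of area I_z about the bending axis (m^4).
#'
#' @return An object of class `beam_section`.
#' @examples
#' barbule <- beam_section(
#'   length_l = 350e-6, young_E = 2.5e9, density_rho = 1150,
#'   section_area = 2e-10, inertia_Iz = 1.7e-21
#' )
#' barbule
#' @export
beam_section <- function(length_l, young_E, density_rho, section_area,
                         inertia_Iz) {
  vals <- c(
    length_l = length_l, young_E = young_E, density_rho = density_rho,
    section_area = section_area, inertia_Iz = inertia_Iz
  )
  stop_unless_positive_scalars(vals)
  stiffness <- young_E * inertia_Iz / (density_rho * section_area)
  if (!is.finite(stiffness) || stiffness <= 0) {
    stop("stiffness ratio E*Iz/(rho*A) must be finite and positive",
      call. = FALSE
    )
  }
  structure(
    list(
      length_l = length_l, young_E = young_E, density_rho = density_rho,
      section_area = section_area, inertia_Iz = inertia_Iz
    ),
    class = "beam_section"
  )
}

#' @export
print.beam_section <- function(x, ...) {
  cat("<beam_section> uniform cantilever\n")
  cat(sprintf("  length     l   = %g m\n", x$length_l))
  cat(sprintf("  modulus    E   = %g Pa\n", x$young_E))
  cat(sprintf("  density    rho = %g kg/m^3\n", x$density_rho))
  cat(sprintf("  area       A   = %g m^2\n", x$section_area))
  cat(sprintf("  inertia    Iz  = %g m^4\n", x$inertia_Iz))
  invisible(x)
}

#' Linearly tapered cantilever beam
#'
#' A cantilever of rectangular cross-section whose thickness decreases
#' linearly from `root_thickness_t` at the clamped root to zero at the free
#' tip, as in the static-deflection model of a barbule or barb under the
#' distributed air load. The taper slope is t/l, so the thickness at x is
#' t - (t/l) x and the second moment of area is w (t - (t/l) x)^3 / 12.
#'
#' @param length_l Beam length l (m).
#' @param root_thickness_t Thickness t at the root (m).
#' @param width_w Beam width w (m), constant along the beam.
#' @param young_E Young's elastic modulus E (Pa).
#'
#' @return An object of class `tapered_beam` with derived field
#'   `taper_slope` = t/l.
#' @examples
#' tapered_beam(length_l = 350e-6, root_thickness_t = 10e-6,
#'              width_w = 20e-6, young_E = 2.5e9)
#' @export
tapered_beam <- function(length_l, root_thickness_t, width_w, young_E) {
  vals <- c(
    length_l = length_l, root_thickness_t = root_thickness_t,
    width_w = width_w, young_E = young_E
  )
  stop_unless_positive_scalars(vals)
  structure(
    list(
      length_l = length_l, root_thickness_t = root_thickness_t,
      width_w = width_w, young_E = young_E,
      taper_slope = root_thickness_t / length_l
    ),
    class = "tapered_beam"
  )
}

#' @export
print.tapered_beam <- function(x, ...) {
  cat("<tapered_beam> linearly tapered cantilever (rectangular section)\n")
  cat(sprintf("  length        l = %g m\n", x$length_l))
  cat(sprintf("  root thickness t = %g m\n", x$root_thickness_t))
  cat(sprintf("  width         w = %g m\n", x$width_w))
  cat(sprintf("  modulus       E = %g Pa\n", x$young_E))
  cat(sprintf("  taper slope  t/l = %g\n", x$taper_slope))
  invisible(x)
}

#' Distributed air load on the feather vane
#'
#' The pressure transmitted to the vane when the bird's weight is carried by
#' the wing-plus-body area: q = m g / A. The pressure acts over the width of
#' each beam, giving a line load q w.
#'
#' @param bird_mass_m Total mass of the bird m (kg).
#' @param gravity_g Gravitational acceleration g (m/s^2). Default 9.81.
#' @param wing_body_area_A Area of wings and body A (m^2).
#'
#' @return An object of class `air_load` with derived field `pressure_q`
#'   (Pa).
#' @examples
#' air_load(bird_mass_m = 0.35, wing_body_area_A = 0.065)
#' @export
air_load <- function(bird_mass_m, gravity_g = 9.81, wing_body_area_A) {
  vals <- c(
    bird_mass_m = bird_mass_m, gravity_g = gravity_g,
    wing_body_area_A = wing_body_area_A
  )
  stop_unless_positive_scalars(vals)
  structure(
    list(
      bird_mass_m = bird_mass_m, gravity_g = gravity_g,
      wing_body_area_A = wing_body_area_A,
      pressure_q = bird_mass_m * gravity_g / wing_body_area_A
    ),
    class = "air_load"
  )
}

#' @export
print.air_load <- function(x, ...) {
  cat("<air_load> distributed pressure q = m g / A\n")
  cat(sprintf("  mass    m = %g kg\n", x$bird_mass_m))
  cat(sprintf("  gravity g = %g m/s^2\n", x$gravity_g))
  cat(sprintf("  area    A = %g m^2\n", x$wing_body_area_A))
  cat(sprintf("  pressure q = %g Pa\n", x$pressure_q))
  invisible(x)
}

#' Uniform beam section from root dimensions of a tapered beam
#'
#' The modal model assumes a uniform beam; a tapered barbule is fed to it
#' through its root cross-section: A = w t, Iz = w t^3 / 12.
#'
#' @param beam A `tapered_beam`.
#' @param density_rho Mass density rho (kg/m^3).
#' @return A `beam_section` with the root cross-section.
#' @export
as_beam_section <- function(beam, density_rho) {
  stopifnot(inherits(beam, "tapered_beam"))
  beam_section(
    length_l = beam$length_l,
    young_E = beam$young_E,
    density_rho = density_rho,
    section_area = beam$width_w * beam$root_thickness_t,
    inertia_Iz = beam$width_w * beam$root_thickness_t^3 / 12
  )
}

# all named values scalar, finite, strictly positive
stop_unless_positive_scalars <- function(vals) {
  ok <- vapply(
    vals,
    function(v) is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0,
    logical(1)
  )
  if (!all(ok)) {
    bad <- names(vals)[!ok]
    stop(
      sprintf(
        "field(s) %s must be finite, strictly positive scalars",
        paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(TRUE)
}
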