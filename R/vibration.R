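#' First-mode vibration field of a cantilevered barbule
#'
#' After the combing (tip) force is released, the barbule vibrates in its
#' first primary mode:
#' y(x, t) = C \[cosh(b xi) - cos(b xi) - sigma (sinh(b xi) - sin(b xi))\]
#' sin(p1 t + phi), with b = 1.875104 the first eigenvalue, xi = x/l, and
#' p1 the first natural frequency. This constructor resolves the first
#' mode for the beam and attaches the excitation.
#'
#' @param beam A [beam_section()].
#' @param excitation An `excitation_amplitude` from
#'   [amplitude_from_tip_force()], or a tip force (N) from which one is
#'   built with the default phase.
#' @return An object of class `vibration_field` with elements `beam`,
#'   `excitation`, and `mode` (list: `mode_index`, `beta`, `wavenumber_k`,
#'   `sigma`, `omega_p`).
#' @examples
#' b <- beam_section(350e-6, 2.5e9, 1150, 2e-10, 1.7e-21)
#' vf <- vibration_field(b, excitation = 1e-6)
#' displacement(vf, xi = 1, time = 0)
#' @export
vibration_field <- function(beam, excitation) {
  stopifnot(inherits(beam, "beam_section"))
  if (is.numeric(excitation)) {
    excitation <- amplitude_from_tip_force(excitation, beam)
  }
  stopifnot(inherits(excitation, "excitation_amplitude"))
  beta1 <- solve_eigenvalues(1)
  mode <- list(
    mode_index = 1L,
    beta = beta1,
    wavenumber_k = beta1 / beam$length_l,
    sigma = sigma_coefficient(beta1),
    omega_p = natural_frequency(beta1, beam)
  )
  structure(
    list(beam = beam, excitation = excitation, mode = mode),
    class = "vibration_field"
  )
}

#' @export
print.vibration_field <- function(x, ...) {
  cat("<vibration_field> first primary mode of a cantilevered barbule\n")
  cat(sprintf(
    "  beta1 = %.6f, p1 = %g rad/s (%g Hz)\n",
    x$mode$beta, x$mode$omega_p, x$mode$omega_p / (2 * pi)
  ))
  cat(sprintf(
    "  amplitude C = %g m, phase = %g rad\n",
    x$excitation$amplitude_C, x$excitation$phase_phi
  ))
  invisible(x)
}

#' Transverse displacement of the vibrating barbule
#'
#' y(xi l, t) = C S(beta1, xi) sin(p1 t + phi) with S the normalised mode
#' shape from [mode_shape()].
#'
#' @param field A [vibration_field()].
#' @param xi Relative position(s) x/l in \[0, 1\].
#' @param time Time(s) t (s).
#' @return Displacement (m); vectorised over `xi` and `time` with the usual
#'   recycling.
#' @export
displacement <- function(field, xi, time) {
  stopifnot(inherits(field, "vibration_field"))
  field$excitation$amplitude_C * mode_shape(field$mode$beta, xi) *
    sin(field$mode$omega_p * time + field$excitation$phase_phi)
}

#' Transverse velocity of the vibrating barbule
#'
#' v(xi l, t) = p1 C S(beta1, xi) cos(p1 t + phi), the exact time
#' derivative of [displacement()].
#'
#' @inheritParams displacement
#' @return Velocity (m/s).
#' @export
velocity <- function(field, xi, time) {
  stopifnot(inherits(field, "vibration_field"))
  field$mode$omega_p * field$excitation$amplitude_C *
    mode_shape(field$mode$beta, xi) *
    cos(field$mode$omega_p * time + field$excitation$phase_phi)
}

#' Approximate angular velocity of the barbule about its root
#'
#' The first-mode vibration looks like a rigid oscillation about the
#' clamped root, so the angular velocity is approximated as the tip
#' velocity divided by the beam length: omega(t) = v(l, t) / l. This is
#' the small-angle approximation; no arctangent correction is applied.
#'
#' @param field A [vibration_field()].
#' @param time Time(s) t (s).
#' @return Angular velocity (rad/s).
#' @export
angular_velocity <- function(field, time) {
  velocity(field, 1, time) / field$beam$length_l
}

#' Peak tip kinematics and droplet-shedding speed
#'
#' The tip velocity amplitude is v_max = coeff C / l^2 sqrt(E Iz/(rho A))
#' and the peak angular speed is omega_max = v_max / l, where
#' coeff = beta1^2 S(beta1, 1) = 7.03203 is the dimensionless tip
#' coefficient. v_max is also the largest speed a water drop attached to
#' the free end reaches during the return motion — the droplet-shedding
#' speed (the drop is treated as massless; it does not alter the mode).
#'
#' @param field A [vibration_field()].
#' @return An object of class `tip_kinematics`: list with `coeff`
#'   (dimensionless), `v_max` (m/s) and `omega_max` (rad/s).
#' @examples
#' b <- beam_section(350e-6, 2.5e9, 1150, 2e-10, 1.7e-21)
#' tip_kinematics(vibration_field(b, 1e-6))
#' @export
tip_kinematics <- function(field) {
  stopifnot(inherits(field, "vibration_field"))
  beam <- field$beam
  beta1 <- field$mode$beta
  coeff <- beta1^2 * mode_shape(beta1, 1)
  scale <- sqrt(beam$young_E * beam$inertia_Iz /
    (beam$density_rho * beam$section_area))
  v_max <- coeff * field$excitation$amplitude_C / beam$length_l^2 * scale
  structure(
    list(coeff = coeff, v_max = v_max, omega_max = v_max / beam$length_l),
    class = "tip_kinematics"
  )
}

#' @export
print.tip_kinematics <- function(x, ...) {
  cat("<tip_kinematics>\n")
  cat(sprintf("  tip coefficient beta1^2 Y(l)/C = %.5f\n", x$coeff))
  cat(sprintf("  v_max     = %g m/s (droplet-shedding speed)\n", x$v_max))
  cat(sprintf("  omega_max = %g rad/s\n", x$omega_max))
  invisible(x)
}

#' Tip time series over whole vibration periods
#'
#' Samples tip displacement, tip velocity and the approximate angular
#' velocity on a regular time grid covering `periods` periods of the first
#' mode.
#'
#' @param field A [vibration_field()].
#' @param periods Number of periods to cover (default 1).
#' @param samples_per_period Samples per period (default 4096).
#' @return A data.frame with columns `time`, `tip_displacement`,
#'   `tip_velocity`, `angular_velocity`.
#' @export
tip_time_series <- function(field, periods = 1, samples_per_period = 4096) {
  stopifnot(inherits(field, "vibration_field"))
  period <- 2 * pi / field$mode$omega_p
  time <- seq(0, periods * period,
    length.out = max(2L, as.integer(periods * samples_per_period)) + 1L
  )
  data.frame(
    time = time,
    tip_displacement = displacement(field, 1, time),
    tip_velocity = velocity(field, 1, time),
    angular_velocity = angular_velocity(field, time)
  )
}
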