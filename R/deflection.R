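#' Shear force and bending moment under the distributed air load
#'
#' For a cantilever of width w carrying the line load q w (q = m g / A the
#' air pressure), the internal shear at x is Q(x) = q w (l - x) and the
#' bending moment is M(x) = q w (l - x)^2 / 2; both vanish at the free tip.
#'
#' @param beam A [tapered_beam()].
#' @param load An [air_load()].
#' @param x Position(s) along the beam, 0 <= x <= l (m).
#' @return A data.frame with columns `x`, `shear` (N) and `moment` (N m).
#' @export
shear_and_moment <- function(beam, load, x) {
  stopifnot(inherits(beam, "tapered_beam"), inherits(load, "air_load"))
  check_position(x, beam$length_l)
  qw <- load$pressure_q * beam$width_w
  data.frame(
    x = x,
    shear = qw * (beam$length_l - x),
    moment = 0.5 * qw * (beam$length_l - x)^2
  )
}

#' Second moment of area of the tapered section
#'
#' The thickness decreases linearly from t at the root to 0 at the tip, so
#' I(x) = w (t - (t/l) x)^3 / 12. At x = l the section vanishes; the
#' function returns 0 there with a warning (the deflection closed form
#' remains finite at the tip).
#'
#' @param beam A [tapered_beam()].
#' @param x Position(s) 0 <= x <= l (m).
#' @return Second moment of area (m^4), vectorised.
#' @export
section_inertia <- function(beam, x) {
  stopifnot(inherits(beam, "tapered_beam"))
  check_position(x, beam$length_l)
  if (any(x == beam$length_l)) {
    warning("section vanishes at the tip (x = l): inertia is 0",
      call. = FALSE
    )
  }
  thick <- beam$root_thickness_t - beam$taper_slope * x
  beam$width_w * thick^3 / 12
}

#' Deflection of a tapered barbule under the distributed air load
#'
#' The deflection curve is delta(x) = integral over \[0, x\] of
#' 6 q (l - y)^3 / (E (t - (t/l) y)^3) dy. Because the taper slope is t/l,
#' the integrand collapses to the constant 6 q l^3 / (E t^3), so the
#' deflection is linear in x:
#' delta(x) = 6 q l^3 x / (E t^3) = 6 m g l^3 x / (E A t^3),
#' with maximum delta_max = 6 m g l^4 / (E A t^3) at the distal end.
#' `method = "quadrature"` evaluates the integral by adaptive quadrature
#' instead, as an independent check of the cancellation.
#'
#' @param beam A [tapered_beam()].
#' @param load An [air_load()].
#' @param x Position(s) 0 <= x <= l (m).
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return Deflection (m), vectorised over `x`.
#' @examples
#' bb <- tapered_beam(350e-6, 10e-6, 20e-6, 2.5e9)
#' q <- air_load(0.35, 9.81, 0.065)
#' deflection_tapered(bb, q, bb$length_l) # delta_max
#' @export
deflection_tapered <- function(beam, load, x,
                               method = c("closed", "quadrature")) {
  stopifnot(inherits(beam, "tapered_beam"), inherits(load, "air_load"))
  method <- match.arg(method)
  check_position(x, beam$length_l)
  q <- load$pressure_q
  E <- beam$young_E
  t <- beam$root_thickness_t
  l <- beam$length_l
  if (method == "closed") {
    return(6 * q * l^3 * x / (E * t^3))
  }
  integrand <- function(y) {
    6 * q * (l - y)^3 / (E * (t - beam$taper_slope * y)^3)
  }
  vapply(x, function(xi) {
    if (xi == 0) {
      return(0)
    }
    stats::integrate(integrand,
      lower = 0, upper = xi,
      rel.tol = 1e-12, abs.tol = 0
    )$value
  }, numeric(1))
}

#' Deflection of a barb under the distributed air load
#'
#' A barb is the same tapered cantilever at a larger scale; the identical
#' formula applies with the barb's length and root thickness:
#' delta(x) = 6 m g lB^3 x / (E A tB^3).
#'
#' @param barb A [tapered_beam()] describing the barb.
#' @inheritParams deflection_tapered
#' @return Deflection (m), vectorised over `x`.
#' @export
deflection_barb <- function(barb, load, x,
                            method = c("closed", "quadrature")) {
  deflection_tapered(barb, load, x, method = method)
}

#' Tip deflection of a uniform cantilever under a point load
#'
#' A point (combing) force P at the free end deflects the tip by
#' delta = P l^3 / (3 E Iz), obtained from the unit-load integral
#' of M dM/dP / (E Iz) = P (l - x)^2 / (E Iz) over the beam; after the
#' force is removed the beam springs back to its initial position.
#' `method = "quadrature"` evaluates that integral numerically as an
#' independent check.
#'
#' @param beam A [beam_section()] (uniform section).
#' @param P Point force (N), non-negative.
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return Tip deflection (m).
#' @export
point_load_deflection <- function(beam, P,
                                  method = c("closed", "quadrature")) {
  stopifnot(inherits(beam, "beam_section"))
  method <- match.arg(method)
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0) {
    stop("P must be a finite non-negative scalar", call. = FALSE)
  }
  l <- beam$length_l
  EI <- beam$young_E * beam$inertia_Iz
  if (method == "closed") {
    return(P * l^3 / (3 * EI))
  }
  if (P == 0) {
    return(0)
  }
  stats::integrate(function(x) P * (l - x)^2 / EI,
    lower = 0, upper = l, rel.tol = 1e-13, abs.tol = 0
  )$value
}

#' Deflection profile of a tapered beam under the air load
#'
#' Tabulates shear, moment, section inertia and deflection at `n` evenly
#' spaced stations from root to tip. When the tip deflection exceeds 10% of
#' the beam length the small-deflection linear model is questionable and a
#' warning is issued (this ratio threshold is a package choice).
#'
#' @param beam A [tapered_beam()].
#' @param load An [air_load()].
#' @param n Number of stations (default 101).
#' @return A data.frame with columns `x`, `shear`, `moment`, `inertia`,
#'   `deflection`.
#' @export
deflection_profile <- function(beam, load, n = 101) {
  stopifnot(inherits(beam, "tapered_beam"), inherits(load, "air_load"))
  x <- seq(0, beam$length_l, length.out = n)
  sm <- shear_and_moment(beam, load, x)
  inertia <- suppressWarnings(section_inertia(beam, x))
  deflection <- deflection_tapered(beam, load, x)
  if (max(deflection) / beam$length_l > 0.1) {
    warning(sprintf(
      "delta_max/l = %.3g exceeds 0.1: the linear small-deflection model may not hold",
      max(deflection) / beam$length_l
    ), call. = FALSE)
  }
  data.frame(
    x = x, shear = sm$shear, moment = sm$moment,
    inertia = inertia, deflection = deflection
  )
}

check_position <- function(x, l) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > l)) {
    stop(sprintf("x must lie in [0, %g]", l), call. = FALSE)
  }
  invisible(TRUE)
}
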