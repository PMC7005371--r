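#' Characteristic equation of the clamped-free beam
#'
#' Free bending vibration of a cantilever (clamped at x = 0, free at x = l)
#' admits non-trivial mode shapes only where the boundary-condition
#' determinant vanishes, which reduces to the transcendental condition
#' cos(beta) = -sech(beta) with beta = k l the dimensionless eigenvalue.
#' This function returns the residual cos(beta) + sech(beta); its zeros are
#' the eigenvalues.
#'
#' sech is evaluated as 2 exp(-beta) / (1 + exp(-2 beta)), which decays
#' instead of overflowing for large beta, so the residual is well defined
#' for arbitrarily high modes.
#'
#' @param beta Non-negative dimensionless argument(s) beta = k l.
#' @return cos(beta) + sech(beta), vectorised over `beta`.
#' @examples
#' characteristic_residual(1.875104) # ~ 0: first eigenvalue
#' characteristic_residual(0)        # 2
#' @export
characteristic_residual <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta < 0)) {
    stop("beta must be finite and non-negative", call. = FALSE)
  }
  cos(beta) + sech_safe(beta)
}

# overflow-safe sech: 2 e^{-b} / (1 + e^{-2b}) for b >= 0
sech_safe <- function(b) {
  e <- exp(-b)
  2 * e / (1 + e * e)
}

#' Eigenvalues of the cantilever characteristic equation
#'
#' Finds the `n_modes` smallest positive roots beta_n of
#' cos(beta) = -sech(beta). Because sech decays exponentially, root n lies
#' within a shrinking neighbourhood of the cosine zero (2n - 1) pi / 2;
#' each root is bracketed there ([1, 3] for the first) and refined with a
#' bracketing root-finder, then polished by Newton steps so the residual is
#' at machine precision (far below the 1e-12 tolerance target).
#'
#' @param n_modes Number of modes requested (positive integer).
#' @param tol Interval tolerance passed to the bracketing refiner.
#' @return Numeric vector of the eigenvalues beta_1 < ... < beta_n.
#' @examples
#' solve_eigenvalues(6) # 1.875104 4.694091 7.854757 ...
#' @export
solve_eigenvalues <- function(n_modes, tol = 1e-12) {
  if (!is.numeric(n_modes) || length(n_modes) != 1L || !is.finite(n_modes) ||
    n_modes < 1 || n_modes != round(n_modes)) {
    stop("n_modes must be a positive integer", call. = FALSE)
  }
  n_modes <- as.integer(n_modes)
  vapply(seq_len(n_modes), function(j) {
    centre <- (2 * j - 1) * pi / 2
    if (j == 1L) {
      lo <- 1.0
      hi <- 3.0
    } else {
      lo <- centre - 0.5
      hi <- centre + 0.5
    }
    flo <- characteristic_residual(lo)
    fhi <- characteristic_residual(hi)
    if (!(flo * fhi < 0)) {
      stop(sprintf(
        "eigenvalue bracketing failed for mode %d: f(%g)=%g, f(%g)=%g",
        j, lo, flo, hi, fhi
      ), call. = FALSE)
    }
    root <- stats::uniroot(characteristic_residual,
      lower = lo, upper = hi,
      tol = min(tol, 1e-12)
    )$root
    # Newton polish: residual derivative is O(1) near every root, so two
    # steps reach the floating-point floor of the residual
    for (i in 1:3) {
      f <- characteristic_residual(root)
      fp <- -sin(root) - sech_safe(root) * tanh(root)
      step <- f / fp
      if (!is.finite(step)) break
      root <- root - step
      if (abs(step) < 1e-15) break
    }
    root
  }, numeric(1))
}

#' Mode-shape coefficient sigma
#'
#' The clamped-free mode shape is
#' Y(x)/C = cosh(k x) - cos(k x) - sigma (sinh(k x) - sin(k x)) with
#' sigma(beta) = (sinh beta - sin beta) / (cosh beta + cos beta), the ratio
#' fixed by the free-end boundary conditions. For the first eigenvalue the
#' coefficient is 0.7341; sigma -> 1 as beta grows.
#'
#' For beta >= 20 the hyperbolic terms are rescaled by e^{-beta} so the
#' ratio never overflows.
#'
#' @param beta Positive dimensionless eigenvalue(s).
#' @return sigma(beta), vectorised.
#' @examples
#' sigma_coefficient(1.875104) # 0.7341
#' @export
sigma_coefficient <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta must be finite and strictly positive", call. = FALSE)
  }
  ifelse(
    beta < 20,
    (sinh(beta) - sin(beta)) / (cosh(beta) + cos(beta)),
    {
      e <- exp(-beta)
      ((1 - e * e) - 2 * e * sin(beta)) / ((1 + e * e) + 2 * e * cos(beta))
    }
  )
}

# 1 - sigma(beta), computed without cancellation:
# (e^{-beta} + cos beta + sin beta) / (cosh beta + cos beta), with the
# denominator rescaled by e^{-beta} for large beta.
one_minus_sigma <- function(beta) {
  e <- exp(-beta)
  num <- e + cos(beta) + sin(beta)
  if (beta < 20) {
    num / (cosh(beta) + cos(beta))
  } else {
    num * (2 * e) / ((1 + e * e) + 2 * e * cos(beta))
  }
}

#' Cantilever mode shape
#'
#' Evaluates the normalised clamped-free mode shape
#' Y(xi l)/C = cosh(beta xi) - cos(beta xi) - sigma(beta) (sinh(beta xi) -
#' sin(beta xi)) at relative position xi = x/l in \[0, 1\]. The growing
#' combination cosh(a) - sigma sinh(a) is assembled as
#' ((1 - sigma) e^a + (1 + sigma) e^{-a}) / 2 with 1 - sigma computed in a
#' cancellation-free form, so the shape stays accurate for high modes where
#' sigma is exponentially close to 1.
#'
#' @param beta Positive eigenvalue of the characteristic equation (scalar).
#' @param xi Relative position(s) x/l in \[0, 1\].
#' @return Dimensionless shape value(s) Y/C.
#' @examples
#' b1 <- solve_eigenvalues(1)
#' mode_shape(b1, 0) # 0 (clamped root)
#' mode_shape(b1, 1) # 2.000 (free tip)
#' @export
mode_shape <- function(beta, xi) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
    beta <= 0) {
    stop("beta must be a positive finite scalar", call. = FALSE)
  }
  if (!is.numeric(xi) || any(!is.finite(xi)) || any(xi < 0) || any(xi > 1)) {
    stop("xi must lie in [0, 1]", call. = FALSE)
  }
  sig <- sigma_coefficient(beta)
  oms <- one_minus_sigma(beta)
  a <- beta * xi
  # cosh(a) - sigma*sinh(a) without catastrophic cancellation at large a
  hyper <- (oms * exp(a) + (1 + sig) * exp(-a)) / 2
  out <- hyper - cos(a) + sig * sin(a)
  out[a == 0] <- 0 # clamped root is exact
  out
}

#' Natural angular frequency of a mode
#'
#' p_n = k_n^2 sqrt(E Iz / (rho A)) with k_n = beta_n / l: the angular
#' frequency (rad/s) of mode n of the uniform cantilever.
#'
#' @param beta Positive dimensionless eigenvalue(s) beta_n.
#' @param beam A [beam_section()].
#' @return Angular frequency (rad/s), vectorised over `beta`.
#' @export
natural_frequency <- function(beta, beam) {
  stopifnot(inherits(beam, "beam_section"))
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta must be finite and strictly positive", call. = FALSE)
  }
  (beta / beam$length_l)^2 *
    sqrt(beam$young_E * beam$inertia_Iz /
      (beam$density_rho * beam$section_area))
}

#' Excitation amplitude from a tip force
#'
#' A point force F at the free tip deflects the cantilever statically by
#' F l^3 / (3 E Iz); since the first mode shape reaches 2.000 at the tip,
#' the modal amplitude constant is C = F l^3 / (6 E Iz). The phase defaults
#' to pi/2 so that at t = 0 the beam sits at the static deflection shape
#' with zero velocity — release from rest after the combing force is
#' removed.
#'
#' @param tip_force_F Tip force F (N), non-negative.
#' @param beam A [beam_section()].
#' @param phase_phi Phase angle phi (rad). Default `pi/2`.
#' @return An object of class `excitation_amplitude` with fields
#'   `tip_force_F`, `amplitude_C` (m) and `phase_phi`.
#' @export
amplitude_from_tip_force <- function(tip_force_F, beam, phase_phi = pi / 2) {
  stopifnot(inherits(beam, "beam_section"))
  if (!is.numeric(tip_force_F) || length(tip_force_F) != 1L ||
    !is.finite(tip_force_F) || tip_force_F < 0) {
    stop("tip_force_F must be a finite non-negative scalar", call. = FALSE)
  }
  if (!is.numeric(phase_phi) || length(phase_phi) != 1L ||
    !is.finite(phase_phi)) {
    stop("phase_phi must be a finite scalar", call. = FALSE)
  }
  structure(
    list(
      tip_force_F = tip_force_F,
      amplitude_C = tip_force_F * beam$length_l^3 /
        (6 * beam$young_E * beam$inertia_Iz),
      phase_phi = phase_phi
    ),
    class = "excitation_amplitude"
  )
}

#' @export
print.excitation_amplitude <- function(x, ...) {
  cat("<excitation_amplitude>\n")
  cat(sprintf("  tip force F = %g N\n", x$tip_force_F))
  cat(sprintf("  amplitude C = F l^3 / (6 E Iz) = %g m\n", x$amplitude_C))
  cat(sprintf("  phase phi   = %g rad\n", x$phase_phi))
  invisible(x)
}

#' Mode table for a beam
#'
#' Solves the first `n_modes` eigenvalues and tabulates, per mode, the
#' dimensionless root beta, wavenumber k = beta/l (1/m), shape coefficient
#' sigma and angular frequency omega_p (rad/s).
#'
#' @param beam A [beam_section()].
#' @param n_modes Number of modes (positive integer).
#' @return A data.frame with columns `mode_index`, `beta`, `wavenumber_k`,
#'   `sigma`, `omega_p`.
#' @examples
#' b <- beam_section(350e-6, 2.5e9, 1150, 2e-10, 1.7e-21)
#' mode_table(b, 3)
#' @export
mode_table <- function(beam, n_modes = 6) {
  stopifnot(inherits(beam, "beam_section"))
  beta <- solve_eigenvalues(n_modes)
  data.frame(
    mode_index = seq_along(beta),
    beta = beta,
    wavenumber_k = beta / beam$length_l,
    sigma = sigma_coefficient(beta),
    omega_p = natural_frequency(beta, beam)
  )
}
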