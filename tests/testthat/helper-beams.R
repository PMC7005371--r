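# shared fixtures: beams built in code, no files

# unit-parameter beam: E = Iz = rho = A = l = 1, so omega_n = beta_n^2
unit_beam <- function() {
  beam_section(
    length_l = 1, young_E = 1, density_rho = 1,
    section_area = 1, inertia_Iz = 1
  )
}

# pigeon-scale barbule as a uniform root-section beam
barbule_beam <- function(length_l = 350e-6, thickness = 10e-6,
                         width = 20e-6, E = 2.5e9, rho = 1150) {
  beam_section(
    length_l = length_l, young_E = E, density_rho = rho,
    section_area = width * thickness,
    inertia_Iz = width * thickness^3 / 12
  )
}

# random tapered beam + air load drawn on log scales (physical magnitudes)
random_tapered <- function() {
  tapered_beam(
    length_l = exp(runif(1, log(1e-4), log(1e-1))),
    root_thickness_t = exp(runif(1, log(1e-6), log(1e-3))),
    width_w = exp(runif(1, log(1e-6), log(1e-3))),
    young_E = exp(runif(1, log(1e8), log(1e11)))
  )
}

random_air_load <- function() {
  air_load(
    bird_mass_m = exp(runif(1, log(0.05), log(5))),
    gravity_g = 9.81,
    wing_body_area_A = exp(runif(1, log(0.01), log(1)))
  )
}

# one-sided finite-difference estimate of the m-th derivative of f at x0
# using np points x0, x0 + s*h, ..., x0 + (np-1)*s*h (s = -1 for backward).
# Weights from the Taylor moment system in units of h (Fornberg-style).
fd_one_sided <- function(f, x0, m, h, side = -1, np = m + 5) {
  nodes <- side * (0:(np - 1))
  A <- t(vapply(0:(np - 1), function(k) nodes^k / factorial(k), numeric(np)))
  rhs <- as.numeric(0:(np - 1) == m)
  w <- solve(A, rhs) / h^m
  sum(w * vapply(nodes, function(s) f(x0 + s * h), numeric(1)))
}

# Table of printed characteristic-equation roots
printed_roots <- c(
  1.875104, 4.694091, 7.854757, 10.995541, 14.137168, 17.278759
)
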