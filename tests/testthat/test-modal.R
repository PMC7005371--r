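test_that("characteristic residual vanishes at tabulated roots and is 2 at zero", {
  expect_lt(abs(characteristic_residual(1.875104)), 1e-5)
  expect_lt(abs(characteristic_residual(4.694091)), 1e-5)
  expect_identical(characteristic_residual(0), 2)
  expect_error(characteristic_residual(-1), "non-negative")
})

test_that("residual is overflow-safe for very large beta", {
  big <- c(100, 710, 5000)
  expect_true(all(is.finite(characteristic_residual(big))))
  # sech term is negligible there: residual ~ cos(beta)
  expect_equal(characteristic_residual(big), cos(big), tolerance = 1e-12)
})

test_that("eigenvalues reproduce the printed table and the asymptote", {
  beta <- solve_eigenvalues(6)
  expect_equal(beta, printed_roots, tolerance = 1e-6)
  expect_lt(max(abs(beta - printed_roots)), 1e-6)
  expect_equal(solve_eigenvalues(1), 1.875104, tolerance = 1e-6)
  # 7th root sits within 1e-4 of the cosine zero 13*pi/2 (sech decay);
  # frozen brute-force bisection value for the 7th root:
  b7_bisect <- local({
    f <- function(b) cos(b) + 1 / cosh(b)
    lo <- 20.0
    hi <- 20.8
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  })
  b7 <- solve_eigenvalues(7)[7]
  expect_equal(b7, b7_bisect, tolerance = 1e-12)
  expect_lt(abs(b7 - 13 * pi / 2), 1e-4)
})

test_that("eigenvalue sequence obeys the solver's structural guarantees", {
  beta <- solve_eigenvalues(12)
  # strictly increasing, residual at machine level, determinant form small
  expect_true(all(diff(beta) > 0))
  expect_true(all(abs(characteristic_residual(beta)) < 1e-12))
  det_resid <- abs(cos(beta) * cosh(beta) + 1)
  expect_true(all(det_resid[1:5] < 1e-8))
  # higher modes: bound set by the conditioning of the cosh-amplified form
  cond_bound <- 4 * .Machine$double.eps * beta * cosh(beta)
  expect_true(all(det_resid < pmax(cond_bound, 1e-10)))
  # gap to the cosine zeros alternates in sign and shrinks like 2 e^{-beta}
  gap <- beta - (2 * seq_along(beta) - 1) * pi / 2
  # |gap| ~ sech(beta) < 2 e^{-beta}; allow rounding slack of a few ulps
  expect_true(all(
    abs(gap[-1]) <= 2 * exp(-beta[-1]) +
      8 * .Machine$double.eps * beta[-1]
  ))
  expect_true(all(diff(sign(gap)) != 0))
  # |beta_n - (2n-1)pi/2| shrinks monotonically with mode number
  expect_true(all(diff(abs(gap)) < 0))
})

test_that("eigenvalues are invariant under solver tolerance tightening", {
  loose <- solve_eigenvalues(6, tol = 1e-10)
  tight <- solve_eigenvalues(6, tol = 1e-14)
  expect_equal(round(loose, 6), round(tight, 6))
})

test_that("sigma coefficient matches the printed value, its limits, and a high-precision oracle", {
  b <- solve_eigenvalues(2)
  expect_equal(round(sigma_coefficient(b[1]), 4), 0.7341)
  # small-beta limit: sinh-sin ~ b^3/3, cosh+cos ~ 2 -> sigma -> 0
  expect_lt(sigma_coefficient(1e-4), 1e-10)
  # frozen extended-precision oracle for
  # (sinh(b2)-sin(b2))/(cosh(b2)+cos(b2)) at b2 = 4.6940911329741746:
  expect_equal(sigma_coefficient(4.6940911329741746), 1.0184673187592194,
    tolerance = 1e-10
  )
  # large beta: sigma -> 1 from above/below without overflow
  expect_equal(sigma_coefficient(50), 1, tolerance = 1e-12)
  expect_true(is.finite(sigma_coefficient(2000)))
})

test_that("mode shape satisfies all four clamped-free boundary conditions", {
  h <- 5e-3
  for (beta in solve_eigenvalues(6)) {
    shape <- function(xi) mode_shape(beta, xi)
    amp <- max(abs(shape(seq(0, 1, length.out = 201))))
    # clamped root: zero value and slope (derivative scale amp * beta^m)
    expect_identical(shape(0), 0)
    slope0 <- fd_one_sided(shape, 0, m = 1, h = h, side = +1)
    expect_lt(abs(slope0) / (amp * beta), 1e-5)
    # free tip: zero bending moment (Y'') and zero shear (Y''')
    d2 <- fd_one_sided(shape, 1, m = 2, h = h, side = -1)
    expect_lt(abs(d2) / (amp * beta^2), 1e-5)
    d3 <- fd_one_sided(shape, 1, m = 3, h = h, side = -1)
    expect_lt(abs(d3) / (amp * beta^3), 1e-5)
  }
})

test_that("first-mode tip value and stability properties hold", {
  b1 <- solve_eigenvalues(1)
  expect_equal(round(mode_shape(b1, 1), 3), 2.000)
  # bit-stable across repeated calls
  xi <- seq(0, 1, length.out = 17)
  expect_identical(mode_shape(b1, xi), mode_shape(b1, xi))
  # high mode: tip value is (-1)^{n+1} * 2 within exponential error, and
  # the exponential-difference assembly stays finite where naive
  # cosh - sigma*sinh would lose all digits
  b10 <- solve_eigenvalues(10)[10]
  expect_equal(abs(mode_shape(b10, 1)), 2, tolerance = 1e-6)
  expect_true(all(is.finite(mode_shape(b10, xi))))
  expect_error(mode_shape(b1, 1.5), "\\[0, 1\\]")
})

test_that("natural frequency follows the dispersion relation and its scalings", {
  b1 <- solve_eigenvalues(1)
  expect_equal(natural_frequency(b1, unit_beam()), b1^2)
  expect_lt(
    abs(natural_frequency(1.875104, unit_beam()) - 3.516015), 1e-5
  )
  beam <- barbule_beam()
  f0 <- natural_frequency(b1, beam)
  doubled <- barbule_beam(length_l = 2 * 350e-6)
  expect_equal(natural_frequency(b1, doubled), f0 / 4)
  stiff <- beam_section(
    beam$length_l, 4 * beam$young_E, beam$density_rho,
    beam$section_area, beam$inertia_Iz
  )
  expect_equal(natural_frequency(b1, stiff), 2 * f0)
})

test_that("tip-force amplitude follows C = F l^3 / (6 E Iz)", {
  expect_identical(
    amplitude_from_tip_force(0, unit_beam())$amplitude_C, 0
  )
  expect_equal(amplitude_from_tip_force(6, unit_beam())$amplitude_C, 1)
  # consistency with the static tip deflection: C * Y(l)/C = F l^3/(3 E Iz)
  beam <- barbule_beam()
  F <- 2.3e-6
  C <- amplitude_from_tip_force(F, beam)$amplitude_C
  b1 <- solve_eigenvalues(1)
  expect_equal(
    C * mode_shape(b1, 1),
    point_load_deflection(beam, F),
    tolerance = 1e-4
  )
  expect_equal(amplitude_from_tip_force(1, unit_beam())$phase_phi, pi / 2)
})

test_that("mode table carries consistent derived columns", {
  beam <- barbule_beam()
  tab <- mode_table(beam, 4)
  expect_equal(tab$mode_index, 1:4)
  expect_equal(tab$wavenumber_k, tab$beta / beam$length_l)
  expect_equal(tab$omega_p, natural_frequency(tab$beta, beam))
  expect_equal(tab$sigma, sigma_coefficient(tab$beta))
})

test_that("invalid beam sections are rejected", {
  expect_error(beam_section(-1, 1, 1, 1, 1), "positive")
  expect_error(beam_section(1, 1, 0, 1, 1), "positive")
  expect_error(solve_eigenvalues(0), "positive integer")
})
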