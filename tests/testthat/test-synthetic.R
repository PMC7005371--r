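degenerate_config <- function(seed = 1L) {
  generator_config(
    seed = seed,
    n_barbs_range = c(3L, 3L),
    barbules_per_barb_range = c(4L, 4L),
    barb_length_range = c(20e-3, 20e-3),
    barb_thickness_range = c(250e-6, 250e-6),
    barbule_length_range = c(350e-6, 350e-6),
    barbule_thickness_range = c(10e-6, 10e-6)
  )
}

# fingerprint of a generated structure, for inequality checks
feather_fingerprint <- function(f) {
  list(
    n = length(f$barbs),
    lens = unlist(lapply(f$barbs, function(b) b$tapered_beam$length_l))
  )
}

test_that("generation is a pure function of the configuration", {
  cfg <- generator_config(seed = 42L)
  f1 <- generate_feather(cfg)
  f2 <- generate_feather(cfg)
  expect_identical(f1, f2)
  expect_identical(summarize_feather(f1), summarize_feather(f2))
  # a different seed changes the sample
  f3 <- generate_feather(generator_config(seed = 43L))
  expect_false(identical(
    feather_fingerprint(f1), feather_fingerprint(f3)
  ))
  # the caller's RNG stream is not consumed
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generate_feather(cfg))
  expect_identical(runif(3), before)
})

test_that("degenerate ranges collapse to the stated dimensions and counts", {
  f <- generate_feather(degenerate_config())
  expect_length(f$barbs, 3L)
  for (barb in f$barbs) {
    expect_equal(barb$tapered_beam$length_l, 20e-3)
    expect_equal(barb$tapered_beam$root_thickness_t, 250e-6)
    expect_length(barb$barbules, 4L)
    for (bbl in barb$barbules) {
      expect_equal(bbl$tapered_beam$length_l, 350e-6)
      expect_equal(bbl$tapered_beam$root_thickness_t, 10e-6)
      expect_equal(bbl$beam_section$section_area, 20e-6 * 10e-6)
      expect_equal(bbl$beam_section$inertia_Iz, 20e-6 * (10e-6)^3 / 12)
    }
  }
})

test_that("configured counts are honored exactly", {
  cfg <- generator_config(
    seed = 5L,
    n_barbs_range = c(10L, 10L),
    barbules_per_barb_range = c(20L, 20L)
  )
  f <- generate_feather(cfg)
  expect_length(f$barbs, 10L)
  expect_identical(
    sum(vapply(f$barbs, function(b) length(b$barbules), integer(1))), 200L
  )
})

test_that("generated feathers respect the hierarchy and feed both models cleanly", {
  for (seed in c(1L, 2L, 3L)) {
    f <- generate_feather(generator_config(seed = seed))
    barb_lengths <- vapply(
      f$barbs, function(b) b$tapered_beam$length_l, numeric(1)
    )
    bbl_lengths <- unlist(lapply(f$barbs, function(b) {
      vapply(b$barbules, function(u) u$tapered_beam$length_l, numeric(1))
    }))
    expect_gt(min(barb_lengths), max(bbl_lengths))
    # pipeline closure: every barbule passes the modal and static stages
    s <- summarize_feather(f)
    expect_equal(nrow(s), length(bbl_lengths))
    expect_true(all(is.finite(s$omega_p1)))
    expect_true(all(s$omega_p1 > 0))
    expect_true(all(is.finite(s$delta_max)))
    expect_true(all(s$delta_max > 0))
  }
})

test_that("inconsistent configurations are rejected before sampling", {
  expect_error(
    generator_config(n_barbs_range = c(5L, 2L)), "lo <= hi"
  )
  expect_error(
    generator_config(barb_length_range = c(-1, 1)), "lo <= hi"
  )
  expect_error(
    generator_config(
      barbule_length_range = c(1e-3, 20e-3),
      barb_length_range = c(15e-3, 30e-3)
    ),
    "hierarchy"
  )
  expect_error(generator_config(young_E = -1), "positive")
})

test_that("feather summary is ordered, consistent, and scales with length", {
  f <- generate_feather(degenerate_config())
  s <- summarize_feather(f)
  expect_equal(
    s[, c("barb_index", "barbule_index")],
    s[order(s$barb_index, s$barbule_index), c("barb_index", "barbule_index")]
  )
  # identical barbules -> identical derived quantities
  expect_equal(length(unique(s$omega_p1)), 1L)
  expect_equal(length(unique(s$delta_max)), 1L)
  # summary row matches a direct single-beam computation
  sec <- f$barbs[[1]]$barbules[[1]]$beam_section
  tb <- f$barbs[[1]]$barbules[[1]]$tapered_beam
  b1 <- solve_eigenvalues(1)
  expect_equal(s$omega_p1[1], natural_frequency(b1, sec))
  expect_equal(s$delta_max[1], deflection_tapered(tb, f$load, tb$length_l))
  expect_equal(
    s$vmax_per_C[1],
    tip_kinematics(vibration_field(sec, 1))$v_max /
      amplitude_from_tip_force(1, sec)$amplitude_C,
    tolerance = 1e-12
  )
  # halving every barbule length at fixed material -> omega_p1 x 4
  half <- generate_feather(generator_config(
    seed = 1L,
    n_barbs_range = c(3L, 3L), barbules_per_barb_range = c(4L, 4L),
    barb_length_range = c(20e-3, 20e-3),
    barb_thickness_range = c(250e-6, 250e-6),
    barbule_length_range = c(175e-6, 175e-6),
    barbule_thickness_range = c(10e-6, 10e-6)
  ))
  s_half <- summarize_feather(half)
  expect_equal(s_half$omega_p1, 4 * s$omega_p1, tolerance = 1e-12)
})

test_that("an empty feather yields an empty summary with the full header", {
  f <- generate_feather(degenerate_config())
  f$barbs <- list()
  s <- summarize_feather(f)
  expect_equal(nrow(s), 0L)
  expect_true(all(c(
    "barb_index", "barbule_index", "length_l", "omega_p1", "vmax_per_C",
    "delta_max", "linearity_warning"
  ) %in% names(s)))
})
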