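# Sphere contact model: forward/inverse relations and their limits.

test_that("indentation-contact radius relations are mutual inverses", {
  R <- 3.31
  expect_identical(indentation_from_contact_radius(0, R), 0)
  expect_identical(contact_radius_from_indentation(0, R), 0)

  # closed form at a = 1 um, frozen from a 40-digit independent evaluation
  expect_equal(indentation_from_contact_radius(1, R),
               0.31184518979097712, tolerance = 1e-14)

  # small-contact limit: delta ~ a^2 / R within 1% for a/R <= 0.05
  a <- seq(1e-3, 0.05, length.out = 20) * R
  d <- indentation_from_contact_radius(a, R)
  expect_lt(max(abs(d - a^2 / R) / d), 0.01)

  # round trip over the whole physical range
  dd <- 10^seq(log10(1e-4), log10(2), length.out = 100)
  aa <- contact_radius_from_indentation(dd, R)
  expect_lt(max(abs(indentation_from_contact_radius(aa, R) - dd) / dd), 1e-9)
  expect_true(all(diff(aa) > 0))  # monotone in delta

  # inverse over a/R in [1e-4, 0.999]
  a2 <- c(1e-4, 0.01, 0.1, 0.5, 0.9, 0.99, 0.999) * R
  d2 <- indentation_from_contact_radius(a2, R)
  expect_lt(max(abs(contact_radius_from_indentation(d2, R) - a2) / a2), 1e-9)

  # large indentation (delta = R): a stays strictly below R
  a_big <- contact_radius_from_indentation(R, R)
  expect_lt(a_big, R)
  expect_gt(a_big, 0.8 * R)
  # and keeps approaching R as delta grows
  expect_gt(contact_radius_from_indentation(5 * R, R), 0.95 * R)
})

test_that("domain errors are raised for invalid geometry", {
  expect_error(indentation_from_contact_radius(-0.1, 3.31))
  expect_error(indentation_from_contact_radius(3.31, 3.31))
  expect_error(indentation_from_contact_radius(4, 3.31))
  expect_error(contact_radius_from_indentation(-1, 3.31))
  expect_error(probe_geometry(radius_um = -1))
  expect_error(material_params(-2))
  expect_error(material_params(2, poisson_ratio = 0.7))
})

test_that("spherical load matches its independent high-precision oracle", {
  m <- material_params(5, 0.5)
  p <- probe_geometry(3.31)
  expect_identical(sneddon_force(0, m, p), 0)
  # frozen: bisection for a at delta = 0.5 um + closed form, 40 digits
  expect_equal(sneddon_force(0.5, m, p), 5.6311262212071080, tolerance = 1e-12)
  expect_equal(hertz_force(0.5, m, p), 5.7176357023416032, tolerance = 1e-12)

  # linear in E: doubling the modulus doubles the load
  m2 <- material_params(10, 0.5)
  expect_equal(sneddon_force(0.5, m2, p), 2 * sneddon_force(0.5, m, p))
  # and scales with 1/(1 - nu^2)
  m0 <- material_params(5, 0)
  expect_equal(sneddon_force(0.5, m, p) / sneddon_force(0.5, m0, p),
               1 / (1 - 0.25), tolerance = 1e-12)

  # strictly increasing and convex in depth
  d <- seq(0.05, 2, length.out = 50)
  P <- sneddon_force(d, m, p)
  expect_true(all(P > 0))
  expect_true(all(diff(P) > 0))
  expect_true(all(diff(diff(P)) > 0))
})

test_that("parabolic limit agrees at small depth and bounds at large depth", {
  m <- material_params(3, 0.5)
  p <- probe_geometry(3.31)
  # within 1% for delta/R <= 0.01
  d <- seq(1e-4, 0.01, length.out = 25) * p$radius_um
  rel <- abs(sneddon_force(d, m, p) - hertz_force(d, m, p)) / hertz_force(d, m, p)
  expect_lt(max(rel), 0.01)
  # the sphere is blunter than the paraboloid at depth: lower load
  d3 <- 0.3 * p$radius_um
  expect_lt(sneddon_force(d3, m, p), hertz_force(d3, m, p))
})

test_that("unit system is pinned: kPa x um^2 evaluates to nN", {
  # with E in Pa and lengths in m the load is in N; the reporting-unit
  # identity 1 kPa * 1 um^2 = 1e-9 N = 1 nN must hold exactly
  m <- material_params(7, 0.5)
  p <- probe_geometry(3.31)
  delta_m <- 0.4e-6
  R_m <- 3.31e-6
  a_m <- 3.31e-6 * contact_radius_from_indentation(0.4, 3.31) / 3.31
  P_si <- 7e3 / (1 - 0.25) *
    (((R_m^2 + a_m^2) / 2) * log((R_m + a_m) / (R_m - a_m)) - a_m * R_m)
  expect_equal(sneddon_force(0.4, m, p), P_si / 1e-9, tolerance = 1e-12)
})

test_that("depths beyond twice the probe radius are flagged", {
  m <- material_params(2, 0.5)
  p <- probe_geometry(3.31)
  expect_warning(sneddon_force(2.1 * p$radius_um, m, p), "twice the probe")
  expect_silent(sneddon_force(1.9 * p$radius_um, m, p))
})
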