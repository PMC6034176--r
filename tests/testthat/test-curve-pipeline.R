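# Per-curve pipeline: force/indentation conversion, contact-point
# estimation, modulus fitting.

test_that("force-indentation conversion behaves on limiting curves", {
  calib <- nominal_calib()
  # rigid substrate: deflection equals piezo travel, indentation ~ 0
  cur <- rigid_calibration_curve(sens_nm_per_v = calib$sensitivity_nm_per_v)
  j <- which(cur$piezo_height_um <= 0)[1]
  fi <- to_force_indentation(cur, calib, j)
  expect_lt(max(abs(fi$indentation_um)), 1e-9)
  expect_true(all(diff(fi$force_nn) > 0))

  # free part of a curve converts to ~ zero force
  sim <- simulate_force_curve(3, seed = 1, noise_fraction = 0)
  arr_free <- to_force_indentation(sim$curve, sim$calib, 5L)
  free_part <- head(arr_free$force_nn, 50)
  expect_lt(max(abs(free_part)), 1e-6)
})

test_that("conversion reproduces the generating contact model", {
  # contact placed exactly on a sample: ramp step chosen dyadic
  # (31.25/2000 = 2^-6 um) and the free travel an exact multiple of it,
  # so the discrete contact index is the true contact point
  sim <- simulate_force_curve(3, seed = 1, noise_fraction = 0,
                              speed_um_per_s = 31.25,
                              free_travel_um = 180 * 0.015625)
  j <- sim$true_contact_index - 1L  # the sample exactly at contact
  cur <- sim$curve
  expect_equal(cur$piezo_height_um[j], 0, tolerance = 1e-9)
  fi <- to_force_indentation(cur, sim$calib, j)
  keep <- fi$indentation_um > 1e-4
  pred <- sneddon_force(fi$indentation_um[keep], material_params(3),
                        sim$probe)
  expect_equal(fi$force_nn[keep], pred, tolerance = 1e-6)
})

test_that("missing deflection unit tag is refused", {
  sim <- simulate_force_curve(3, seed = 1)
  cur <- sim$curve
  cur$deflection_unit <- NULL
  expect_error(to_force_indentation(cur, sim$calib, 100L), "unit tag")
})

test_that("contact point is found exactly on noise-free curves", {
  for (e in c(1, 2, 4, 8)) {
    sim <- simulate_force_curve(e, seed = 1, noise_fraction = 0)
    cp <- estimate_contact_point(sim$curve, sim$calib, sim$probe)
    expect_lte(abs(cp$index - sim$true_contact_index), 1)
  }
})

test_that("contact point is robust to deflection noise", {
  errs <- vapply(1:100, function(s) {
    sim <- simulate_force_curve(4, seed = s, noise_fraction = 0.02)
    cp <- estimate_contact_point(sim$curve, sim$calib, sim$probe)
    abs(cp$index - sim$true_contact_index)
  }, numeric(1))
  expect_lte(median(errs), 3)
})

test_that("curves without a distinguishable free region error out", {
  # a pure linear ramp: the probe is on a rigid surface for the whole
  # record, there is no free baseline to separate from contact
  z <- seq(8, by = -0.0166, length.out = 400)
  v <- (10 - z) * 1000 / 15.2
  cur <- force_curve(z, v, deflection_unit = "V")
  expect_error(estimate_contact_point(cur, nominal_calib(), nominal_probe()))
})

test_that("modulus is recovered exactly from noise-free curves", {
  for (e in c(1, 5)) {
    res <- fit_single(e, seed = 2, noise_fraction = 0)
    expect_equal(res$fit$young_modulus_kpa, e, tolerance = 0.01)
    expect_equal(res$fit$force_at_deepest_nn, 1, tolerance = 1e-6)
    expect_lt(res$fit$rms_residual_nn, 1e-4)
  }
})

test_that("robust and least-squares fits agree on clean curves", {
  rob <- fit_single(4, seed = 3, noise_fraction = 0, robust = TRUE)
  ls <- fit_single(4, seed = 3, noise_fraction = 0, robust = FALSE)
  expect_equal(rob$fit$young_modulus_kpa, ls$fit$young_modulus_kpa,
               tolerance = 0.01)
})

test_that("too few contact samples raise a short-fit error", {
  sim <- simulate_force_curve(4, seed = 1)
  n <- sum(sim$curve$segment == "approach")
  expect_error(
    fit_young_modulus(sim$curve, sim$calib, sim$probe, n - 1L),
    "contact samples")
})

test_that("a rigid-substrate curve fits far above the dish threshold", {
  # simulate a dish point: very stiff material under the mapping settings
  sim <- simulate_force_curve(2000, seed = 4, noise_fraction = 0)
  cp <- estimate_contact_point(sim$curve, sim$calib, sim$probe)
  f <- fit_young_modulus(sim$curve, sim$calib, sim$probe, cp$index,
                         set_point_nn = 1)
  expect_gt(f$young_modulus_kpa, 10)
  f <- apply_qc_filters(f)
  expect_true("substrate_stiff" %in% f$qc_flags)
  expect_false(f$accepted)
})
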