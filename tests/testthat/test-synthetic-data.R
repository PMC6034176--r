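# Phantom rendering, force-map simulation and the exchange archive.

test_that("phantom rendering matches the closed-form cap geometry", {
  spec <- phantom_spec(seed = 1, n_rows = 32, n_cols = 32,
                       cell_radius_um = 30, cell_peak_um = 4)
  ph <- render_phantom(spec, 0)
  rb <- 30; h <- 4; Rs <- (rb^2 + h^2) / (2 * h)
  r <- sqrt((ph$x_um - 50)^2 + (ph$y_um - 50)^2)
  expected <- ifelse(r < rb, sqrt(pmax(Rs^2 - r^2, 0)) - (Rs - h), 0)
  expect_equal(ph$height_um, expected, tolerance = 1e-12)
})

test_that("degenerate phantom options behave trivially", {
  # nucleus covering the whole footprint, no ring/fibers: uniform cell E
  spec <- phantom_spec(seed = 1, n_rows = 16, n_cols = 16,
                       nucleus_fraction = 1, nucleus_e_kpa = 3,
                       periphery_e_kpa = 5)
  ph <- render_phantom(spec, 0)
  cell <- ph$height_um > 0
  expect_true(all(ph$e_kpa[cell] == 3))
  # t = 0 applies no decay even with a decay profile configured
  spec2 <- phantom_spec(seed = 1, n_rows = 16, n_cols = 16,
                        decay = list(final_fraction = 0.4, tau_min = 25))
  ph2 <- render_phantom(spec2, 0)
  cell2 <- ph2$height_um > 0
  expect_equal(max(ph2$e_kpa[cell2]), spec2$periphery_e_kpa)
  # geometry exceeding the extent errors
  expect_error(phantom_spec(seed = 1, extent_um = c(40, 40),
                            cell_radius_um = 30), "exceeds")
})

test_that("simulated indentation depths are physically plausible", {
  # at the nominal settings (R = 3.31 um, set point 1 nN), cell moduli of
  # 1-8 kPa indent a few tenths of a micron; each simulated depth must
  # match the analytic depth at which the contact model reaches 1 nN
  moduli <- c(1, 2, 4, 8)
  depths <- vapply(moduli, function(e) {
    res <- fit_single(e, seed = 5, noise_fraction = 0)
    res$fit$max_indentation_um
  }, numeric(1))
  analytic <- vapply(moduli, function(e) {
    f <- function(d) sneddon_force(d, material_params(e), nominal_probe()) - 1
    uniroot(f, c(1e-4, 3), tol = 1e-10)$root
  }, numeric(1))
  expect_equal(depths, analytic, tolerance = 0.02)
  expect_true(all(depths > 0.1 & depths < 1.6))
  expect_true(all(diff(depths) < 0))  # stiffer -> shallower
})

test_that("the set-point trigger truncates the approach", {
  sim <- simulate_force_curve(4, seed = 2, noise_fraction = 0)
  fi <- to_force_indentation(sim$curve, sim$calib, sim$true_contact_index)
  expect_equal(max(fi$force_nn), 1, tolerance = 0.02)
})

test_that("an unreachable set point is flagged", {
  spec <- phantom_spec(seed = 3, n_rows = 2, n_cols = 2,
                       extent_um = c(30, 30), cell_center_um = c(15, 15),
                       cell_radius_um = 12, cell_peak_um = 2,
                       nucleus_fraction = 1, nucleus_e_kpa = 0.005,
                       periphery_e_kpa = 0.005, z_length_um = 8,
                       noise_fraction = 0)
  map <- simulate_force_map(spec, 0)
  tr <- attr(map, "truth")
  cell <- tr$compartment != "substrate"
  expect_true(any(tr$set_point_unreached[cell]))
})

test_that("identical spec and seed reproduce a byte-identical archive", {
  spec <- phantom_spec(seed = 7, n_rows = 6, n_cols = 6,
                       extent_um = c(60, 60), cell_radius_um = 20)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_force_map(simulate_force_map(spec, 0), f1)
  write_force_map(simulate_force_map(spec, 0), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("the exchange archive round trip is bit-exact", {
  spec <- phantom_spec(seed = 8, n_rows = 5, n_cols = 4,
                       extent_um = c(60, 60), cell_radius_um = 20,
                       noise_fraction = 0.02)
  map <- simulate_force_map(spec, 15)
  path <- tempfile(fileext = ".tsv")
  write_force_map(map, path)
  back <- read_force_map(path)
  expect_identical(back$n_rows, map$n_rows)
  expect_identical(back$n_cols, map$n_cols)
  expect_identical(back$extent_um, map$extent_um)
  expect_identical(back$set_point_nn, map$set_point_nn)
  expect_identical(back$timestamp_min, map$timestamp_min)
  for (li in seq_along(map$curves)) {
    expect_identical(back$curves[[li]]$piezo_height_um,
                     map$curves[[li]]$piezo_height_um)
    expect_identical(back$curves[[li]]$deflection,
                     map$curves[[li]]$deflection)
    expect_identical(back$curves[[li]]$segment, map$curves[[li]]$segment)
  }
  unlink(path)
})

test_that("phantom specs round trip through their text serialisation", {
  spec <- phantom_preset("dmso-like", seed = 9, n_rows = 12, n_cols = 12)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back, spec)
  unlink(path)
})

test_that("simulation is reproducible but differs across timepoints", {
  spec <- phantom_spec(seed = 10, n_rows = 4, n_cols = 4,
                       extent_um = c(40, 40), cell_radius_um = 15)
  m1 <- simulate_force_map(spec, 30)
  m2 <- simulate_force_map(spec, 30)
  m3 <- simulate_force_map(spec, 60)
  expect_identical(m1$curves[[1]]$deflection, m2$curves[[1]]$deflection)
  expect_false(identical(m1$curves[[1]]$deflection,
                         m3$curves[[1]]$deflection))
})
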