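# Map assembly, substrate-plane removal, region partition, statistics.

test_that("phantom cell height is recovered from contact points", {
  spec <- phantom_spec(seed = 21, n_rows = 14, n_cols = 14,
                       extent_um = c(80, 80), cell_radius_um = 25,
                       cell_peak_um = 4, noise_fraction = 0)
  map <- simulate_force_map(spec, 0)
  res <- analyze_force_map(map)
  est_peak <- max(res$height$values[res$height$cell_mask])
  true_peak <- max(attr(map, "truth")$height_um)
  expect_equal(est_peak, true_peak, tolerance = 0.05)
  # substrate sits at zero after plane removal
  expect_lt(sqrt(mean(res$height$values[res$height$substrate_mask]^2)), 0.02)
})

test_that("a tilted dish plane is removed to within tens of nanometres", {
  spec <- phantom_spec(seed = 22, n_rows = 12, n_cols = 12,
                       extent_um = c(80, 80), cell_radius_um = 22,
                       cell_peak_um = 3, plane_tilt_deg = 1,
                       noise_fraction = 0)
  map <- simulate_force_map(spec, 0)
  res <- analyze_force_map(map)
  sub <- res$height$substrate_mask
  expect_gt(sum(sub), 20)
  expect_lt(sqrt(mean(res$height$values[sub]^2)), 0.02)  # <= 20 nm RMS
})

test_that("an all-substrate map yields an empty cell mask", {
  n <- 6L
  fits <- data.table::data.table(
    row = rep(1:n, each = n), col = rep(1:n, times = n),
    young_modulus_kpa = 2000, contact_height_um = 0.001,
    contact_index = 100L, max_indentation_um = 0.005,
    force_at_deepest_nn = 1, rms_residual_nn = 0.01,
    max_abs_residual_nn = 0.02, qc_flags = "substrate_stiff",
    accepted = FALSE, error = "")
  maps <- build_maps(fits, n_rows = n, n_cols = n)
  expect_identical(sum(maps$height$cell_mask), 0L)
  expect_error(partition_regions(maps$height), "empty cell mask")
})

test_that("height partition matches the analytic spherical-cap geometry", {
  spec <- phantom_spec(seed = 23, n_rows = 64, n_cols = 64,
                       cell_radius_um = 30, cell_peak_um = 4)
  ph <- render_phantom(spec, 0)
  hm <- structure(list(values = ph$height_um,
                       mask = matrix(TRUE, 64, 64),
                       cell_mask = ph$height_um > 0,
                       substrate_mask = ph$height_um <= 0,
                       noise_floor_um = 0.05, n_rows = 64, n_cols = 64),
                  class = "height_map")
  part <- partition_regions(hm)
  frac <- sum(part$upper_region) / sum(part$cell_mask)
  # analytic area fraction of the half-height disk of this cap: 0.50444
  expect_equal(frac, 0.504444, tolerance = 0.05)
  # masks partition the cell exactly
  expect_true(all(part$upper_region | part$lower_region == part$cell_mask))
  expect_identical(sum(part$upper_region & part$lower_region), 0L)
  expect_identical(sum(part$cell_mask & part$substrate_mask), 0L)
})

test_that("boundary convention: exactly half height is upper region", {
  vals <- matrix(0, 3, 3)
  vals[1, ] <- 4; vals[2, ] <- 2; vals[3, ] <- 1.9
  hm <- structure(list(values = vals, mask = matrix(TRUE, 3, 3),
                       cell_mask = matrix(TRUE, 3, 3),
                       substrate_mask = matrix(FALSE, 3, 3),
                       noise_floor_um = 0.05, n_rows = 3, n_cols = 3),
                  class = "height_map")
  part <- partition_regions(hm)
  expect_true(all(part$upper_region[1, ]))
  expect_true(all(part$upper_region[2, ]))   # exactly 50% -> upper
  expect_true(all(part$lower_region[3, ]))

  # a uniform-height cell is entirely upper region
  hm$values <- matrix(3, 3, 3)
  part_u <- partition_regions(hm)
  expect_true(all(part_u$upper_region))
})

test_that("two-level cell puts only the high plateau in the upper region", {
  vals <- matrix(1, 4, 4); vals[, 3:4] <- 3
  hm <- structure(list(values = vals, mask = matrix(TRUE, 4, 4),
                       cell_mask = matrix(TRUE, 4, 4),
                       substrate_mask = matrix(FALSE, 4, 4),
                       noise_floor_um = 0.05, n_rows = 4, n_cols = 4),
                  class = "height_map")
  part <- partition_regions(hm)
  expect_true(all(part$upper_region[, 3:4]))
  expect_true(all(part$lower_region[, 1:2]))
})

test_that("statistics reproduce hand-computable values", {
  fx <- stats_fixture(c(1, 2, 3, 4, 5))
  st <- timepoint_statistics(fx$stiffness, fx$partition, time_min = 0)
  expect_identical(st$median_e_kpa, 3)
  expect_identical(st$mean_e_kpa, 3)
  expect_equal(st$sem_kpa, sd(1:5) / sqrt(5))
  expect_identical(st$n_points, 5L)

  expect_error(timepoint_statistics(
    stats_fixture(c(1, 2))$stiffness, stats_fixture(c(1, 2))$partition),
    "fewer than 3")
})

test_that("statistics are invariant to grid transposition", {
  set.seed(31)
  vals <- matrix(rlnorm(60, log(3), 0.3), 6, 10)
  mk <- function(v) {
    stiff <- structure(list(values = v, mask = matrix(TRUE, nrow(v), ncol(v)),
                            n_rows = nrow(v), n_cols = ncol(v)),
                       class = "stiffness_map")
    up <- v > median(v)
    part <- structure(list(cell_mask = matrix(TRUE, nrow(v), ncol(v)),
                           substrate_mask = matrix(FALSE, nrow(v), ncol(v)),
                           lower_region = !up, upper_region = up,
                           full_height_um = 1),
                      class = "region_partition")
    timepoint_statistics(stiff, part, 0)
  }
  expect_equal(mk(vals), mk(t(vals)))
})

test_that("time series normalisation and ordering checks work", {
  base <- stats_fixture(c(2, 3, 4))
  st <- do.call(rbind, lapply(c(0, 30, 60), function(t)
    timepoint_statistics(base$stiffness, base$partition, t)))
  ts <- time_series(st)
  expect_equal(ts$max_decrease_pct, 0)
  expect_equal(ts$profile$relative_median, c(1, 1, 1))

  st_bad <- st; st_bad$time_post_thaw_min <- c(0, 60, 30)
  expect_error(time_series(st_bad), "increasing")
})
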