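# Shared fixtures: all built in code at test time.

# Simulate one curve and run the full per-curve pipeline on it.
fit_single <- function(e_kpa, seed = 1, noise_fraction = 0,
                       outlier_fraction = 0, robust = TRUE) {
  sim <- simulate_force_curve(e_kpa, seed = seed,
                              noise_fraction = noise_fraction,
                              outlier_fraction = outlier_fraction)
  cp <- estimate_contact_point(sim$curve, sim$calib, sim$probe)
  fit <- fit_young_modulus(sim$curve, sim$calib, sim$probe, cp$index,
                           robust = robust, set_point_nn = sim$set_point_nn)
  list(sim = sim, cp = cp, fit = fit)
}

# Hard-surface (rigid substrate) calibration curve: in contact the
# deflection tracks the piezo travel exactly, at a known sensitivity.
rigid_calibration_curve <- function(sens_nm_per_v = 15.2, noise_v = 0,
                                    seed = 1, n_free = 300, n_contact = 200,
                                    dz_um = 0.0166) {
  z <- seq(n_free * dz_um, by = -dz_um, length.out = n_free + n_contact)
  travel_nm <- pmax(0, -z) * 1000
  v <- travel_nm / sens_nm_per_v
  if (noise_v > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_v)
  }
  force_curve(piezo_height_um = z, deflection = v, deflection_unit = "V")
}

# Minimal stiffness map + whole-cell partition around a vector of moduli,
# for statistics tests that need exact control of the values.
stats_fixture <- function(values, upper = rep(FALSE, length(values))) {
  n <- length(values)
  vals <- matrix(values, nrow = 1)
  mask <- matrix(TRUE, 1, n)
  stiff <- structure(list(values = vals, mask = mask, n_rows = 1, n_cols = n),
                     class = "stiffness_map")
  up <- matrix(upper, 1, n)
  part <- structure(list(cell_mask = mask,
                         substrate_mask = matrix(FALSE, 1, n),
                         lower_region = mask & !up,
                         upper_region = up,
                         full_height_um = 1),
                    class = "region_partition")
  list(stiffness = stiff, partition = part)
}

nominal_probe <- function() probe_geometry(radius_um = 3.31)
nominal_calib <- function() calibration_record(15.2, 0.018)
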